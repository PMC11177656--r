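#' Construct a patient-result stream
#'
#' A result stream is a data frame with one row per patient result, ordered
#' by timestamp (stable for ties), carrying the exclusion state used by the
#' truncation step. All results belong to one analyte.
#'
#' @param timestamp `POSIXct` (or ISO-8601 strings) of each result.
#' @param value numeric measurements, the `x_t` consumed by the EWMA.
#' @param analyte analyte label (single string).
#' @param instrument instrument identifier(s); recycled.
#' @param excluded logical exclusion flags; excluded results never reach the
#'   control chart.
#' @param exclusion_reason character reasons; must be non-empty wherever
#'   `excluded` is `TRUE`.
#' @return A `result_stream` (data frame) sorted by timestamp.
#' @export
result_stream <- function(timestamp, value, analyte = "analyte",
                          instrument = "inst-1", excluded = FALSE,
                          exclusion_reason = "") {
  if (is.character(timestamp)) timestamp <- parse_instant(timestamp)
  n <- length(timestamp)
  value <- as.numeric(value)
  if (length(value) != n)
    abort_validation("timestamp and value lengths differ (%d vs %d)",
                     n, length(value))
  if (any(!is.finite(value)))
    abort_validation("all result values must be finite")
  df <- data.frame(timestamp = timestamp,
                   analyte = rep_len(as.character(analyte), n),
                   value = value,
                   instrument = rep_len(as.character(instrument), n),
                   excluded = rep_len(as.logical(excluded), n),
                   exclusion_reason = rep_len(as.character(exclusion_reason), n),
                   stringsAsFactors = FALSE)
  if (length(unique(df$analyte)) > 1L)
    abort_validation("a result_stream holds a single analyte")
  if (any(df$excluded & !nzchar(df$exclusion_reason)))
    abort_validation("excluded results must carry an exclusion_reason")
  df <- df[order(df$timestamp), , drop = FALSE]  # order() is stable
  rownames(df) <- NULL
  class(df) <- c("result_stream", "data.frame")
  df
}

accepted_values <- function(stream) stream$value[!stream$excluded]

#' @export
print.result_stream <- function(x, ...) {
  cat(sprintf("<result_stream> %s: %d results (%d accepted), %s .. %s\n",
              x$analyte[1] %||% "?", nrow(x), sum(!x$excluded),
              format(min(x$timestamp)), format(max(x$timestamp))))
  invisible(x)
}

#' Read a patient-result stream from CSV
#'
#' Expects the header `timestamp,analyte,value,instrument` with ISO-8601
#' timestamps and decimal-point numbers. Rows whose value does not parse as
#' a number are collected as rejects (attribute `"rejects"`) rather than
#' aborting the load; rows are returned sorted by timestamp, original file
#' order preserved among ties.
#'
#' @param path CSV file path.
#' @return A `result_stream`; `attr(, "rejects")` is a data frame of the
#'   rejected rows (`row`, `reason`).
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) abort_validation("results file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("timestamp", "analyte", "value", "instrument")
  if (!all(need %in% names(raw)))
    abort_validation("results CSV must have header %s",
                     paste(need, collapse = ","))
  if (nrow(raw) == 0L) {
    warning("empty results file: ", path)
    out <- result_stream(as.POSIXct(character(), tz = "UTC"), numeric(),
                         analyte = "empty")
    attr(out, "rejects") <- data.frame(row = integer(), reason = character())
    return(out)
  }
  val <- suppressWarnings(as.numeric(raw$value))
  ts <- suppressWarnings(parse_instant(raw$timestamp))
  bad_val <- !is.finite(val)
  bad_ts <- is.na(ts)
  bad <- bad_val | bad_ts
  rejects <- data.frame(
    row = which(bad),
    reason = ifelse(bad_val[bad], paste0("non-numeric value: ", raw$value[bad]),
                    paste0("unparseable timestamp: ", raw$timestamp[bad])),
    stringsAsFactors = FALSE)
  keep <- !bad
  out <- result_stream(ts[keep], val[keep],
                       analyte = raw$analyte[keep][1] %||% "analyte",
                       instrument = raw$instrument[keep])
  attr(out, "rejects") <- rejects
  out
}

#' Write a patient-result stream to CSV
#'
#' Inverse of [read_results_csv()]; excluded rows are written like any other
#' (exclusion state is an in-memory annotation, not part of the interchange
#' format).
#'
#' @param stream a `result_stream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(stream, path) {
  df <- data.frame(timestamp = format_instant(stream$timestamp),
                   analyte = stream$analyte,
                   value = stream$value,
                   instrument = stream$instrument)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-risk events
#'
#' A quality-risk event is the interval between the occurrence of a quality
#' problem (calibration, reagent lot change, prolonged on-board time, ...)
#' and its correction; the interval is the ground-truth positive window for
#' scoring alarms. Membership is half-open: `[onset, closure)`.
#'
#' @param cause free-text cause.
#' @param onset,closure event window (`POSIXct` or ISO-8601 strings);
#'   `onset < closure` is required.
#' @param corrective_measure free-text corrective measure.
#' @param analyte optional analyte label.
#' @return A `risk_register` data frame sorted by onset.
#' @export
risk_events <- function(cause, onset, closure, corrective_measure = "",
                        analyte = NA_character_) {
  if (is.character(onset)) onset <- parse_instant(onset)
  if (is.character(closure)) closure <- parse_instant(closure)
  n <- length(cause)
  df <- data.frame(analyte = rep_len(as.character(analyte), n),
                   cause = as.character(cause),
                   onset = onset, closure = closure,
                   corrective = rep_len(as.character(corrective_measure), n),
                   stringsAsFactors = FALSE)
  bad <- !(df$onset < df$closure)
  if (any(bad))
    abort_validation("onset must precede closure (row %s)",
                     paste(which(bad), collapse = ", "))
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("risk_register", "data.frame")
  df
}

#' Read a quality-risk event register from CSV
#'
#' Expects the header `cause,onset,closure,corrective` (extra columns such
#' as `analyte` are carried through). Overlapping events are permitted; the
#' union of their windows defines the positive region.
#'
#' @param path CSV file path.
#' @return A `risk_register` sorted by onset.
#' @export
read_risk_events <- function(path) {
  if (!file.exists(path)) abort_validation("events file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("cause", "onset", "closure", "corrective")
  if (!all(need %in% names(raw)))
    abort_validation("events CSV must have header %s",
                     paste(need, collapse = ","))
  onset <- parse_instant(raw$onset)
  closure <- parse_instant(raw$closure)
  bad <- is.na(onset) | is.na(closure) | !(onset < closure)
  if (any(bad))
    abort_validation("invalid event window (onset >= closure or unparseable) in row %s",
                     paste(which(bad), collapse = ", "))
  risk_events(raw$cause, onset, closure, raw$corrective,
              analyte = raw$analyte %||% NA_character_)
}

#' Flag calibration-related quality-risk events
#'
#' An event is calibration-related when either its cause or its corrective
#' measure mentions calibration (case-insensitive match on "calibrat", which
#' also catches "calibrator").
#'
#' @param events a `risk_register`.
#' @return Logical vector, one flag per event.
#' @export
calibration_related <- function(events) {
  grepl("calibrat", events$cause, ignore.case = TRUE) |
    grepl("calibrat", events$corrective, ignore.case = TRUE)
}
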