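SIM_EPOCH <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")

#' Specify a synthetic patient-result stream
#'
#' The generator emulates an outpatient analyte stream: per-patient true
#' levels are lognormal about the population median with between-subject
#' variation `cvg`, and each reported result adds within-subject plus
#' analytical variation `sqrt(cvi^2 + cva^2)` (all CVs in percent).
#' Arrivals are a Poisson process at `n_per_day` per day. A small
#' `outlier_fraction` of results is replaced by uniform draws over
#' `[median/5, 5*median]`, mimicking pathological extremes.
#'
#' @param median population median in analyte units.
#' @param cvi,cvg,cva within-subject, between-subject and analytical CVs
#'   (percent).
#' @param skew_target `"lognormal"` (default; patient data are typically
#'   right-skewed) or `"none"` for a symmetric Gaussian stream.
#' @param n_per_day mean arrivals per day.
#' @param n_days number of days simulated.
#' @param outlier_fraction fraction in `[0, 0.05]` of results replaced by
#'   outliers.
#' @param seed mandatory integer seed; the stream is fully reproducible.
#' @return A `stream_spec` list.
#' @export
stream_spec <- function(median, cvi = 5, cvg = 5, cva = 2,
                        skew_target = c("lognormal", "none"),
                        n_per_day = 100, n_days = 30,
                        outlier_fraction = 0, seed) {
  skew_target <- match.arg(skew_target)
  if (missing(seed)) abort_validation("stream_spec requires an explicit seed")
  if (median <= 0) abort_validation("median must be positive")
  if (outlier_fraction < 0 || outlier_fraction > 0.05)
    abort_validation("outlier_fraction must lie in [0, 0.05]")
  for (cv in c(cvi, cvg, cva))
    if (!is.finite(cv) || cv < 0) abort_validation("CVs must be finite and >= 0")
  if (n_per_day <= 0 || n_days <= 0)
    abort_validation("n_per_day and n_days must be positive")
  structure(list(median = median, cvi = cvi, cvg = cvg, cva = cva,
                 skew_target = skew_target, n_per_day = n_per_day,
                 n_days = n_days, outlier_fraction = outlier_fraction,
                 seed = as.integer(seed)),
            class = "stream_spec")
}

#' Simulate a patient-result stream
#'
#' @param spec a [stream_spec()].
#' @param analyte analyte label for the stream.
#' @return A `result_stream` starting at 2022-06-01 00:00 UTC, with
#'   attribute `"start"` (the stream epoch).
#' @export
simulate_stream <- function(spec, analyte = "sim") {
  stopifnot(inherits(spec, "stream_spec"))
  with_seed(spec$seed, {
    # Poisson process: exponential gaps at rate n_per_day/day
    n_guess <- stats::qpois(1 - 1e-9, spec$n_per_day * spec$n_days)
    gaps <- stats::rexp(n_guess, rate = spec$n_per_day / 86400)
    tt <- cumsum(gaps)
    tt <- tt[tt < spec$n_days * 86400]
    n <- length(tt)
    cvw <- sqrt(spec$cvi^2 + spec$cva^2) / 100
    cvb <- spec$cvg / 100
    if (spec$skew_target == "lognormal") {
      sb <- sqrt(log1p(cvb^2))
      sw <- sqrt(log1p(cvw^2))
      subject <- spec$median * exp(stats::rnorm(n, 0, sb))
      value <- subject * exp(stats::rnorm(n, 0, sw))
    } else {
      value <- spec$median * (1 + stats::rnorm(n, 0, sqrt(cvb^2 + cvw^2)))
      value <- pmax(value, spec$median * 1e-6)
    }
    if (spec$outlier_fraction > 0) {
      out <- stats::runif(n) < spec$outlier_fraction
      value[out] <- stats::runif(sum(out), spec$median / 5, 5 * spec$median)
    }
    stream <- result_stream(SIM_EPOCH + tt, value, analyte = analyte,
                            instrument = "sim-1")
    attr(stream, "start") <- SIM_EPOCH
    stream
  })
}

#' Specify an analytical error episode
#'
#' Three mechanisms motivated by real quality-risk causes: `step_bias`
#' (calibration shift; adds `magnitude` training SDs to every in-window
#' value), `drift` (reagent deterioration; bias grows by `magnitude` SDs
#' per 100 in-window samples), `imprecision_inflation` (lot variability;
#' in-window deviations from the baseline median are multiplied by
#' `magnitude`).
#'
#' @param kind one of `"step_bias"`, `"drift"`, `"imprecision_inflation"`.
#' @param magnitude positive; SD multiples (step), SD per 100 samples
#'   (drift), or SD multiplier (inflation).
#' @param onset_day,closure_day window in days since stream start,
#'   `onset_day < closure_day`.
#' @param cause_label free-text cause recorded on the ground-truth event.
#' @return An `error_spec` list.
#' @export
error_spec <- function(kind = c("step_bias", "drift", "imprecision_inflation"),
                       magnitude, onset_day, closure_day,
                       cause_label = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || magnitude <= 0)
    abort_validation("magnitude must be > 0")
  if (onset_day >= closure_day)
    abort_validation("onset_day must precede closure_day")
  structure(list(kind = kind, magnitude = magnitude, onset_day = onset_day,
                 closure_day = closure_day,
                 cause_label = cause_label %||% kind),
            class = "error_spec")
}

stream_start <- function(stream) {
  attr(stream, "start") %||% trunc(min(stream$timestamp), units = "days")
}

#' Inject a scheduled analytical error into a stream
#'
#' The error acts on the measurand value itself (pre-truncation), so a
#' large bias can push samples outside the truncation range — reproducing
#' the failure mode where truncation eats the error signal. Out-of-window
#' values are untouched and order is preserved.
#'
#' @param stream a `result_stream`.
#' @param spec an [error_spec()].
#' @param sd_train training SD used to scale the magnitude.
#' @return List: `stream` (modified) and `event` (the matching ground-truth
#'   `risk_register` row).
#' @export
inject_error <- function(stream, spec, sd_train) {
  stopifnot(inherits(spec, "error_spec"))
  start <- stream_start(stream)
  onset <- start + spec$onset_day * 86400
  closure <- start + spec$closure_day * 86400
  span <- range(stream$timestamp)
  if (onset > span[2] || closure < span[1])
    abort_runtime("error window [day %g, day %g) lies outside the stream span",
                  spec$onset_day, spec$closure_day)
  inw <- which(stream$timestamp >= onset & stream$timestamp < closure)
  if (length(inw)) {
    v <- stream$value[inw]
    stream$value[inw] <- switch(spec$kind,
      step_bias = v + spec$magnitude * sd_train,
      drift = v + spec$magnitude * sd_train * seq_along(inw) / 100,
      imprecision_inflation = {
        m <- stats::median(stream$value[-inw])
        m + spec$magnitude * (v - m)
      })
  }
  event <- risk_events(spec$cause_label, onset, closure,
                       corrective_measure = "corrected",
                       analyte = stream$analyte[1])
  list(stream = stream, event = event)
}

#' Build a full simulation scenario
#'
#' Simulates a clean stream from the scenario's `stream` spec, injects its
#' `errors` in declaration order (overlapping windows of different kinds
#' compose in that order, with a warning), and returns the composed stream,
#' the ground-truth risk register, and the sample labels.
#'
#' @param scenario list with elements `stream` (a [stream_spec()] or plain
#'   list of its arguments) and `errors` (list of [error_spec()]s or plain
#'   lists), or the path to a JSON document with the same shape.
#' @param analyte analyte label.
#' @return List: `stream`, `events`, `labels` (consistent with
#'   [label_stream()]), `sd_train` (SD of the clean stream, the error
#'   scale), `clean` (the pre-injection stream).
#' @export
build_scenario <- function(scenario, analyte = "sim") {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  sspec <- scenario$stream
  if (!inherits(sspec, "stream_spec"))
    sspec <- do.call(stream_spec, sspec)
  errors <- lapply(scenario$errors %||% list(), function(e)
    if (inherits(e, "error_spec")) e else do.call(error_spec, e))
  clean <- simulate_stream(sspec, analyte = analyte)
  sd_train <- stats::sd(accepted_values(clean))
  if (length(errors) > 1L) {
    od <- vapply(errors, `[[`, numeric(1), "onset_day")
    cd <- vapply(errors, `[[`, numeric(1), "closure_day")
    kinds <- vapply(errors, `[[`, character(1), "kind")
    for (i in seq_along(errors)[-1]) {
      ov <- which(od[seq_len(i - 1)] < cd[i] & cd[seq_len(i - 1)] > od[i])
      if (length(ov) && any(kinds[ov] != kinds[i]))
        warning("overlapping error windows of different kinds; ",
                "composed in declaration order")
    }
  }
  stream <- clean
  ev_list <- list()
  for (e in errors) {
    r <- inject_error(stream, e, sd_train)
    stream <- r$stream
    ev_list[[length(ev_list) + 1L]] <- r$event
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list)
    else risk_events(character(), as.POSIXct(character(), tz = "UTC"),
                     as.POSIXct(character(), tz = "UTC"))
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("risk_register", "data.frame")
  labels <- label_stream(stream, events)
  list(stream = stream, events = events, labels = labels,
       sd_train = sd_train, clean = clean)
}

#' Read / write a scenario document (JSON)
#'
#' @param path JSON file path.
#' @return For `read_scenario`, the scenario list; for `write_scenario`,
#'   `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort_validation("scenario file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(stream = as.list(doc$stream),
       errors = if (is.data.frame(doc$errors))
         lapply(seq_len(nrow(doc$errors)), function(i)
           as.list(doc$errors[i, , drop = FALSE]))
       else doc$errors %||% list())
}

#' @rdname read_scenario
#' @param scenario scenario list (as accepted by [build_scenario()]).
#' @export
write_scenario <- function(scenario, path) {
  strip <- function(x) { attributes(x)$class <- NULL; x }
  doc <- list(stream = strip(scenario$stream),
              errors = lapply(scenario$errors %||% list(), strip))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
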