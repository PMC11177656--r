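arm_label <- function(method) {
  switch(method, boxcox_normality = "traditional",
         biological_variation = "bv_heuristic", fixed = "traditional",
         abort_validation("unknown truncation arm: %s", method))
}

#' Evaluate one (arm, lambda) PBRTQC model
#'
#' Estimates the truncation range on the training stream, derives control
#' limits from the truncated training values, monitors the truncated
#' validation stream, and scores the alarms against the risk register.
#'
#' @param train,valid training and validation `result_stream`s.
#' @param events `risk_register` of ground-truth quality-risk windows.
#' @param config an [analyte_config()]; its `truncation_method`, limit
#'   multipliers and rule set are used.
#' @param lam EWMA weighting coefficient.
#' @param level alarm level that counts for scoring (see [event_metrics()]).
#' @return A one-row `performance_report`; attributes `"alarms"`,
#'   `"trace"`, `"limits"`, `"truncation"` carry the intermediates.
#' @export
evaluate_model <- function(train, valid, events, config, lam,
                           level = "action") {
  rng <- estimate_truncation(accepted_values(train), config)
  train_t <- apply_truncation(train, rng)
  valid_t <- apply_truncation(valid, rng)
  limits <- compute_control_limits(accepted_values(train_t), lam,
                                   k_warn = config$k_warn,
                                   k_action = config$k_action)
  trace <- ewma_run(valid_t, lam, init = limits$center)
  alarms <- detect_alarms(trace, limits,
                          rules_enabled = config$rules_enabled)
  labeled <- label_stream(valid_t, events)
  m <- event_metrics(alarms, labeled, events, level = level)
  a <- compute_anped(alarms, labeled, events, level = level)
  auc <- if (any(labeled$label) && any(!labeled$label))
    roc_auc(trace, limits, labeled)$auc else NA_real_
  rep <- performance_report(
    analyte = config$analyte_name, arm = arm_label(config$truncation_method),
    lambda = lam, ped = m$ped, fpr = m$fpr, fnr = m$fnr,
    anped = a$anped_reported, auc = auc,
    n_samples = nrow(labeled),
    n_alarms = nrow(filter_alarm_level(alarms, level)),
    truncation_low = rng$low, truncation_high = rng$high)
  attr(rep, "alarms") <- alarms
  attr(rep, "trace") <- trace
  attr(rep, "limits") <- limits
  attr(rep, "truncation") <- rng
  rep
}

#' Split a stream into training and validation spans
#'
#' Mirrors a practice/validation design: the first `fraction` of samples
#' (time-ordered) trains the model, the remainder validates it. Default
#' 6/11 (six months practice, five months validation).
#'
#' @param stream a `result_stream`.
#' @param fraction fraction of samples in the training span.
#' @return List: `train`, `valid`.
#' @export
split_stream <- function(stream, fraction = 6 / 11) {
  if (fraction <= 0 || fraction >= 1)
    abort_validation("split fraction must lie in (0, 1)")
  n <- nrow(stream)
  k <- max(1L, floor(n * fraction))
  train <- stream[seq_len(k), , drop = FALSE]
  valid <- stream[setdiff(seq_len(n), seq_len(k)), , drop = FALSE]
  rownames(valid) <- NULL
  for (s in list(train, valid)) class(s) <- c("result_stream", "data.frame")
  class(train) <- class(valid) <- c("result_stream", "data.frame")
  attr(train, "start") <- attr(stream, "start")
  attr(valid, "start") <- attr(stream, "start")
  list(train = train, valid = valid)
}

#' Run the full two-arm benchmark
#'
#' Reproduces the comparison design: for each truncation arm (Box-Cox
#' normalisation vs biological-variation heuristic) and each weighting
#' coefficient in the grid, build the model on the training span, monitor
#' the validation span, and score against the event register — one report
#' row per (arm, lambda). Deterministic given fixed inputs.
#'
#' @param train,valid training and validation `result_stream`s.
#' @param events `risk_register`.
#' @param config an [analyte_config()]; `lambda_grid` supplies the grid.
#' @param arms truncation methods to compare.
#' @param level alarm level that counts for scoring.
#' @return A `performance_report` with `length(arms) * length(lambda_grid)`
#'   rows; attribute `"selection"` holds the [select_optimal()] result.
#' @export
run_benchmark <- function(train, valid, events, config,
                          arms = c("boxcox_normality",
                                   "biological_variation"),
                          level = "action") {
  rows <- list()
  for (arm in arms) {
    cfg <- config
    cfg$truncation_method <- arm
    for (lam in config$lambda_grid) {
      rows[[length(rows) + 1L]] <-
        evaluate_model(train, valid, events, cfg, lam, level = level)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("performance_report", "data.frame")
  attr(out, "selection") <- select_optimal(out)
  out
}

REPORT_COLUMNS <- c("analyte", "arm", "lambda", "truncation_low",
                    "truncation_high", "n", "n_alarms", "ped", "fpr",
                    "fnr", "anped", "auc")

#' Write / read a performance report
#'
#' CSV with the canonical column set (`analyte,arm,lambda,truncation_low,
#' truncation_high,n,n_alarms,ped,fpr,fnr,anped,auc`); an undefined ANPed
#' (no event detected) is rendered `-`. `write_report_json` mirrors the
#' rows to JSON.
#'
#' @param reports a `performance_report`.
#' @param path output path.
#' @return `path` invisibly; `read_report_csv` returns the report.
#' @export
write_report_csv <- function(reports, path) {
  df <- as.data.frame(reports)[, REPORT_COLUMNS]
  df$anped <- ifelse(is.na(df$anped), "-", as.character(df$anped))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(anped = "character"))
  missing_cols <- setdiff(REPORT_COLUMNS, names(df))
  if (length(missing_cols))
    abort_validation("report CSV missing columns: %s",
                     paste(missing_cols, collapse = ", "))
  df$anped <- suppressWarnings(as.numeric(ifelse(df$anped == "-", NA,
                                                 df$anped)))
  class(df) <- c("performance_report", "data.frame")
  df
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(reports, path) {
  df <- as.data.frame(reports)[, REPORT_COLUMNS]
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Path to the bundled worked-example data
#'
#' The package ships two plain-text fixtures transcribed from the study
#' that motivated this toolkit: `table1_performance.csv` (per-model
#' Ped/FPR/FNR/ANPed/AUC rows for six analytes, two truncation arms, three
#' weighting coefficients) and `table2_risk_register.csv` (the nine-event
#' quality-risk register).
#'
#' @param file file name under `inst/extdata`.
#' @return Absolute path to the installed file.
#' @export
pbrtqc_example <- function(file = "table1_performance.csv") {
  p <- system.file("extdata", file, package = "pbrtqc")
  if (!nzchar(p)) abort_validation("no bundled file named %s", file)
  p
}
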