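#' Label accepted samples against a quality-risk register
#'
#' A sample is positive when its timestamp falls inside at least one risk
#' period, with half-open membership `[onset, closure)`: a sample at the
#' onset instant is positive, a sample at closure is negative. When windows
#' overlap, the earliest-onset event claims the sample.
#'
#' @param stream a `result_stream` (only accepted samples are labelled).
#' @param events a `risk_register` (may be empty).
#' @return A `labeled_stream` data frame: `stream_index`, `timestamp`,
#'   `label` (logical), `event_id` (row in the onset-sorted register, `NA`
#'   for negatives).
#' @export
label_stream <- function(stream, events) {
  keep <- which(!stream$excluded)
  ts <- stream$timestamp[keep]
  label <- rep(FALSE, length(keep))
  event_id <- rep(NA_integer_, length(keep))
  if (!is.null(events) && nrow(events)) {
    for (j in rev(seq_len(nrow(events)))) {  # earliest onset wins overlaps
      inside <- ts >= events$onset[j] & ts < events$closure[j]
      label[inside] <- TRUE
      event_id[inside] <- j
    }
  }
  out <- data.frame(stream_index = keep, timestamp = ts, label = label,
                    event_id = event_id)
  class(out) <- c("labeled_stream", "data.frame")
  out
}

filter_alarm_level <- function(alarms, level = c("action", "warning")) {
  level <- match.arg(level)
  if (level == "action") alarms[alarms$level == "action", , drop = FALSE]
  else alarms
}

#' Event-level detection metrics
#'
#' Ped (probability of error detection) is the percentage of risk events
#' with at least one qualifying alarm inside their period — the event-level
#' sensitivity of the monitor. FNR is its complement (`Ped + FNR = 100`).
#' FPR is sample-level: the percentage of negative (outside every risk
#' period) accepted samples that are alarmed.
#'
#' @param alarms an `alarm_log` from [detect_alarms()].
#' @param labeled a `labeled_stream` over the same accepted stream.
#' @param events the `risk_register` used for labelling.
#' @param level minimum alarm level that counts: `"action"` (default;
#'   out-of-control only) or `"warning"` (warnings also count, the
#'   either-state reading used when scoring platform alarms).
#' @return List with `ped`, `fnr`, `fpr` (percent; `ped`/`fnr` are `NA`
#'   when the register is empty), `n_events`, `n_detected`, `detected`
#'   (logical per event), and sample-level confusion counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
event_metrics <- function(alarms, labeled, events, level = "action") {
  al <- filter_alarm_level(alarms, level)
  alarmed <- labeled$stream_index %in% al$stream_index
  n_events <- if (is.null(events)) 0L else nrow(events)
  detected <- logical(n_events)
  if (n_events) {
    for (j in seq_len(n_events)) {
      inside <- labeled$timestamp >= events$onset[j] &
        labeled$timestamp < events$closure[j]
      detected[j] <- any(alarmed & inside)
    }
  }
  neg <- !labeled$label
  pos <- labeled$label
  list(
    ped = if (n_events) 100 * sum(detected) / n_events else NA_real_,
    fnr = if (n_events) 100 * (1 - sum(detected) / n_events) else NA_real_,
    fpr = if (any(neg)) 100 * sum(alarmed & neg) / sum(neg) else NA_real_,
    n_events = n_events, n_detected = sum(detected), detected = detected,
    tp = sum(alarmed & pos), fp = sum(alarmed & neg),
    tn = sum(!alarmed & neg), fn = sum(!alarmed & pos))
}

#' Average number of patient samples to error detection (ANPed)
#'
#' For each detected event, counts accepted samples from event onset up to
#' and including the first qualifying alarmed sample (a detection on the
#' very first in-window sample scores 1). ANPed is the mean over detected
#' events; it is undefined (`NA`) when no event is detected. Only accepted
#' (post-truncation) samples are counted, since only those reach the chart.
#'
#' @inheritParams event_metrics
#' @return List: `per_event` (count or `NA` per event), `anped` (mean,
#'   unrounded), `anped_reported` (rounded to nearest integer, `NA`
#'   rendered as `"-"` downstream).
#' @export
compute_anped <- function(alarms, labeled, events, level = "action") {
  al <- filter_alarm_level(alarms, level)
  alarmed <- labeled$stream_index %in% al$stream_index
  n_events <- if (is.null(events)) 0L else nrow(events)
  per_event <- rep(NA_real_, n_events)
  if (n_events) {
    for (j in seq_len(n_events)) {
      from_onset <- which(labeled$timestamp >= events$onset[j])
      inside <- labeled$timestamp >= events$onset[j] &
        labeled$timestamp < events$closure[j]
      hit <- which(alarmed & inside)
      if (length(hit) && length(from_onset))
        per_event[j] <- hit[1] - from_onset[1] + 1
    }
  }
  det <- per_event[!is.na(per_event)]
  anped <- if (length(det)) mean(det) else NA_real_
  list(per_event = per_event, anped = anped,
       anped_reported = if (is.na(anped)) NA_real_ else round(anped))
}

#' ROC curve from scores and labels
#'
#' Sweeps a threshold grid over the score (`flagged` when `score > k`),
#' computing TPR (flagged positives / positives, ordinate) against FPR
#' (flagged negatives / negatives, abscissa); the curve is augmented with
#' (0,0) and (1,1) and the AUC is the trapezoid area.
#'
#' @param score numeric anomaly score per sample (higher = more suspect).
#' @param label logical ground-truth labels.
#' @param thresholds numeric threshold grid, or `NULL` to use every unique
#'   score (the exact empirical ROC).
#' @return List: `points` (data frame `threshold`, `fpr`, `tpr`), `auc`.
#' @export
roc_curve <- function(score, label, thresholds = NULL) {
  label <- as.logical(label)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L)
    abort_validation("ROC undefined: need both classes present")
  if (is.null(thresholds))
    thresholds <- sort(unique(c(score, -Inf)))
  tpr <- vapply(thresholds, function(k) sum(score > k & label) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(k) sum(score > k & !label) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(NA, thresholds, NA),
                    fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' ROC/AUC of an EWMA model against labels
#'
#' The per-sample anomaly score is the absolute EWMA z-score
#' `|q - center| / sd_ewma`; the threshold sweep runs over the control-limit
#' multiplier `k` (default 0 to 6 by 0.05, spanning well past any practical
#' action limit).
#'
#' @param trace an [ewma_run()] trace.
#' @param limits matching [compute_control_limits()].
#' @param labeled a `labeled_stream` over the same accepted stream.
#' @param k_grid threshold grid for the multiplier, or `NULL` for the exact
#'   empirical curve.
#' @return List: `points`, `auc`, `score`.
#' @export
roc_auc <- function(trace, limits, labeled, k_grid = seq(0, 6, by = 0.05)) {
  score <- abs(trace$q - limits$center) / limits$sd_ewma
  if (length(score) != nrow(labeled))
    abort_validation("trace and labels cover different accepted streams")
  rc <- roc_curve(score, labeled$label, thresholds = k_grid)
  c(rc, list(score = score))
}

#' Assemble a performance-report row
#'
#' One row per (analyte, truncation arm, lambda) model, with the metric
#' identities enforced: `ped + fnr = 100` (within tolerance) and
#' `0 <= auc <= 1`.
#'
#' @param analyte analyte label.
#' @param arm `"traditional"` (Box-Cox truncation) or `"bv_heuristic"`
#'   (biological-variation truncation).
#' @param lambda EWMA weighting coefficient.
#' @param ped,fpr,fnr percentages (`ped`/`fnr` may be `NA`).
#' @param anped mean samples-to-detection, `NA` when undefined.
#' @param auc area under the ROC curve in `[0, 1]`.
#' @param n_samples accepted validation samples scored.
#' @param n_alarms qualifying alarms raised.
#' @param truncation_low,truncation_high the applied truncation range.
#' @return A one-row `performance_report` data frame.
#' @export
performance_report <- function(analyte, arm = c("traditional", "bv_heuristic"),
                               lambda, ped, fpr, fnr = NULL, anped = NA_real_,
                               auc, n_samples = NA_integer_,
                               n_alarms = NA_integer_,
                               truncation_low = NA_real_,
                               truncation_high = NA_real_) {
  arm <- match.arg(arm)
  check_lambda(lambda)
  if (is.null(fnr)) fnr <- if (is.na(ped)) NA_real_ else 100 - ped
  if (!is.na(ped) && !is.na(fnr) && abs(ped + fnr - 100) > 1e-6)
    abort_validation("ped + fnr must equal 100 (got %g + %g)", ped, fnr)
  if (!is.na(auc) && (auc < 0 || auc > 1))
    abort_validation("auc must lie in [0, 1]")
  out <- data.frame(analyte = analyte, arm = arm, lambda = lambda,
                    truncation_low = truncation_low,
                    truncation_high = truncation_high,
                    n = n_samples, n_alarms = n_alarms,
                    ped = ped, fpr = fpr, fnr = fnr, anped = anped,
                    auc = auc, stringsAsFactors = FALSE)
  class(out) <- c("performance_report", "data.frame")
  out
}

#' Select the optimal PBRTQC model per analyte
#'
#' Applies the laboratory acceptability filter — error detection Ped > 90%
#' and false positive rate FPR < 5% — then ranks survivors by AUC (larger
#' is better; AUC > 0.9 is considered excellent), breaking ties toward the
#' smaller weighting coefficient. When no model survives the filter, the
#' analyte is flagged and the best-AUC model is reported as provisional.
#'
#' @param reports a `performance_report` data frame (rows for one or more
#'   analytes), or a list of such.
#' @param ped_min,fpr_max filter thresholds (default 90 and 5, percent).
#' @return Data frame with one row per analyte: `analyte`, `arm`, `lambda`,
#'   `auc`, `ped`, `fpr`, `meets_criteria`.
#' @export
select_optimal <- function(reports, ped_min = 90, fpr_max = 5) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (!nrow(reports)) abort_validation("no reports to select from")
  sel <- lapply(split(reports, reports$analyte), function(rr) {
    ok <- !is.na(rr$ped) & rr$ped > ped_min & !is.na(rr$fpr) &
      rr$fpr < fpr_max
    pool <- if (any(ok)) rr[ok, , drop = FALSE] else rr
    # max AUC, ties toward smaller lambda
    pool <- pool[order(-pool$auc, pool$lambda), , drop = FALSE]
    best <- pool[1, , drop = FALSE]
    data.frame(analyte = best$analyte, arm = best$arm, lambda = best$lambda,
               auc = best$auc, ped = best$ped, fpr = best$fpr,
               meets_criteria = any(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}
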