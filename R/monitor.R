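#' EWMA control limits from a training window
#'
#' Centre line is the training mean. The chart SD uses the asymptotic EWMA
#' standard deviation `sd_train * sqrt(lam / (2 - lam))`; warning and action
#' limits sit at `k_warn` and `k_action` chart SDs. Optionally the exact
#' time-varying factor `sqrt(1 - (1 - lam)^(2t))` can be applied by the
#' caller via `exact_factor()`; it only matters for the first ~3/lam points.
#'
#' @param training_values numeric vector of accepted (post-truncation)
#'   training results; at least 30 required.
#' @param lam EWMA weighting coefficient in (0, 1).
#' @param k_warn,k_action limit multipliers, `0 < k_warn < k_action`.
#' @return A `control_limits` list: `center`, `sd_train`, `sd_ewma`,
#'   `warn_low`, `warn_high`, `action_low`, `action_high`, `lam`.
#' @export
compute_control_limits <- function(training_values, lam, k_warn = 2,
                                   k_action = 3) {
  training_values <- training_values[is.finite(training_values)]
  if (length(training_values) < 30L)
    abort_validation("insufficient training data: %d values (need >= 30)",
                     length(training_values))
  check_lambda(lam)
  if (k_warn <= 0 || k_action <= k_warn)
    abort_validation("need 0 < k_warn < k_action")
  center <- mean(training_values)
  sd_train <- stats::sd(training_values)
  sd_ewma <- sd_train * sqrt(lam / (2 - lam))
  structure(list(center = center, sd_train = sd_train, sd_ewma = sd_ewma,
                 warn_low = center - k_warn * sd_ewma,
                 warn_high = center + k_warn * sd_ewma,
                 action_low = center - k_action * sd_ewma,
                 action_high = center + k_action * sd_ewma,
                 lam = lam, k_warn = k_warn, k_action = k_action),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf(
    "<control_limits> center %.4g, sd_ewma %.4g | warn [%.4g, %.4g], action [%.4g, %.4g]\n",
    x$center, x$sd_ewma, x$warn_low, x$warn_high, x$action_low,
    x$action_high))
  invisible(x)
}

#' Time-varying EWMA SD inflation factor
#'
#' Multiplies `sd_ewma` to give the exact chart SD at accepted-sample index
#' `t` (1-based): `sqrt(1 - (1 - lam)^(2t))`.
#'
#' @param t positive integer index or vector of indices.
#' @param lam weighting coefficient.
#' @return Numeric factor(s) in (0, 1].
#' @export
exact_factor <- function(t, lam) sqrt(1 - (1 - lam)^(2 * t))

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0 ||
      lam >= 1)
    abort_validation("lambda must satisfy 0 < lambda < 1 (got %s)",
                     deparse(lam))
  invisible(lam)
}

#' Run the EWMA recursion over an accepted stream
#'
#' `q_t = lam * x_t + (1 - lam) * q_(t-1)`, `q_0 = init`; one trace value
#' per accepted result. Smaller `lam` means a longer memory and better
#' sensitivity to small persistent bias.
#'
#' @param stream a `result_stream` (excluded results are skipped) or a
#'   plain numeric vector.
#' @param lam weighting coefficient in (0, 1).
#' @param init starting estimate `q_0`; conventionally the training mean.
#' @return An `ewma_trace` list: `q` (numeric, aligned to accepted
#'   results), `timestamp`, `index` (positions in the full stream), `lam`,
#'   `init`.
#' @export
ewma_run <- function(stream, lam, init) {
  check_lambda(lam)
  if (!is.numeric(init) || length(init) != 1L || !is.finite(init))
    abort_validation("init must be a single finite number")
  if (is.numeric(stream)) {
    x <- stream
    ts <- rep(as.POSIXct(NA), length(x))
    idx <- seq_along(x)
  } else {
    keep <- !stream$excluded
    x <- stream$value[keep]
    ts <- stream$timestamp[keep]
    idx <- which(keep)
  }
  q <- if (length(x))
    as.numeric(stats::filter(lam * x, 1 - lam, method = "recursive",
                             init = init))
  else numeric()
  structure(list(q = q, timestamp = ts, index = idx, lam = lam, init = init),
            class = "ewma_trace")
}

#' @export
print.ewma_trace <- function(x, ...) {
  cat(sprintf("<ewma_trace> %d points, lambda %.3g, init %.4g, q in [%.4g, %.4g]\n",
              length(x$q), x$lam, x$init,
              if (length(x$q)) min(x$q) else NA, if (length(x$q)) max(x$q) else NA))
  invisible(x)
}

#' Evaluate Westgard multirules on a z-score series
#'
#' Classic multirule QC over z-scores (deviations from a stated mean in SD
#' units):
#' \itemize{
#'   \item 1-2S: `|z| > 2` — warning only.
#'   \item 1-3S: `|z| > 3`.
#'   \item 2-2S: two consecutive z both `> 2` or both `< -2`.
#'   \item R-4S: a consecutive pair with opposite signs and range `> 4`
#'     (the within-run duplicate form does not apply to patient streams).
#'   \item 10-X: ten consecutive z strictly on one side of zero.
#' }
#' Sequential rules report at the last index of the triggering window.
#'
#' @param z numeric z-score vector.
#' @return Data frame with columns `index` (1-based), `rule`, `level`
#'   (`"warning"` for 1-2S, `"action"` otherwise), one row per firing.
#' @export
westgard_evaluate <- function(z) {
  n <- length(z)
  if (!n) return(data.frame(index = integer(), rule = character(),
                            level = character(), stringsAsFactors = FALSE))
  hit_frame <- function(index, rule, level)
    data.frame(index = index, rule = rep_len(rule, length(index)),
               level = rep_len(level, length(index)),
               stringsAsFactors = FALSE)
  hits <- list(
    hit_frame(which(abs(z) > 2), "1-2S", "warning"),
    hit_frame(which(abs(z) > 3), "1-3S", "action"))
  if (n >= 2L) {
    i <- 2:n
    two2 <- (z[i] > 2 & z[i - 1] > 2) | (z[i] < -2 & z[i - 1] < -2)
    r4 <- (sign(z[i]) * sign(z[i - 1]) < 0) & (abs(z[i] - z[i - 1]) > 4)
    hits <- c(hits, list(hit_frame(i[two2], "2-2S", "action"),
                         hit_frame(i[r4], "R-4S", "action")))
  }
  if (n >= 10L) {
    s <- sign(z)
    # run length of constant nonzero sign ending at each index
    run <- integer(n)
    run[1] <- as.integer(s[1] != 0)
    for (i in 2:n)
      run[i] <- if (s[i] != 0 && s[i] == s[i - 1]) run[i - 1] + 1L
                else as.integer(s[i] != 0)
    hits <- c(hits, list(hit_frame(which(run >= 10L), "10-X", "action")))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$index, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect alarms on an EWMA trace
#'
#' A point is at action level when the trace leaves the action band or any
#' rejection-grade Westgard rule fires on the trace z-series; warning level
#' when it is between the warning and action bands or only 1-2S fires.
#' Consecutive alarmed points are merged into episodes.
#'
#' @param trace an [ewma_run()] trace.
#' @param limits matching [compute_control_limits()].
#' @param rules_enabled subset of `c("limit_chart", "westgard")`.
#' @return An `alarm_log` data frame: `index` (position in the accepted
#'   stream), `stream_index`, `timestamp`, `level`, `rule`, `episode_id`.
#' @export
detect_alarms <- function(trace, limits,
                          rules_enabled = c("limit_chart", "westgard")) {
  stopifnot(inherits(trace, "ewma_trace"), inherits(limits, "control_limits"))
  rules_enabled <- match.arg(rules_enabled, several.ok = TRUE)
  q <- trace$q
  n <- length(q)
  recs <- list()
  if ("limit_chart" %in% rules_enabled && n) {
    act <- which(q < limits$action_low | q > limits$action_high)
    warn <- setdiff(which(q < limits$warn_low | q > limits$warn_high), act)
    recs <- c(recs, list(
      data.frame(index = act,
                 rule = rep_len("ewma>k_action", length(act)),
                 level = rep_len("action", length(act)),
                 stringsAsFactors = FALSE),
      data.frame(index = warn,
                 rule = rep_len("ewma>k_warn", length(warn)),
                 level = rep_len("warning", length(warn)),
                 stringsAsFactors = FALSE)))
  }
  if ("westgard" %in% rules_enabled && n) {
    zz <- (q - limits$center) / limits$sd_ewma
    recs <- c(recs, list(westgard_evaluate(zz)))
  }
  log <- do.call(rbind, recs)
  if (is.null(log) || nrow(log) == 0L) {
    log <- data.frame(index = integer(), stream_index = integer(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      level = character(), rule = character(),
                      episode_id = integer(), stringsAsFactors = FALSE)
    class(log) <- c("alarm_log", "data.frame")
    return(log)
  }
  log <- log[order(log$index, log$level, log$rule), , drop = FALSE]
  alarmed <- sort(unique(log$index))
  # consecutive alarmed points form one episode
  ep_start <- c(TRUE, diff(alarmed) > 1L)
  ep_of <- stats::setNames(cumsum(ep_start), alarmed)
  log$episode_id <- as.integer(ep_of[as.character(log$index)])
  log$stream_index <- trace$index[log$index]
  log$timestamp <- trace$timestamp[log$index]
  log <- log[, c("index", "stream_index", "timestamp", "level", "rule",
                 "episode_id")]
  rownames(log) <- NULL
  class(log) <- c("alarm_log", "data.frame")
  log
}

#' Episode summary of an alarm log
#'
#' @param log an `alarm_log`.
#' @return Data frame with one row per episode: `episode_id`, `start`,
#'   `end` (accepted-stream indices), `level` (worst level in episode).
#' @export
alarm_episodes <- function(log) {
  if (!nrow(log))
    return(data.frame(episode_id = integer(), start = integer(),
                      end = integer(), level = character()))
  sp <- split(log, log$episode_id)
  out <- do.call(rbind, lapply(sp, function(e) data.frame(
    episode_id = e$episode_id[1],
    start = min(e$index), end = max(e$index),
    level = if (any(e$level == "action")) "action" else "warning",
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
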