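# Independent oracles and fixture builders shared across the suite.
# Each oracle is written in a deliberately naive style, separate from the
# package's implementation path.

# plain-loop EWMA recursion
ewma_loop_oracle <- function(x, lam, init) {
  q <- numeric(length(x))
  prev <- init
  for (i in seq_along(x)) {
    prev <- lam * x[i] + (1 - lam) * prev
    q[i] <- prev
  }
  q
}

# per-index, per-rule Westgard evaluation by direct definition
westgard_oracle <- function(z) {
  rows <- list()
  add <- function(i, rule, level)
    rows[[length(rows) + 1L]] <<- data.frame(index = i, rule = rule,
                                             level = level)
  n <- length(z)
  for (i in seq_len(n)) {
    if (abs(z[i]) > 2) add(i, "1-2S", "warning")
    if (abs(z[i]) > 3) add(i, "1-3S", "action")
    if (i >= 2) {
      if ((z[i] > 2 && z[i - 1] > 2) || (z[i] < -2 && z[i - 1] < -2))
        add(i, "2-2S", "action")
      opposite <- (z[i] > 0 && z[i - 1] < 0) || (z[i] < 0 && z[i - 1] > 0)
      if (opposite && abs(z[i] - z[i - 1]) > 4) add(i, "R-4S", "action")
    }
    if (i >= 10) {
      w <- z[(i - 9):i]
      if (all(w > 0) || all(w < 0)) add(i, "10-X", "action")
    }
  }
  if (!length(rows))
    return(data.frame(index = integer(), rule = character(),
                      level = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$index, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rank-sum (Mann-Whitney) AUC
auc_rank_oracle <- function(score, label) {
  label <- as.logical(label)
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# dense-grid Box-Cox profile-likelihood argmax via MASS
boxcox_mass_oracle <- function(x, grid = seq(-2, 2, by = 0.005)) {
  bc <- MASS::boxcox(x ~ 1, lambda = grid, plotit = FALSE)
  bc$x[which.max(bc$y)]
}

# hourly stream fixture
make_stream <- function(values, analyte = "fix", start = "2022-06-01T00:00:00") {
  ts <- parse_ts(start) + 3600 * (seq_along(values) - 1)
  result_stream(ts, values, analyte = analyte)
}

parse_ts <- function(x) as.POSIXct(sub("T", " ", x), tz = "UTC")

# minimal alarm log pointing at given accepted-stream rows of `labeled`
make_alarm_log <- function(labeled, at, level = "action") {
  at <- as.integer(at)
  data.frame(index = at, stream_index = labeled$stream_index[at],
             timestamp = labeled$timestamp[at],
             level = rep_len(level, length(at)),
             rule = rep_len("ewma>k_action", length(at)),
             episode_id = seq_along(at))
}

write_tmp_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
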