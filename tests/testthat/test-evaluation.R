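fixture_labeled <- function(n = 200, events = NULL, start = "2022-06-01") {
  s <- make_stream(rep(100, n), start = paste0(start, "T00:00:00"))
  label_stream(s, events)
}

test_that("label_stream uses half-open [onset, closure) windows", {
  s <- make_stream(rep(1, 5))  # hourly from 00:00
  ev <- risk_events("x", "2022-06-01T01:00:00", "2022-06-01T03:00:00")
  lab <- label_stream(s, ev)
  expect_equal(lab$label, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(lab$event_id, c(NA, 1L, 1L, NA, NA))

  # no events -> all negative
  lab0 <- label_stream(s, NULL)
  expect_false(any(lab0$label))

  # overlap resolves to the earliest-onset event
  ev2 <- risk_events(c("a", "b"),
                     c("2022-06-01T00:00:00", "2022-06-01T01:00:00"),
                     c("2022-06-01T02:00:00", "2022-06-01T04:00:00"))
  lab2 <- label_stream(s, ev2)
  expect_equal(lab2$event_id[2], 1L)
  # excluded samples are not labelled
  s2 <- apply_truncation(s, truncation_fixed(0.5, 0.9))
  expect_equal(nrow(label_stream(s2, ev)), 0)
})

test_that("event_metrics computes Ped, FNR, FPR per definition", {
  # 9 events over 9 disjoint hours; stream of 180 hourly samples
  onsets <- sprintf("2022-06-0%dT00:00:00", 1:7)
  onsets <- c(onsets, "2022-06-08T00:00:00", "2022-06-09T00:00:00")
  closes <- sub("T00", "T02", onsets)
  ev <- risk_events(paste0("e", 1:9), onsets, closes)
  s <- make_stream(rep(1, 9 * 24))
  lab <- label_stream(s, ev)
  # alarm inside events 1..8, none in event 9
  first_idx <- vapply(1:8, function(j)
    which(lab$timestamp >= ev$onset[j] & lab$timestamp < ev$closure[j])[1],
    integer(1))
  alarms <- make_alarm_log(lab, first_idx)
  m <- event_metrics(alarms, lab, ev)
  expect_equal(m$ped, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(m$fnr, 100 / 9, tolerance = 1e-9)
  expect_equal(round(m$ped, 2), 88.89)
  expect_equal(m$fpr, 0)

  # 5 alarmed among 100 negative samples -> FPR 5
  ev1 <- risk_events("e", "2022-06-01T00:00:00", "2022-06-03T04:00:00")
  s2 <- make_stream(rep(1, 152))  # 52 positive, 100 negative
  lab2 <- label_stream(s2, ev1)
  neg_idx <- which(!lab2$label)[1:5]
  m2 <- event_metrics(make_alarm_log(lab2, neg_idx), lab2, ev1)
  expect_equal(m2$fpr, 5)
  expect_equal(m2$ped, 0)

  # zero events -> Ped/FNR undefined
  m0 <- event_metrics(make_alarm_log(lab2, 1L), lab2, NULL)
  expect_true(is.na(m0$ped) && is.na(m0$fnr))
})

test_that("Ped + FNR = 100 and confusion counts conserve on random fixtures", {
  set.seed(31)
  for (i in 1:20) {
    n <- 150
    s <- make_stream(rnorm(n, 100, 5))
    k <- sample(2:5, 1)
    on <- sort(sample(0:(n - 10), k)) * 3600 + parse_ts("2022-06-01T00:00:00")
    ev <- risk_events(paste0("e", 1:k), on, on + sample(3:8, k, TRUE) * 3600)
    lab <- label_stream(s, ev)
    alarms <- make_alarm_log(lab, sort(sample(n, sample(0:20, 1))))
    m <- event_metrics(alarms, lab, ev)
    expect_equal(m$ped + m$fnr, 100, tolerance = 1e-9)
    expect_equal(m$tp + m$fn, sum(lab$label))
    expect_equal(m$fp + m$tn, sum(!lab$label))
    expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(lab))
  }
})

test_that("compute_anped counts accepted samples from onset to first alarm", {
  s <- make_stream(rep(1, 300))
  # onset strictly between samples 100 and 101
  ev <- risk_events("e", "2022-06-05T03:30:00", "2022-06-09T00:00:00")
  lab <- label_stream(s, ev)
  expect_equal(which(lab$timestamp >= ev$onset)[1], 101)
  a <- compute_anped(make_alarm_log(lab, 108L), lab, ev)
  expect_equal(a$per_event, 8)

  # detection on the very first in-window sample scores 1
  a1 <- compute_anped(make_alarm_log(lab, 101L), lab, ev)
  expect_equal(a1$per_event, 1)

  # mean over detected events, rounded for reporting
  ev2 <- risk_events(c("a", "b"),
                     c("2022-06-05T03:30:00", "2022-06-10T03:30:00"),
                     c("2022-06-09T00:00:00", "2022-06-12T00:00:00"))
  lab2 <- label_stream(s, ev2)
  i2 <- which(lab2$timestamp >= ev2$onset[2])[1]
  a2 <- compute_anped(make_alarm_log(lab2, c(103L, i2 + 3L)), lab2, ev2)
  expect_equal(a2$per_event, c(3, 4))
  expect_equal(a2$anped, 3.5)
  expect_equal(a2$anped_reported, 4)

  # zero detections -> undefined
  a0 <- compute_anped(make_alarm_log(lab, integer()), lab, ev)
  expect_true(is.na(a0$anped))
})

test_that("roc_curve handles separation, permutation null, and the rank oracle", {
  # perfect separation
  rc <- roc_curve(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(rc$auc, 1.0)

  # exact curve equals the Mann-Whitney oracle at small n
  set.seed(32)
  for (i in 1:10) {
    n <- 40
    score <- rnorm(n)
    label <- runif(n) < 0.4
    if (!any(label) || all(label)) next
    rc <- roc_curve(score, label, thresholds = NULL)
    expect_equal(rc$auc, auc_rank_oracle(score, label), tolerance = 1e-12)
  }

  # permuted labels -> AUC near 0.5
  set.seed(33)
  score <- rlnorm(10000)
  label <- sample(rep(c(TRUE, FALSE), 5000))
  expect_equal(roc_curve(score, label, NULL)$auc, 0.5, tolerance = 0.03)

  # invariance under strictly monotone transform of the score
  set.seed(34)
  score <- rnorm(300)
  label <- runif(300) < 0.3
  a1 <- roc_curve(score, label, NULL)$auc
  a2 <- roc_curve(exp(score), label, NULL)$auc
  expect_equal(a1, a2, tolerance = 1e-12)

  expect_error(roc_curve(1:5, rep(TRUE, 5)),
               class = "pbrtqc_validation_error")
})

test_that("roc_auc scores the EWMA trace against labels on the k grid", {
  set.seed(35)
  sc <- build_scenario(list(
    stream = stream_spec(median = 100, cvi = 7, cvg = 7, cva = 1.4,
                         n_per_day = 50, n_days = 40, seed = 351),
    errors = list(error_spec("step_bias", 3, 25, 35))))
  sp <- split_stream(sc$stream, 0.5)
  cl <- compute_control_limits(accepted_values(sp$train), 0.05)
  tr <- ewma_run(sp$valid, 0.05, init = cl$center)
  lab <- label_stream(sp$valid, sc$events)
  r <- roc_auc(tr, cl, lab)
  expect_true(r$auc > 0.9)  # a 3 SD step is easy to rank
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= -1e-12))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
})

test_that("select_optimal applies the Ped/FPR filter then max AUC", {
  t1 <- read_report_csv(pbrtqc_example("table1_performance.csv"))
  amh <- t1[t1$analyte == "AMH", ]
  expect_equal(nrow(amh), 6)
  sel <- select_optimal(amh)
  expect_equal(sel$arm, "bv_heuristic")
  expect_equal(sel$lambda, 0.02)
  expect_true(sel$meets_criteria)

  # all rows failing the filter -> provisional best-AUC
  none <- do.call(rbind, list(
    performance_report("x", "traditional", 0.02, ped = 50, fpr = 1, auc = 0.8),
    performance_report("x", "traditional", 0.05, ped = 95, fpr = 9, auc = 0.9)))
  sel2 <- select_optimal(none)
  expect_false(sel2$meets_criteria)
  expect_equal(sel2$lambda, 0.05)  # best AUC still reported

  # equal AUC among survivors -> smaller lambda wins
  tie <- do.call(rbind, list(
    performance_report("y", "bv_heuristic", 0.05, ped = 95, fpr = 1, auc = 0.92),
    performance_report("y", "bv_heuristic", 0.02, ped = 94, fpr = 2, auc = 0.92)))
  expect_equal(select_optimal(tie)$lambda, 0.02)

  # boundary: ped = 90 or fpr = 5 do NOT pass the strict filter
  edge <- do.call(rbind, list(
    performance_report("z", "bv_heuristic", 0.02, ped = 90, fpr = 0, auc = 0.99),
    performance_report("z", "bv_heuristic", 0.03, ped = 91, fpr = 5, auc = 0.99),
    performance_report("z", "bv_heuristic", 0.05, ped = 91, fpr = 4.9, auc = 0.5)))
  sel3 <- select_optimal(edge)
  expect_equal(sel3$lambda, 0.05)
})

test_that("performance_report enforces the metric identities", {
  expect_error(performance_report("x", "traditional", 0.02, ped = 80,
                                  fpr = 1, fnr = 30, auc = 0.9),
               class = "pbrtqc_validation_error")
  expect_error(performance_report("x", "traditional", 0.02, ped = 80,
                                  fpr = 1, auc = 1.9),
               class = "pbrtqc_validation_error")
  r <- performance_report("x", "bv_heuristic", 0.02, ped = 80, fpr = 1,
                          auc = 0.9)
  expect_equal(r$fnr, 20)
})
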