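test_that("control limits follow the asymptotic EWMA SD formula", {
  set.seed(21)
  x <- rnorm(200, 50, 10)
  cl <- compute_control_limits(x, lam = 0.05)
  expect_equal(cl$center, mean(x))
  expect_equal(cl$sd_ewma, sd(x) * sqrt(0.05 / 1.95))
  expect_lt(cl$action_low, cl$warn_low)
  expect_lt(cl$warn_low, cl$center)
  expect_lt(cl$center, cl$warn_high)
  expect_lt(cl$warn_high, cl$action_high)

  # lam -> 1 limit: sd_ewma -> sd_train
  cl2 <- compute_control_limits(x, lam = 1 - 1e-9)
  expect_equal(cl2$sd_ewma, sd(x), tolerance = 1e-6)

  expect_error(compute_control_limits(rnorm(10), 0.05),
               class = "pbrtqc_validation_error")
  expect_error(compute_control_limits(x, 1.5),
               class = "pbrtqc_validation_error")
})

test_that("exact_factor approaches 1 and matches its definition", {
  expect_equal(exact_factor(1, 0.05), sqrt(1 - 0.95^2))
  expect_equal(exact_factor(1000, 0.05), 1, tolerance = 1e-12)
})

test_that("ewma_run matches the recursion exactly", {
  expect_equal(ewma_run(110, lam = 0.05, init = 100)$q, 100.5)

  # constant stream is a fixed point
  s <- make_stream(rep(7.5, 40))
  tr <- ewma_run(s, lam = 0.1, init = 7.5)
  expect_equal(tr$q, rep(7.5, 40))

  # brute-force loop oracle, 1000 points
  set.seed(22)
  x <- rlnorm(1000, 4, 0.3)
  for (lam in c(0.02, 0.05, 0.5)) {
    got <- ewma_run(x, lam, init = 55)$q
    want <- ewma_loop_oracle(x, lam, 55)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(ewma_run(x, lam = 0, init = 1),
               class = "pbrtqc_validation_error")
})

test_that("ewma_run skips excluded results", {
  s <- make_stream(c(10, 1000, 12))
  s <- apply_truncation(s, truncation_fixed(5, 100))
  tr <- ewma_run(s, 0.5, init = 10)
  expect_equal(length(tr$q), 2)
  expect_equal(tr$index, c(1L, 3L))
  expect_equal(tr$q, ewma_loop_oracle(c(10, 12), 0.5, 10))
})

test_that("EWMA trace is bounded by running min/max including init", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(300, 100, 15)
    init <- runif(1, 80, 120)
    q <- ewma_run(x, runif(1, 0.01, 0.9), init)$q
    lo <- cummin(c(init, x))[-1]
    hi <- cummax(c(init, x))[-1]
    expect_true(all(q >= lo - 1e-9 & q <= hi + 1e-9))
  }
})

test_that("westgard_evaluate reproduces the rule definitions", {
  v <- westgard_evaluate(c(0.1, 3.2))
  expect_setequal(v$rule[v$index == 2], c("1-2S", "1-3S"))
  expect_equal(v$level[v$rule == "1-2S"], "warning")

  v <- westgard_evaluate(c(2.3, 2.4))
  expect_true("2-2S" %in% v$rule[v$index == 2])

  v <- westgard_evaluate(c(2.3, -2.2))
  expect_true("R-4S" %in% v$rule[v$index == 2])
  expect_false("2-2S" %in% v$rule)

  v <- westgard_evaluate(rep(0.4, 10))
  expect_equal(v$rule, "10-X")
  expect_equal(v$index, 10L)

  expect_equal(nrow(westgard_evaluate(c(0, 1, -1, 1.9))), 0)
  # zero is on neither side: breaks a 10-X run
  expect_equal(nrow(westgard_evaluate(c(rep(0.4, 5), 0, rep(0.4, 5)))), 0)
})

test_that("westgard engine matches the naive oracle on random sequences", {
  set.seed(24)
  alphabet <- c(0, 1, -1, 2.1, -2.1, 2.5, -2.5, 3.1, -3.1)
  for (i in 1:2000) {
    z <- sample(alphabet, sample(1:10, 1), replace = TRUE)
    expect_identical(westgard_evaluate(z), westgard_oracle(z))
  }
})

test_that("detect_alarms classifies levels and merges episodes", {
  cl <- compute_control_limits(rnorm(100, 0, 1) - mean(rnorm(100)), 0.5)
  cl$center <- 0; cl$sd_ewma <- 1
  cl$warn_low <- -2; cl$warn_high <- 2
  cl$action_low <- -3; cl$action_high <- 3
  fake_trace <- function(q) structure(
    list(q = q, timestamp = parse_ts("2022-06-01") + seq_along(q) * 60,
         index = seq_along(q), lam = 0.5, init = 0), class = "ewma_trace")

  # single crossing at index 7 -> one action episode [7,7]
  q <- rep(0, 10); q[7] <- 3.5
  log <- detect_alarms(fake_trace(q), cl, rules_enabled = "limit_chart")
  expect_equal(unique(log$index), 7L)
  expect_equal(unique(log$level), "action")
  ep <- alarm_episodes(log)
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start, ep$end), c(7L, 7L))

  # entirely inside warn band -> empty log
  log0 <- detect_alarms(fake_trace(rep(1.5, 20)), cl,
                        rules_enabled = "limit_chart")
  expect_equal(nrow(log0), 0)

  # indices 5-9 above action -> one episode, not five
  q <- rep(0, 12); q[5:9] <- 3.2
  log2 <- detect_alarms(fake_trace(q), cl, rules_enabled = "limit_chart")
  ep2 <- alarm_episodes(log2)
  expect_equal(nrow(ep2), 1)
  expect_equal(c(ep2$start, ep2$end), c(5L, 9L))

  # between warn and action -> warning level
  q <- rep(0, 5); q[3] <- 2.5
  log3 <- detect_alarms(fake_trace(q), cl, rules_enabled = "limit_chart")
  expect_equal(unique(log3$level), "warning")

  # westgard on the z-series: 2-2S fires at action level inside warn band
  q <- c(0, 0, 2.5, 2.6, 0)
  log4 <- detect_alarms(fake_trace(q), cl,
                        rules_enabled = c("limit_chart", "westgard"))
  expect_true("2-2S" %in% log4$rule)
  expect_true("action" %in% log4$level[log4$rule == "2-2S"])
})

test_that("null-stream action rate sits in the binomial envelope of a 10x reference", {
  lam <- 0.05
  n <- 20000
  ref <- with(list(), {
    set.seed(25)
    train <- rnorm(2000, 100, 10)
    cl <- compute_control_limits(train, lam)
    x <- rnorm(10 * n, 100, 10)
    q <- ewma_run(x, lam, init = cl$center)$q
    mean(q < cl$action_low | q > cl$action_high)
  })
  set.seed(26)
  train <- rnorm(2000, 100, 10)
  cl <- compute_control_limits(train, lam)
  x <- rnorm(n, 100, 10)
  log <- detect_alarms(ewma_run(x, lam, init = cl$center), cl,
                       rules_enabled = "limit_chart")
  hits <- length(unique(log$index[log$level == "action"]))
  env <- qbinom(c(0.005, 0.995), n, max(ref, 1e-6))
  expect_gte(hits, env[1])
  expect_lte(hits, env[2])
})
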