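#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `y = log(x)` at
#' `lambda = 0` (the continuous limit). `bc_lambda` is the power-transform
#' exponent, unrelated to the EWMA weighting coefficient.
#'
#' @param values positive numeric vector.
#' @param bc_lambda transform exponent.
#' @return Transformed numeric vector.
#' @export
boxcox_transform <- function(values, bc_lambda) {
  if (any(values <= 0))
    abort_validation("Box-Cox requires strictly positive values; shift first")
  if (abs(bc_lambda) < 1e-12) log(values)
  else (values^bc_lambda - 1) / bc_lambda
}

boxcox_inverse <- function(y, bc_lambda) {
  if (abs(bc_lambda) < 1e-12) return(exp(y))
  base <- bc_lambda * y + 1
  out <- rep(NA_real_, length(y))
  ok <- base > 0
  out[ok] <- base[ok]^(1 / bc_lambda)
  out
}

# Profile log-likelihood of the Box-Cox model at each exponent, up to an
# additive constant: -n/2 log(sigma2_hat(y)) + (lambda - 1) sum(log x),
# with the MLE (1/n) variance.
boxcox_loglik <- function(values, lambdas) {
  n <- length(values)
  lx <- log(values)
  slx <- sum(lx)
  vapply(lambdas, function(l) {
    y <- if (abs(l) < 1e-12) lx else (values^l - 1) / l
    s2 <- sum((y - mean(y))^2) / n
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (l - 1) * slx
  }, numeric(1))
}

#' Fit the Box-Cox exponent by profile maximum likelihood
#'
#' Maximises the profile log-likelihood over a dense grid on `[-2, 2]`
#' (step 0.01) followed by local refinement with [stats::optimize()].
#'
#' @param values positive numeric vector (at least 20 distinct values).
#' @param lower,upper search interval for the exponent.
#' @return A `boxcox_fit` list: `bc_lambda`, `loglik`, `shift` (always 0
#'   here; shifts are handled by the caller).
#' @export
fit_boxcox_lambda <- function(values, lower = -2, upper = 2) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 20L)
    abort_validation("Box-Cox fit needs at least 20 distinct values (got %d)",
                     length(unique(values)))
  if (any(values <= 0))
    abort_validation("Box-Cox fit requires positive values; shift first")
  if (stats::sd(values) == 0)
    abort_validation("degenerate input: zero variance")
  grid <- seq(lower, upper, by = 0.01)
  ll <- boxcox_loglik(values, grid)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(l) boxcox_loglik(values, l),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  structure(list(bc_lambda = opt$maximum, loglik = opt$objective, shift = 0),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("<boxcox_fit> bc_lambda = %.4f (loglik %.2f, shift %g)\n",
              x$bc_lambda, x$loglik, x$shift))
  invisible(x)
}

new_truncation_range <- function(low, high, method, retained_fraction,
                                 bc_lambda = NULL) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    abort_validation("truncation range must satisfy low < high (got %g, %g)",
                     low, high)
  structure(list(low = low, high = high, method = method,
                 retained_fraction = retained_fraction,
                 bc_lambda = bc_lambda),
            class = "truncation_range")
}

#' @export
print.truncation_range <- function(x, ...) {
  cat(sprintf("<truncation_range> [%g, %g] (%s, retains %.1f%%%s)\n",
              x$low, x$high, x$method, 100 * x$retained_fraction,
              if (!is.null(x$bc_lambda))
                sprintf(", bc_lambda %.3f", x$bc_lambda) else ""))
  invisible(x)
}

#' Truncation range by Box-Cox normalisation (traditional arm)
#'
#' Transforms the training values to near-normality, takes
#' `mean +/- k_sigma * sd` in transformed space, and back-transforms. The
#' interval is intersected with the observed data range. Non-positive data
#' are shifted by `eps - min` (`eps = 1e-6 * range`) before the transform
#' and the shift is inverted afterwards. The in-transform SD uses the MLE
#' (1/n) denominator, so the bounds are invariant to duplicating the data.
#'
#' @param values numeric training values.
#' @param k_sigma central-coverage multiplier in transformed space
#'   (default 3, roughly 99.7% coverage for normal data).
#' @return A `truncation_range` with `retained_fraction` and the fitted
#'   `bc_lambda` recorded.
#' @export
truncation_by_normality <- function(values, k_sigma = 3) {
  values <- values[is.finite(values)]
  if (!length(values)) abort_validation("no finite training values")
  shift <- 0
  if (min(values) <= 0) {
    shift <- 1e-6 * diff(range(values)) - min(values)
    if (shift <= -min(values)) shift <- abs(min(values)) + 1e-6
  }
  x <- values + shift
  fit <- fit_boxcox_lambda(x)
  y <- boxcox_transform(x, fit$bc_lambda)
  n <- length(y)
  m <- mean(y)
  s <- sqrt(sum((y - m)^2) / n)
  lo_y <- m - k_sigma * s
  hi_y <- m + k_sigma * s
  lo <- boxcox_inverse(lo_y, fit$bc_lambda) - shift
  hi <- boxcox_inverse(hi_y, fit$bc_lambda) - shift
  # back-transform can fall outside the transform's domain (lambda*y+1 <= 0);
  # fall back to the observed extremes there
  if (is.na(lo)) lo <- min(values)
  if (is.na(hi)) hi <- max(values)
  lo <- max(lo, min(values))
  hi <- min(hi, max(values))
  retained <- mean(values >= lo & values <= hi)
  new_truncation_range(lo, hi, "boxcox_normality", retained,
                       bc_lambda = fit$bc_lambda)
}

#' Truncation range from biological variation (heuristic arm)
#'
#' Documented stand-in for proprietary AI range selection: the interval is
#' centred on the median with half-width
#' `k_bv * median * sqrt(cvi^2 + cvg^2) / 100` (CVs in percent; a missing
#' CVg degrades gracefully to CVi alone), then clipped to the 0.5th-99.5th
#' percentiles of the training data so the range never extends far beyond
#' observed results.
#'
#' @param values numeric training values.
#' @param cvi within-subject biological variation, percent (required).
#' @param cvg between-subject biological variation, percent, or `NA`.
#' @param k_bv half-width multiplier (default 2).
#' @return A `truncation_range`.
#' @export
truncation_by_bv <- function(values, cvi, cvg = NA_real_, k_bv = 2) {
  values <- values[is.finite(values)]
  if (!length(values)) abort_validation("no finite training values")
  if (is.null(cvi) || is.na(cvi))
    abort_validation("biological-variation truncation requires CVi")
  if (is.null(cvg) || is.na(cvg)) cvg <- 0
  center <- stats::median(values)
  half <- k_bv * center * sqrt(cvi^2 + cvg^2) / 100
  q <- stats::quantile(values, c(0.005, 0.995), names = FALSE, type = 7)
  lo <- max(center - half, q[1])
  hi <- min(center + half, q[2])
  retained <- mean(values >= lo & values <= hi)
  new_truncation_range(lo, hi, "biological_variation", retained)
}

#' Fixed truncation range
#'
#' @param low,high explicit bounds, `low < high`.
#' @param values optional training values used only to record the retained
#'   fraction.
#' @return A `truncation_range`.
#' @export
truncation_fixed <- function(low, high, values = NULL) {
  retained <- if (is.null(values)) NA_real_
    else mean(values >= low & values <= high)
  new_truncation_range(low, high, "fixed", retained)
}

#' Estimate a truncation range per an analyte configuration
#'
#' Dispatches on `config$truncation_method` with the method parameters in
#' `config$truncation_params`.
#'
#' @param values training values.
#' @param config an [analyte_config()].
#' @return A `truncation_range`.
#' @export
estimate_truncation <- function(values, config) {
  p <- config$truncation_params
  switch(config$truncation_method,
    boxcox_normality = truncation_by_normality(values,
                                               k_sigma = p$k_sigma %||% 3),
    biological_variation = truncation_by_bv(values, cvi = config$cvi,
                                            cvg = config$cvg,
                                            k_bv = p$k_bv %||% 2),
    fixed = truncation_fixed(p$low, p$high, values))
}

#' Apply a truncation range to a stream
#'
#' Results outside `[low, high]` are marked excluded with reason
#' `"truncated"` and are skipped by the monitor. Values are never altered
#' and order is preserved (exclusion, not winsorisation).
#'
#' @param stream a `result_stream`.
#' @param range a `truncation_range`.
#' @return The stream with updated exclusion flags;
#'   `attr(, "exclusion_stats")` records kept/excluded counts.
#' @export
apply_truncation <- function(stream, range) {
  stopifnot(inherits(range, "truncation_range"))
  out <- !stream$excluded & (stream$value < range$low |
                             stream$value > range$high)
  stream$excluded[out] <- TRUE
  stream$exclusion_reason[out] <- "truncated"
  attr(stream, "exclusion_stats") <- list(
    kept = sum(!stream$excluded),
    excluded = sum(stream$excluded),
    total = nrow(stream))
  stream
}
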