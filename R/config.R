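#' Analyte monitoring configuration
#'
#' Bundles everything needed to build a PBRTQC model for one analyte:
#' biological-variation coefficients, the EWMA weighting-coefficient grid,
#' the truncation method and its parameters, and the control-limit
#' multipliers.
#'
#' @param analyte_name analyte label, e.g. `"TT4"`.
#' @param units measurement units, e.g. `"nmol/L"`.
#' @param cvi within-subject biological variation, percent. May be `NA`.
#' @param cvg between-subject biological variation, percent. May be `NA`
#'   (several immunoassay analytes have no catalogued CVg).
#' @param reference_interval optional numeric `c(low, high)` in analyte units.
#' @param lambda_grid EWMA weighting coefficients, each in (0, 1).
#'   Default `c(0.02, 0.03, 0.05)`.
#' @param truncation_method one of `"boxcox_normality"`,
#'   `"biological_variation"`, `"fixed"`.
#' @param truncation_params named list of method-specific numbers:
#'   `k_sigma` for Box-Cox (default 3), `k_bv` for biological variation
#'   (default 2), `low`/`high` for fixed.
#' @param k_warn warning-limit multiplier (default 2).
#' @param k_action action-limit multiplier (default 3); must exceed `k_warn`.
#' @param rules_enabled subset of `c("limit_chart", "westgard")`.
#' @return An object of class `analyte_config`.
#' @export
analyte_config <- function(analyte_name,
                           units = "",
                           cvi = NA_real_,
                           cvg = NA_real_,
                           reference_interval = NULL,
                           lambda_grid = c(0.02, 0.03, 0.05),
                           truncation_method = c("boxcox_normality",
                                                 "biological_variation",
                                                 "fixed"),
                           truncation_params = list(),
                           k_warn = 2,
                           k_action = 3,
                           rules_enabled = "limit_chart") {
  truncation_method <- match.arg(truncation_method)
  if (!is.character(analyte_name) || !nzchar(analyte_name))
    abort_validation("analyte_name must be a non-empty string")
  lambda_grid <- as.numeric(lambda_grid)
  if (length(lambda_grid) == 0L || anyNA(lambda_grid) ||
      any(lambda_grid <= 0 | lambda_grid >= 1))
    abort_validation("every lambda must satisfy 0 < lambda < 1 (got %s)",
                     paste(lambda_grid, collapse = ", "))
  for (cv in list(cvi = cvi, cvg = cvg)) {
    if (!is.na(cv) && cv < 0)
      abort_validation("biological variation CVs must be non-negative")
  }
  if (!is.numeric(k_warn) || !is.numeric(k_action) || k_warn <= 0 ||
      k_action <= 0 || k_warn >= k_action)
    abort_validation("need 0 < k_warn < k_action (got %s, %s)",
                     k_warn, k_action)
  if (!is.null(reference_interval)) {
    reference_interval <- as.numeric(reference_interval)
    if (length(reference_interval) != 2L ||
        reference_interval[1] >= reference_interval[2])
      abort_validation("reference_interval must be c(low, high), low < high")
  }
  bad_rules <- setdiff(rules_enabled, c("limit_chart", "westgard"))
  if (length(bad_rules))
    abort_validation("unknown rules: %s", paste(bad_rules, collapse = ", "))
  if (truncation_method == "fixed") {
    lo <- truncation_params$low
    hi <- truncation_params$high
    if (is.null(lo) || is.null(hi) || !is.finite(lo) || !is.finite(hi) ||
        lo >= hi)
      abort_validation(
        "fixed truncation requires truncation_params low < high")
  }
  structure(list(analyte_name = analyte_name, units = units,
                 cvi = as.numeric(cvi), cvg = as.numeric(cvg),
                 reference_interval = reference_interval,
                 lambda_grid = lambda_grid,
                 truncation_method = truncation_method,
                 truncation_params = truncation_params,
                 k_warn = k_warn, k_action = k_action,
                 rules_enabled = rules_enabled),
            class = "analyte_config")
}

#' @export
print.analyte_config <- function(x, ...) {
  cat(sprintf("<analyte_config> %s (%s)\n", x$analyte_name, x$units))
  cat(sprintf("  CVi %s%%, CVg %s%% | lambda grid {%s}\n",
              x$cvi, x$cvg, paste(x$lambda_grid, collapse = ", ")))
  cat(sprintf("  truncation: %s | k_warn %g, k_action %g | rules: %s\n",
              x$truncation_method, x$k_warn, x$k_action,
              paste(x$rules_enabled, collapse = "+")))
  invisible(x)
}

#' Load analyte configurations from a JSON document
#'
#' The document holds one object per analyte under an `"analytes"` array
#' (or is itself an array). Missing fields take the package defaults
#' (`k_warn = 2`, `k_action = 3`, lambda grid `{0.02, 0.03, 0.05}`).
#'
#' @param path path to a JSON configuration file.
#' @return Named list of [analyte_config()] objects, one per analyte.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- doc$analytes %||% doc
  if (length(entries) == 0L) abort_validation("config declares no analytes")
  cfgs <- lapply(entries, function(e) {
    analyte_config(
      analyte_name = e$analyte_name %||% e$analyte,
      units = e$units %||% "",
      cvi = e$cvi %||% NA_real_,
      cvg = e$cvg %||% NA_real_,
      reference_interval = if (!is.null(e$reference_interval))
        unlist(e$reference_interval),
      lambda_grid = if (!is.null(e$lambda_grid)) unlist(e$lambda_grid)
        else c(0.02, 0.03, 0.05),
      truncation_method = e$truncation_method %||% "boxcox_normality",
      truncation_params = lapply(e$truncation_params %||% list(), unlist),
      k_warn = e$k_warn %||% 2,
      k_action = e$k_action %||% 3,
      rules_enabled = unlist(e$rules_enabled %||% "limit_chart")
    )
  })
  names(cfgs) <- vapply(cfgs, `[[`, character(1), "analyte_name")
  cfgs
}
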