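#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pbrtqc_validation_error", "pbrtqc_error")))
}

abort_runtime <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pbrtqc_runtime_error", "pbrtqc_error")))
}

#' Evaluate an expression with a private RNG stream
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's
#' `.Random.seed`, so package functions never leak global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_validation("seed must be a single integer (got %s)", deparse(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# ISO-8601 parser: accepts "2022-06-16", "2022-06-16 08:00:00",
# "2022-06-16T08:00:00". Everything is treated as UTC; the toolkit is
# locale-independent by construction.
parse_instant <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

format_instant <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
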