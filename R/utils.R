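#' @keywords internal
"_PACKAGE"

# Condition constructors: every user-facing error carries a class so callers
# (and the pipeline driver) can map failures to exit codes.
stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("paddyMeHg_format_error", "error")))
}
stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("paddyMeHg_schema_error", "error")))
}
stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("paddyMeHg_domain_error", "error")))
}
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("paddyMeHg_config_error", "error")))
}
stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("paddyMeHg_data_error", "error")))
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages at or above this level are written to `stderr`.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("paddyMeHg.log_level", "info")
  options(paddyMeHg.log_level = level)
  invisible(old)
}

log_msg <- function(level, msg, ...) {
  cur <- getOption("paddyMeHg.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[cur]]) {
    message(sprintf("[%s] %s", level, sprintf(msg, ...)))
  }
  invisible(NULL)
}

#' Derive a child seed from a parent seed and an index path
#'
#' A documented counter scheme: `seed` is folded with each index through a
#' Lehmer-style multiplicative step modulo 2147483647, so any single split,
#' permutation, or module run is reproducible in isolation from the global
#' seed. All arithmetic stays below 2^53, so the result is exact in doubles.
#'
#' @param seed Integer parent seed.
#' @param ... Integer indices (e.g. split number, permutation number).
#' @return An integer in \[1, 2147483646\].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (i in as.numeric(c(...))) {
    s <- (s * 48271 + i + 1) %% m
  }
  as.integer(s + 1)
}

# Evaluate expr with a fixed, platform-stable RNG state; restores the caller's
# state afterwards. Mersenne-Twister + inversion gives identical streams on
# all platforms R supports.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# z-standardize a numeric vector; constant vectors error (no scale information)
zscore <- function(x, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_domain("cannot standardize constant %s", what)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
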