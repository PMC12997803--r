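# Local similarity analysis for short, evenly indexed time series: a
# rank-normal transform, a delay-limited running-maximum dynamic program for
# the local similarity score, whole-series permutation p-values, and BH FDR.

#' Rank-normal score transform
#'
#' Maps midranks `r` to `qnorm((r - 0.5) / n)`. Rank-based, so any strictly
#' monotone transform of the input yields identical output.
#'
#' @param x Numeric vector, length >= 4, no missing values.
#' @return Numeric vector of normal scores.
#' @export
normal_score <- function(x) {
  if (anyNA(x)) stop_data("normal_score forbids missing values; drop or interpolate first")
  n <- length(x)
  if (n < 4L) stop_domain("need length >= 4, got %d", n)
  if (stats::sd(x) == 0) stop_domain("constant vector carries no rank information")
  stats::qnorm((rank(x) - 0.5) / n)
}

# running-maximum (Kadane) recursion for the best contiguous-window sum.
# Windows are accumulated left-to-right, so the result is bit-identical to
# naive enumeration of every window (fp addition is monotone); all-negative
# input yields the largest single element.
.max_subarray <- function(z) {
  best <- -Inf
  cur <- 0
  for (v in z) {
    cur <- cur + v
    if (cur < v) cur <- v
    if (cur > best) best <- cur
  }
  best
}

#' Delay-limited local similarity score
#'
#' Over all delays `d` with `|d| <= D` and all contiguous index windows,
#' finds the maximum of `|sum x[i] * y[i + d]|`, normalized by the full
#' series length `n`. Positive and negative associations are scanned by a
#' running-maximum (Kadane) recursion over the aligned products for each
#' delay; ties are broken toward smaller `|d|`, then toward a positive sign.
#' A positive returned `delay` means `y` lags `x` by that many steps.
#'
#' @param x,y Numeric vectors of equal length `n >= 4` (normal-score them
#'   first for the canonical statistic, see [normal_score()]).
#' @param D Maximum absolute delay, `0 <= D < n`.
#' @return List with `score` (>= 0), `sign` (`"positive"` or `"negative"`),
#'   `delay` (integer in `[-D, D]`).
#' @export
local_similarity <- function(x, y, D = 3L) {
  n <- length(x)
  if (length(y) != n) stop_domain("x and y must have equal length")
  if (n < 4L) stop_domain("need length >= 4, got %d", n)
  if (D < 0 || D >= n) stop_config("D must satisfy 0 <= D < n")
  best <- list(score = 0, sign = "positive", delay = 0L)
  delays <- 0L
  for (a in seq_len(D)) delays <- c(delays, a, -a)  # smaller |d| first
  for (d in delays) {
    idx <- if (d >= 0) seq_len(n - d) else seq(1 - d, n)
    z <- x[idx] * y[idx + d]
    pos <- max(0, .max_subarray(z)) / n
    neg <- max(0, .max_subarray(-z)) / n
    # strict improvement only: earlier delays (and positive sign) win ties
    if (pos >= neg) {
      if (pos > best$score) best <- list(score = pos, sign = "positive", delay = as.integer(d))
      if (neg > best$score) best <- list(score = neg, sign = "negative", delay = as.integer(d))
    } else {
      if (neg > best$score) best <- list(score = neg, sign = "negative", delay = as.integer(d))
      if (pos > best$score) best <- list(score = pos, sign = "positive", delay = as.integer(d))
    }
  }
  best
}

#' Local similarity tests of many series against one target
#'
#' Each series (column) is rank-normalized and scored against the
#' rank-normalized target with [local_similarity()]. Per-pair p-values come
#' from whole-series permutation of the target copy assigned to that pair:
#' `p = (1 + #{permuted score >= observed}) / (1 + n_perm)`. Series lengths
#' of ~11 points make theoretical approximations unreliable, so permutation
#' is the only p-value path. `q` is the BH adjustment over all pairs tested
#' together.
#'
#' @param series Numeric matrix or data frame, rows = time points in order,
#'   columns = series.
#' @param target Numeric target series (e.g. MeHg), same length as the
#'   series rows.
#' @param D Maximum absolute delay.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param normalize Apply [normal_score()] to all series first (default
#'   `TRUE`).
#' @return Data frame of class `lsa_result`: `series_id`, `score`, `sign`,
#'   `delay`, `p`, `q`.
#' @export
lsa_test <- function(series, target, D = 3L, n_perm = 199, seed = 1,
                     normalize = TRUE) {
  series <- as.matrix(series)
  if (nrow(series) != length(target))
    stop_domain("series rows (%d) and target length (%d) differ",
                nrow(series), length(target))
  if (n_perm < 99) stop_config("n_perm must be >= 99")
  ids <- colnames(series) %||% sprintf("series_%03d", seq_len(ncol(series)))
  tgt <- if (normalize) normal_score(target) else target
  cols <- lapply(seq_len(ncol(series)), function(j) {
    if (normalize) normal_score(series[, j]) else series[, j]
  })
  n <- length(tgt)
  rows <- lapply(seq_len(ncol(series)), function(j) {
    obs <- local_similarity(tgt, cols[[j]], D)
    perm_ge <- with_seed(derive_seed(seed, j), {
      sum(vapply(seq_len(n_perm), function(k) {
        local_similarity(tgt[sample.int(n)], cols[[j]], D)$score >= obs$score
      }, TRUE))
    })
    data.frame(series_id = ids[j], score = obs$score, sign = obs$sign,
               delay = obs$delay, p = (1 + perm_ge) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  class(out) <- c("lsa_result", "data.frame")
  out
}
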