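# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration, closed forms, hand formulas) and never
# call the code paths they check.

set_log_level("warn")

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive local-similarity enumeration over every (delay, start, length)
brute_lsa_score <- function(x, y, D) {
  n <- length(x)
  best <- 0
  for (d in -D:D) {
    idx <- if (d >= 0) seq_len(n - d) else seq(1 - d, n)
    z <- x[idx] * y[idx + d]
    m <- length(z)
    for (s in seq_len(m)) {
      acc <- 0
      for (e in s:m) {
        acc <- acc + z[e]
        best <- max(best, abs(acc))
      }
    }
  }
  best / n
}

# published TMM definition, no trimming, precision-weighted mean of M values
hand_tmm_factors_notrim <- function(counts) {
  counts <- as.matrix(counts)
  N <- colSums(counts)
  # reference: upper-quartile count fraction closest to the mean fraction
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75)) / N
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    y <- counts[, i]; r <- counts[, ref]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    M <- log2((y / N[i]) / (r / N[ref]))
    w <- (N[i] - y) / (N[i] * y) + (N[ref] - r) / (N[ref] * r)
    2^(sum(M / w) / sum(1 / w))
  }, 0)
  f / exp(mean(log(f)))
}

# Gaussian log-likelihood at the MLE variance and the small-sample AIC
hand_loglik <- function(residuals) {
  n <- length(residuals)
  s2 <- sum(residuals^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}
hand_aicc <- function(loglik, k, n) -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)

# Spearman rho by the definitional route: Pearson correlation of midranks
hand_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Kruskal-Wallis statistic from the rank formula with tie correction
hand_kruskal <- function(groups) {
  all <- unlist(groups)
  n <- length(all)
  r <- rank(all)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(all)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# BH step-up applied literally
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# domtblout writer for hand-built rows (io fixture helper)
write_domtbl_lines <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r$target, "-", "300", r$query, "-", r$qlen, r$evalue, r$score,
          "0.1", "1", "1", r$evalue, r$evalue, r$dom_score %||% r$score, "0.1",
          "1", r$qlen, "1", r$qlen, "1", r$qlen, "0.90",
          r$desc %||% "", sep = " ")
  }, "")
  writeLines(c("# hmmsearch domtblout", lines), path)
}
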