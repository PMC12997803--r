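# Beta-diversity machinery: Bray-Curtis dissimilarity, principal-coordinates
# embedding, distance-based RDA with permutation tests, and PERMANOVA with
# Bonferroni-corrected pairwise comparisons.

#' Bray-Curtis dissimilarity matrix
#'
#' `D[i, j] = sum|x - y| / sum(x + y)` over taxa, via [vegan::vegdist()].
#'
#' @param table Non-negative samples x taxa matrix or data frame; no sample
#'   may be all-zero.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop_domain("abundance table has negative cells")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop_data("all-zero sample(s): %s",
              paste(rownames(m)[zero] %||% which(zero), collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal-coordinates analysis
#'
#' Gower-centered double-centering eigen-decomposition of a distance matrix.
#' Axes with eigenvalue below `1e-10 x` the largest are dropped; axes with
#' negative eigenvalues are dropped and their total magnitude reported (no
#' Lingoes/Cailliez correction is applied).
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return List with `points` (samples x retained axes), `eigenvalues`
#'   (retained, positive), `negative_magnitude` (sum of |negative
#'   eigenvalues|), `all_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stop_data("PCoA needs at least 3 samples, got %d", n)
  # cmdscale warns when fewer than k axes have positive eigenvalues; the
  # eigenvalue screen below handles that case deliberately
  sol <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sol$eig
  neg <- sum(abs(eig[eig < 0]))
  if (neg > 0) {
    log_msg("info", "PCoA dropped negative eigenvalues (total magnitude %.3g)", neg)
  }
  if (all(eig <= 0)) {
    return(list(points = matrix(0, n, 0, dimnames = list(attr(d, "Labels"), NULL)),
                eigenvalues = numeric(0), negative_magnitude = neg,
                all_eigenvalues = eig))
  }
  keep <- which(eig > 1e-10 * max(eig))
  pts <- sol$points[, keep, drop = FALSE]
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("PCo", seq_along(keep))
  list(points = pts, eigenvalues = eig[keep], negative_magnitude = neg,
       all_eigenvalues = eig)
}

#' Distance-based redundancy analysis with permutation tests
#'
#' Constrains a Bray-Curtis (or other) distance matrix on a table of
#' environmental variables via [vegan::capscale()] (PCoA axes regressed on
#' the variables). The constrained fraction is the canonical eigenvalue sum
#' over the total retained (positive) eigenvalue sum. Overall and marginal
#' per-variable significance come from permutation of the environment rows,
#' with `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param d A `dist` object.
#' @param env Data frame of explanatory variables (rows match `d` labels;
#'   standardize continuous variables beforehand for comparable loadings).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed making every permutation p reproducible.
#' @param margin Also run marginal per-variable tests (default `TRUE`; the
#'   overall test alone is cheaper for simulations).
#' @return Object of class `db_rda_result`: list with `constrained_fraction`,
#'   `overall` (pseudo-F and p), `term_tests` (per-variable pseudo-F and p),
#'   `scores`, `eigenvalues`, `model`.
#' @export
db_rda <- function(d, env, n_perm = 999, seed = 1, margin = TRUE) {
  d <- stats::as.dist(d)
  env <- as.data.frame(env)
  if (nrow(env) != attr(d, "Size"))
    stop_data("env rows (%d) do not match distance size (%d)", nrow(env), attr(d, "Size"))
  if (n_perm < 99) stop_config("n_perm must be >= 99")
  num <- env[vapply(env, is.numeric, TRUE)]
  if (ncol(num) > 1) {
    qr_ <- qr(scale(as.matrix(num), scale = FALSE))
    if (qr_$rank < ncol(num)) {
      drop <- colnames(num)[qr_$pivot[(qr_$rank + 1):ncol(num)]]
      stop_data("collinear environmental column(s): %s", paste(drop, collapse = ", "))
    }
  }
  mod <- vegan::capscale(d ~ ., data = env)
  eig_c <- mod$CCA$eig
  eig_u <- mod$CA$eig
  cf <- sum(eig_c) / (sum(eig_c) + sum(eig_u[eig_u > 0]))
  set.seed(seed, kind = "Mersenne-Twister")
  ov <- stats::anova(mod, permutations = n_perm)
  if (margin) {
    set.seed(seed, kind = "Mersenne-Twister")
    mg <- stats::anova(mod, by = "margin", permutations = n_perm)
    terms_df <- data.frame(term = rownames(mg), pseudo_F = mg$F,
                           p = mg$`Pr(>F)`, stringsAsFactors = FALSE)
    terms_df <- terms_df[!is.na(terms_df$pseudo_F), , drop = FALSE]
  } else {
    terms_df <- data.frame(term = character(), pseudo_F = numeric(),
                           p = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(constrained_fraction = cf,
                 overall = list(pseudo_F = ov$F[1], p = ov$`Pr(>F)`[1]),
                 term_tests = terms_df,
                 scores = vegan::scores(mod, display = "sites"),
                 eigenvalues = list(constrained = eig_c, unconstrained = eig_u),
                 model = mod),
            class = "db_rda_result")
}

#' @export
print.db_rda_result <- function(x, ...) {
  cat(sprintf("db-RDA: constrained fraction %.2f%% (overall P = %.4g)\n",
              100 * x$constrained_fraction, x$overall$p))
  if (nrow(x$term_tests)) {
    cat("Marginal term tests:\n")
    print(x$term_tests, row.names = FALSE)
  }
  invisible(x)
}

#' PERMANOVA with optional Bonferroni pairwise comparisons
#'
#' Permutational multivariate ANOVA on a distance matrix via
#' [vegan::adonis2()] (distance-partitioning pseudo-F, unrestricted
#' permutations, `p = (1 + #{null >= observed}) / (1 + n_perm)`). With
#' `pairwise = TRUE`, the first grouping factor's group pairs are each
#' re-tested on the corresponding sub-matrix and the pairwise p-values are
#' multiplied by the number of comparisons, capped at 1.
#'
#' @param d A `dist` object.
#' @param groups Factor/character vector, or data frame of grouping factors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param pairwise Also run Bonferroni-corrected pairwise tests.
#' @return Object of class `permanova_result`: `overall` data frame (term,
#'   df, pseudo-F, R2, p) and, when requested, `pairwise` data frame.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, pairwise = FALSE) {
  d <- stats::as.dist(d)
  if (!is.data.frame(groups)) groups <- data.frame(group = groups)
  groups <- as.data.frame(lapply(groups, as.factor))
  if (nrow(groups) != attr(d, "Size"))
    stop_data("groups rows (%d) do not match distance size (%d)",
              nrow(groups), attr(d, "Size"))
  for (col in names(groups)) {
    sizes <- table(groups[[col]])
    if (length(sizes) < 2L) stop_data("factor '%s' has fewer than 2 groups", col)
    if (any(sizes < 2L)) {
      stop_data("factor '%s' has group(s) of size 1: %s", col,
                paste(names(sizes)[sizes < 2], collapse = ", "))
    }
  }
  set.seed(seed, kind = "Mersenne-Twister")
  fit <- vegan::adonis2(d ~ ., data = groups, permutations = n_perm, by = "terms")
  keep <- !rownames(fit) %in% c("Residual", "Total")
  overall <- data.frame(term = rownames(fit)[keep], df = fit$Df[keep],
                        pseudo_F = fit$F[keep], R2 = fit$R2[keep],
                        p = fit$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  out <- list(overall = overall, pairwise = NULL)
  if (pairwise) {
    g <- groups[[1L]]
    lev <- levels(droplevels(g))
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    m <- as.matrix(d)
    rows <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      idx <- which(g %in% pr)
      sub <- stats::as.dist(m[idx, idx])
      set.seed(derive_seed(seed, i), kind = "Mersenne-Twister")
      f <- vegan::adonis2(sub ~ grp,
                          data = data.frame(grp = droplevels(g[idx])),
                          permutations = n_perm)
      data.frame(group1 = pr[1], group2 = pr[2], pseudo_F = f$F[1],
                 p_raw = f$`Pr(>F)`[1],
                 p_bonferroni = min(1, f$`Pr(>F)`[1] * length(pairs)),
                 stringsAsFactors = FALSE)
    })
    out$pairwise <- do.call(rbind, rows)
  }
  structure(out, class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA:\n")
  print(x$overall, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise comparisons (Bonferroni-corrected):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Principal component analysis of standardized variables
#'
#' Thin utility over [stats::prcomp()] with centering and scaling, for
#' geochemistry overview plots.
#'
#' @param table Numeric samples x variables data frame or matrix.
#' @return A `prcomp` object.
#' @export
pca_standardized <- function(table) {
  stats::prcomp(as.matrix(table), center = TRUE, scale. = TRUE)
}
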