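# Rank statistics and the multiple-regression / AICc model-selection
# machinery used for attributing MeHg variability to guild abundances and
# geochemistry.

#' Spearman rank correlation with t-approximation p-value
#'
#' Pairs with a missing value in either vector are dropped; at least four
#' complete pairs are required. `rho` is the Pearson correlation of midranks;
#' the two-sided p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_data("need >= 4 complete pairs, got %d", n)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-sample and k-sample rank tests
#'
#' `mann_whitney` runs the two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#' with the normal approximation and tie correction; `kruskal_wallis` runs
#' the Kruskal-Wallis chi-square test with tie correction. Both delegate to
#' the standard implementations in \pkg{stats}.
#'
#' @param groups List of numeric vectors (exactly 2 for `mann_whitney`,
#'   2 or more for `kruskal_wallis`).
#' @param kind `"mann_whitney"` or `"kruskal_wallis"`.
#' @return List with `statistic`, `p`.
#' @export
rank_tests <- function(groups, kind = c("mann_whitney", "kruskal_wallis")) {
  kind <- match.arg(kind)
  if (any(!lengths(groups))) stop_data("empty group supplied")
  if (kind == "mann_whitney") {
    if (length(groups) != 2L) stop_domain("mann_whitney needs exactly 2 groups")
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              exact = FALSE, correct = FALSE))
  } else {
    if (length(groups) < 2L) stop_domain("kruskal_wallis needs >= 2 groups")
    ht <- stats::kruskal.test(groups)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]; input order is preserved and
#' adjusted values are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_domain("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Specify a candidate regression model
#'
#' @param name Model name.
#' @param response Response column name.
#' @param terms Character vector of terms: main effects (column names),
#'   interactions as `"a:b"` (which also implies nothing about main effects —
#'   list them explicitly), and categorical covariates (e.g. `"site"`,
#'   `"compartment"`). `character(0)` gives the intercept-only model.
#' @param standardize Z-score the response's continuous predictors before
#'   fitting (default `TRUE`); categorical covariates are left as factors.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, response, terms, standardize = TRUE) {
  if (anyDuplicated(terms)) stop_config("model '%s' has duplicate terms", name)
  structure(list(name = name, response = response, terms = terms,
                 standardize = standardize), class = "model_spec")
}

# columns referenced by a spec (interaction terms split on ':')
.spec_columns <- function(spec) {
  unique(c(spec$response, unlist(strsplit(spec$terms, ":", fixed = TRUE))))
}

#' The default seven-model candidate family
#'
#' Spans the hypotheses about MeHg drivers tested by AICc selection:
#' (1) intercept-only; (2) F1Hg; (3) hgcA_total; (4) F1Hg + hgcA_total;
#' (5) F1Hg + hgcA_total + site + compartment; (6) the F1Hg x hgcA_total
#' interaction model; (7) the interaction model with site and compartment.
#' Replaceable with any list of [model_spec()]s.
#'
#' @param response Response column (default `"MeHg"`).
#' @param standardize Passed to each [model_spec()].
#' @return Named list of seven `model_spec`s.
#' @export
seven_model_family <- function(response = "MeHg", standardize = TRUE) {
  mk <- function(name, terms) model_spec(name, response, terms, standardize)
  list(
    null = mk("null", character(0)),
    f1 = mk("f1", "F1Hg"),
    hgca = mk("hgca", "hgcA_total"),
    additive = mk("additive", c("F1Hg", "hgcA_total")),
    additive_design = mk("additive_design",
                         c("F1Hg", "hgcA_total", "site", "compartment")),
    interaction = mk("interaction", c("F1Hg", "hgcA_total", "F1Hg:hgcA_total")),
    interaction_design = mk("interaction_design",
                            c("F1Hg", "hgcA_total", "F1Hg:hgcA_total",
                              "site", "compartment"))
  )
}

#' Fit one candidate model by ordinary least squares
#'
#' Categorical covariates are expanded to treatment contrasts with the first
#' level alphabetically as reference. With `standardize`, continuous
#' predictors are z-scored before fitting (so coefficients are per-SD);
#' `scale_response` additionally z-scores the response. The log-likelihood is
#' Gaussian at the MLE variance, and `k` counts the intercept, slopes, and
#' the error variance.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing all referenced columns.
#' @param scale_response Also z-score the response (default `FALSE`).
#' @return List with `name`, `coefficients` (data frame term/estimate/se/t/p),
#'   `loglik`, `k`, `n`, `r_squared`, `adj_r_squared`, `sigma`, `fit`.
#' @export
fit_ols <- function(spec, data, scale_response = FALSE) {
  cols <- .spec_columns(spec)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_schema("model '%s' references absent column(s): %s", spec$name,
                paste(missing, collapse = ", "))
  }
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  for (col in cols) {
    if (is.character(df[[col]])) df[[col]] <- factor(df[[col]], levels = sort(unique(df[[col]])))
  }
  if (spec$standardize) {
    for (col in setdiff(cols, spec$response)) {
      if (is.numeric(df[[col]])) df[[col]] <- zscore(df[[col]], col)
    }
  }
  if (scale_response) df[[spec$response]] <- zscore(df[[spec$response]], spec$response)
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(spec$response, "~", rhs))
  fit <- stats::lm(form, data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    alias <- colnames(stats::model.matrix(fit))[is.na(stats::coef(fit))]
    stop_data("model '%s' has a rank-deficient design; collinear term(s): %s",
              spec$name, paste(alias, collapse = ", "))
  }
  n <- nrow(df)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")  # slopes + intercept + error variance
  if (n <= k - 1L) stop_data("model '%s': n (%d) must exceed parameter count", spec$name, n)
  ct <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(name = spec$name, coefficients = coefs, loglik = ll, k = k, n = n,
       r_squared = summary(fit)$r.squared,
       adj_r_squared = summary(fit)$adj.r.squared,
       sigma = sqrt(sum(stats::residuals(fit)^2) / n), fit = fit)
}

.aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc model selection over a candidate family
#'
#' All candidates are fitted to the same complete-case rows (the
#' intersection over every model's columns), so AICc values are comparable.
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k` counting the error
#' variance. Reports per-model coefficients, AICc, ΔAICc, and Akaike
#' weights, residual-normality (Shapiro-Wilk) and heteroscedasticity
#' (Breusch-Pagan) diagnostics, and flags model pairs where adding an
#' interaction term raises AICc by >= 2 ("interaction adds nothing").
#'
#' @param specs List of [model_spec()]s.
#' @param data Data frame.
#' @param scale_response Passed to [fit_ols()].
#' @return Object of class `aicc_selection`: list with `table` (data frame
#'   `model`, `k`, `n`, `loglik`, `AICc`, `delta_AICc`, `weight`), `best`,
#'   `fits`, `diagnostics`, `interaction_report`.
#' @export
aicc_select <- function(specs, data, scale_response = FALSE) {
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- vapply(specs, `[[`, "", "name")
  all_cols <- unique(unlist(lapply(specs, .spec_columns)))
  missing <- setdiff(all_cols, names(data))
  if (length(missing)) {
    stop_schema("candidate family references absent column(s): %s",
                paste(missing, collapse = ", "))
  }
  cc <- data[stats::complete.cases(data[all_cols]), , drop = FALSE]
  fits <- lapply(specs, fit_ols, data = cc, scale_response = scale_response)
  n <- fits[[1]]$n
  k <- vapply(fits, `[[`, 0, "k")
  bad <- which(n - k - 1 <= 0)
  if (length(bad)) {
    stop_data("AICc undefined (n - k - 1 <= 0) for model(s): %s",
              paste(names(fits)[bad], collapse = ", "))
  }
  ll <- vapply(fits, `[[`, 0, "loglik")
  aicc <- mapply(.aicc, ll, k, n)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(model = names(fits), k = k, n = n, loglik = ll,
                    AICc = aicc, delta_AICc = delta, weight = w,
                    row.names = NULL, stringsAsFactors = FALSE)
  diagnostics <- do.call(rbind, lapply(fits, function(f) {
    res <- stats::residuals(f$fit)
    sw <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
      stats::shapiro.test(res)$p.value else NA_real_
    bp <- if (length(stats::coef(f$fit)) > 1)
      tryCatch(lmtest::bptest(f$fit)$p.value, error = function(e) NA_real_)
      else NA_real_
    data.frame(model = f$name, shapiro_p = sw, bp_p = unname(bp),
               stringsAsFactors = FALSE)
  }))
  rownames(diagnostics) <- NULL
  # model pairs differing by exactly one interaction term
  inter <- list()
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    extra <- setdiff(specs[[j]]$terms, specs[[i]]$terms)
    if (length(extra) == 1L && grepl(":", extra, fixed = TRUE) &&
        all(specs[[i]]$terms %in% specs[[j]]$terms)) {
      d <- aicc[j] - aicc[i]
      inter[[length(inter) + 1L]] <- data.frame(
        base = names(specs)[i], with_interaction = names(specs)[j],
        interaction = extra, delta_AICc = d, adds_nothing = d >= 2,
        stringsAsFactors = FALSE)
    }
  }
  interaction_report <- if (length(inter)) do.call(rbind, inter) else NULL
  structure(list(table = tab[order(tab$AICc), ], best = names(fits)[which.min(aicc)],
                 fits = fits, diagnostics = diagnostics,
                 interaction_report = interaction_report),
            class = "aicc_selection")
}

#' @export
print.aicc_selection <- function(x, ...) {
  cat("AICc model selection (", nrow(x$table), " candidates, n = ",
      x$table$n[1], ")\n\n", sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$AICc <- round(tab$AICc, 2)
  tab$delta_AICc <- round(tab$delta_AICc, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
  cat("\nBest model:", x$best, "\n")
  if (!is.null(x$interaction_report) && any(x$interaction_report$adds_nothing)) {
    r <- x$interaction_report[x$interaction_report$adds_nothing, ]
    for (i in seq_len(nrow(r))) {
      cat(sprintf("Note: adding %s to '%s' raises AICc by %.1f (no improvement)\n",
                  r$interaction[i], r$base[i], r$delta_AICc[i]))
    }
  }
  invisible(x)
}

#' @method summary aicc_selection
#' @export
summary.aicc_selection <- function(object, ...) {
  best <- object$fits[[object$best]]
  cat("Best model:", object$best, "\n")
  print(best$coefficients, row.names = FALSE)
  cat(sprintf("R-squared %.3f (adjusted %.3f)\n",
              best$r_squared, best$adj_r_squared))
  invisible(object)
}
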