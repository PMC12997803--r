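# Random-forest attribution protocol: repeated seeded 70/30 train/test
# splits, out-of-bag permutation importance (%IncMSE), per-split
# response-permutation significance tests, and aggregation into per-variable
# significance rates. The forest learner is randomForest; the protocol
# around it is implemented here.

#' Random-forest protocol configuration
#'
#' Defaults mirror the study protocol: 2001 trees, `mtry = 4`, 100 random
#' 70/30 train/test splits. Per-split variable significance uses
#' response-permutation null forests (the response is permuted within the
#' training rows and the forest refitted); null forests may be smaller than
#' the main forest for tractability (`null_trees`).
#'
#' @param n_trees Trees per main forest (default 2001).
#' @param mtry Variables tried per split (default 4).
#' @param n_splits Number of train/test splits (default 100).
#' @param train_fraction Fraction of rows used for training (default 0.7).
#' @param n_null_perms Response permutations per split for significance
#'   (default 100; 0 disables significance testing).
#' @param null_trees Trees per null forest (default 501).
#' @param alpha Per-split significance level (default 0.05).
#' @param seed Protocol seed; split `i`, permutation `j` uses
#'   `derive_seed(seed, i, j)`, so any single split is reproducible alone.
#' @param predictors Optional ordered predictor subset (default: all
#'   feature columns).
#' @param subset Optional logical row filter (e.g. flooded samples only).
#' @param scale_importance Use the standard-error-scaled %IncMSE convention
#'   (default `TRUE`); `FALSE` gives the unscaled mean MSE increase.
#' @return List of class `rf_protocol_config`.
#' @export
rf_protocol_config <- function(n_trees = 2001, mtry = 4, n_splits = 100,
                               train_fraction = 0.7, n_null_perms = 100,
                               null_trees = 501, alpha = 0.05, seed = 1,
                               predictors = NULL, subset = NULL,
                               scale_importance = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie in (0, 1)")
  structure(list(n_trees = n_trees, mtry = mtry, n_splits = n_splits,
                 train_fraction = train_fraction, n_null_perms = n_null_perms,
                 null_trees = null_trees, alpha = alpha, seed = seed,
                 predictors = predictors, subset = subset,
                 scale_importance = scale_importance),
            class = "rf_protocol_config")
}

#' Build the predictor table for RF attribution
#'
#' Inner join of the guild-abundance table and the geochemistry panel on
#' `sample_id`, plus elementwise product columns for the requested
#' interactions (named `a_x_b`). The default predictor set in downstream
#' runs is 12 columns: nine functional-guild columns (including the
#' methanogen x methanotroph product) and three geochemical columns.
#'
#' @param guilds Guild-abundance data frame with `sample_id`.
#' @param geochem Geochemistry data frame with `sample_id`.
#' @param interactions List of character pairs to turn into product columns
#'   (default: methanogen x methanotroph).
#' @param standardize Z-score the paired columns before multiplying
#'   (default `TRUE`), so a product column is large when both members
#'   deviate in the same direction and negative when they diverge — the
#'   usual interaction reading. With `FALSE` the raw elementwise product is
#'   used. Tree models are invariant to monotone rescaling of single
#'   columns, so only the product columns are affected.
#' @return Data frame keyed by `sample_id`.
#' @export
build_feature_table <- function(guilds, geochem,
                                interactions = list(c("methanogen", "methanotroph")),
                                standardize = TRUE) {
  joined <- merge(guilds, geochem, by = "sample_id", sort = FALSE)
  dropped <- (nrow(guilds) - nrow(joined)) + (nrow(geochem) - nrow(joined))
  if (dropped > 0) {
    log_msg("info", "build_feature_table: dropped %d sample(s) absent from one table",
            dropped)
  }
  for (pair in interactions) {
    missing <- setdiff(pair, names(joined))
    if (length(missing)) {
      stop_schema("interaction pair (%s) references absent column(s): %s",
                  paste(pair, collapse = ", "), paste(missing, collapse = ", "))
    }
    a <- joined[[pair[1]]]
    b <- joined[[pair[2]]]
    if (standardize) {
      a <- zscore(a, pair[1])
      b <- zscore(b, pair[2])
    }
    joined[[paste(pair, collapse = "_x_")]] <- a * b
  }
  joined
}

.default_rf_predictors <- c("methanogen", "methanotroph",
                            "methanogen_x_methanotroph", "hgcA_total",
                            "hgcA_methanogen", "dsrA_SRB", "IRB", "merB",
                            "mbnT_demethylator", "F1Hg", "DOM", "SUVA254")

.split_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  c(rmse = sqrt(mean((obs - pred)^2)),
    mae = mean(abs(obs - pred)),
    r2 = 1 - ss_res / ss_tot,
    pearson_r = if (stats::sd(pred) > 0) stats::cor(obs, pred) else NA_real_)
}

#' Run the repeated-split RF attribution protocol
#'
#' For each of `n_splits` seeded 70/30 splits: fit a forest on the training
#' rows, record held-out RMSE, MAE, R², and Pearson r, and take each
#' variable's %IncMSE (mean over trees of the out-of-bag MSE increase after
#' within-OOB permutation of that variable, scaled by its standard error
#' over trees unless `scale_importance = FALSE`). Per-variable split
#' significance compares the observed importance with `n_null_perms` null
#' importances from forests refitted on the training response permuted
#' within the training rows: `p = (1 + #{null >= obs}) / (1 + n_null_perms)`.
#' Across splits, each variable gets its mean %IncMSE with a 95% t-interval,
#' its significance rate (fraction of splits with `p < alpha`), and its mean
#' p-value.
#'
#' @param features Feature data frame (see [build_feature_table()]).
#' @param response Response column name (e.g. `"MeHg"`).
#' @param cfg An [rf_protocol_config()].
#' @return Object of class `rf_attribution`: `splits` (per-split metric data
#'   frame), `importance` (per-variable summary), `importance_matrix`
#'   (splits x variables), `pvalue_matrix`, `config`, `n`.
#' @export
run_rf_protocol <- function(features, response, cfg = rf_protocol_config()) {
  if (!response %in% names(features)) {
    stop_schema("response column '%s' not in features", response)
  }
  predictors <- cfg$predictors %||%
    setdiff(names(features), c(response, "sample_id"))
  missing <- setdiff(predictors, names(features))
  if (length(missing)) {
    stop_schema("predictor column(s) absent: %s", paste(missing, collapse = ", "))
  }
  df <- features[, c(response, predictors), drop = FALSE]
  if (!is.null(cfg$subset)) df <- df[cfg$subset, , drop = FALSE]
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    log_msg("info", "run_rf_protocol: dropped %d incomplete row(s)", sum(!cc))
    df <- df[cc, , drop = FALSE]
  }
  n <- nrow(df)
  y <- df[[response]]
  X <- df[, predictors, drop = FALSE]
  if (stats::sd(y) == 0) stop_data("response is constant")
  if (cfg$mtry > length(predictors)) {
    stop_config("mtry (%d) exceeds number of predictors (%d)",
                cfg$mtry, length(predictors))
  }
  n_train <- round(cfg$train_fraction * n)
  if (n_train <= 10) stop_data("training set too small (%d rows)", n_train)

  imp_of <- function(rf, scale) {
    randomForest::importance(rf, type = 1, scale = scale)[, 1L]
  }
  n_var <- length(predictors)
  imp_mat <- matrix(NA_real_, cfg$n_splits, n_var,
                    dimnames = list(NULL, predictors))
  p_mat <- matrix(NA_real_, cfg$n_splits, n_var,
                  dimnames = list(NULL, predictors))
  metrics <- matrix(NA_real_, cfg$n_splits, 4,
                    dimnames = list(NULL, c("rmse", "mae", "r2", "pearson_r")))
  for (i in seq_len(cfg$n_splits)) {
    obs_raw <- NULL
    tr <- NULL
    with_seed(derive_seed(cfg$seed, i, 0), {
      tr <- sample.int(n, n_train)
      rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                       ntree = cfg$n_trees, mtry = cfg$mtry,
                                       importance = TRUE)
      pred <- stats::predict(rf, X[-tr, , drop = FALSE])
      metrics[i, ] <- .split_metrics(y[-tr], pred)
      imp_mat[i, ] <- imp_of(rf, cfg$scale_importance)
      # the permutation-null comparison uses the unscaled MSE increase:
      # the SE-scaled statistic grows with tree count, so null forests of a
      # different size would bias the test
      obs_raw <- imp_of(rf, FALSE)
    })
    if (cfg$n_null_perms > 0) {
      null_imp <- matrix(NA_real_, cfg$n_null_perms, n_var)
      for (j in seq_len(cfg$n_null_perms)) {
        with_seed(derive_seed(cfg$seed, i, j), {
          y_perm <- sample(y[tr])
          rf0 <- randomForest::randomForest(X[tr, , drop = FALSE], y_perm,
                                            ntree = cfg$null_trees,
                                            mtry = cfg$mtry, importance = TRUE)
          null_imp[j, ] <- imp_of(rf0, FALSE)
        })
      }
      p_mat[i, ] <- (1 + colSums(null_imp >= rep(obs_raw, each = cfg$n_null_perms))) /
        (1 + cfg$n_null_perms)
    }
  }
  mean_imp <- colMeans(imp_mat)
  se_imp <- apply(imp_mat, 2, stats::sd) / sqrt(cfg$n_splits)
  tcrit <- stats::qt(0.975, df = max(cfg$n_splits - 1, 1))
  importance <- data.frame(
    variable = predictors,
    mean_incmse = mean_imp,
    ci_lo = mean_imp - tcrit * se_imp,
    ci_hi = mean_imp + tcrit * se_imp,
    significance_rate = if (cfg$n_null_perms > 0)
      colMeans(p_mat < cfg$alpha) else NA_real_,
    mean_p = if (cfg$n_null_perms > 0) colMeans(p_mat) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(splits = as.data.frame(metrics), importance = importance,
                 importance_matrix = imp_mat, pvalue_matrix = p_mat,
                 config = cfg, n = n),
            class = "rf_attribution")
}

#' Rank predictors by mean %IncMSE
#'
#' Descending mean %IncMSE; ties broken by significance rate (descending),
#' then variable name.
#'
#' @param result An `rf_attribution` object.
#' @return The `importance` data frame, ranked, with a `rank` column.
#' @export
rank_variables <- function(result) {
  imp <- result$importance
  sig <- imp$significance_rate
  sig[is.na(sig)] <- 0
  ord <- order(-imp$mean_incmse, -sig, imp$variable)
  out <- imp[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.rf_attribution <- function(x, ...) {
  cat(sprintf("RF attribution: %d splits, n = %d, %d predictors\n",
              nrow(x$splits), x$n, ncol(x$importance_matrix)))
  m <- colMeans(x$splits, na.rm = TRUE)
  cat(sprintf("Mean test performance: R² = %.3f, RMSE = %.3f, MAE = %.3f, r = %.3f\n",
              m["r2"], m["rmse"], m["mae"], m["pearson_r"]))
  cat("\nVariable importance (ranked):\n")
  tab <- rank_variables(x)
  tab$mean_incmse <- round(tab$mean_incmse, 2)
  tab$ci_lo <- round(tab$ci_lo, 2)
  tab$ci_hi <- round(tab$ci_hi, 2)
  tab$mean_p <- round(tab$mean_p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
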