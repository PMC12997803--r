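test_that("spearman_cor matches the midrank oracle, including ties", {
  expect_equal(spearman_cor(1:4 * 1.0, c(10, 20, 30, 45) * 1.0)$rho, 1)
  expect_equal(spearman_cor(1:4 * 1.0, c(30, 20, 10, 5))$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(x, y)$rho, hand_spearman(x, y), tolerance = 1e-12)
  # invariance to strictly monotone transforms
  expect_equal(spearman_cor(exp(x), y^3)$rho, spearman_cor(x, y)$rho,
               tolerance = 1e-12)
  # missing pairs are dropped, n reported
  res <- spearman_cor(c(x, NA), c(y, 1))
  expect_identical(res$n, 4L)
  expect_error(spearman_cor(1:3 * 1.0, 3:1 * 1.0), class = "paddyMeHg_data_error")
})

test_that("rank tests match brute-force rank computations", {
  # identical groups: no separation
  g <- list(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(rank_tests(g, "mann_whitney")$p, 0.99)
  # complete separation of two groups of 10: U at its extreme (0 or 100)
  sep <- list(as.numeric(1:10), as.numeric(101:110))
  expect_true(rank_tests(sep, "mann_whitney")$statistic %in% c(0, 100))
  # 3-group toy equals the hand rank formula (with tie correction)
  toy <- list(c(1, 5, 8), c(2, 2, 9), c(4, 7, 7, 10))
  expect_equal(rank_tests(toy, "kruskal_wallis")$statistic, hand_kruskal(toy),
               tolerance = 1e-12)
  expect_error(rank_tests(list(1:3, numeric()), "mann_whitney"),
               class = "paddyMeHg_data_error")
})

test_that("bh_fdr applies the step-up rule and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(0.2), 0.2)
  p <- c(0.4, 0.01, 0.9, 0.02, 0.05)
  expect_equal(bh_fdr(p), hand_bh(p), tolerance = 1e-15)
  expect_error(bh_fdr(c(0.1, 1.2)), class = "paddyMeHg_domain_error")
})

test_that("fit_ols recovers exact linear structure and the Gaussian loglik", {
  d <- data.frame(y = 2 * (1:10), x = as.numeric(1:10))
  # summary.lm warns about the deliberately perfect fit
  f <- suppressWarnings(fit_ols(model_spec("m", "y", "x", standardize = FALSE), d))
  expect_equal(f$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # intercept-only loglik equals the closed form
  d2 <- data.frame(y = c(1.2, 3.4, 2.2, 5.1, 4.4))
  f2 <- fit_ols(model_spec("null", "y", character(0)), d2)
  expect_equal(f2$loglik, hand_loglik(d2$y - mean(d2$y)), tolerance = 1e-10)
  expect_equal(f2$k, 2)
  # collinear designs error with the offending term
  d3 <- data.frame(y = rnorm(8), a = 1:8, b = 2 * (1:8))
  expect_error(fit_ols(model_spec("c", "y", c("a", "b"), standardize = FALSE), d3),
               class = "paddyMeHg_data_error")
})

test_that("standardized fits recover the generative F1-Hg coefficient", {
  ok <- vapply(1:50, function(s) {
    p <- make_panel(sim_config(seed = s, preset = "dominant_f1",
                               beta_methanogen = 0, noise_sd = 0.15))
    f <- fit_ols(model_spec("f1", "MeHg", "F1Hg", standardize = TRUE),
                 p$geochem)
    abs(f$coefficients$estimate[2] - 0.73) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("AICc selection obeys its formula and flags useless interactions", {
  # hand-checked AICc on a 6-point, 1-predictor toy
  d <- data.frame(y = c(1.1, 2.3, 2.9, 4.2, 4.8, 6.3), x = as.numeric(1:6))
  sel <- aicc_select(list(m = model_spec("m", "y", "x", standardize = FALSE)), d)
  f <- stats::lm(y ~ x, d)
  expect_equal(sel$table$AICc,
               hand_aicc(hand_loglik(stats::residuals(f)), k = 3, n = 6),
               tolerance = 1e-10)
  # two identical specs: identical AICc, both deltas 0
  sel2 <- aicc_select(list(a = model_spec("a", "y", "x"),
                           b = model_spec("b", "y", "x")), d)
  expect_equal(sel2$table$delta_AICc, c(0, 0), tolerance = 1e-12)
  expect_equal(sum(sel2$table$weight), 1, tolerance = 1e-9)
  # interaction report on simulated data with no interaction effect
  p <- make_panel(sim_config(seed = 3, preset = "model5"))
  dat <- merge(merge(p$geochem, p$guilds, by = "sample_id"), p$meta,
               by = "sample_id")
  sel3 <- aicc_select(seven_model_family(), dat)
  expect_true(all(sel3$table$delta_AICc >= 0))
  expect_equal(sum(sel3$table$weight), 1, tolerance = 1e-9)
  ir <- sel3$interaction_report
  expect_true(!is.null(ir) && nrow(ir) >= 1)
})

test_that("n - k - 1 <= 0 is rejected by model name", {
  d <- data.frame(y = c(1, 2, 3.5), x = c(1, 2, 3))
  expect_error(aicc_select(list(tiny = model_spec("tiny", "y", "x")), d),
               "tiny", class = "paddyMeHg_data_error")
})

test_that("null-generator selection is not pathologically optimistic", {
  # under a no-effect generator, non-null models rarely beat the null by > 2
  beats <- vapply(1:40, function(s) {
    p <- make_panel(sim_config(seed = s, preset = "null"))
    dat <- merge(merge(p$geochem, p$guilds, by = "sample_id"), p$meta,
                 by = "sample_id")
    sel <- aicc_select(seven_model_family(), dat)
    tab <- sel$table
    tab$AICc[tab$model == "null"] - min(tab$AICc) > 2
  }, TRUE)
  expect_lt(mean(beats), 0.3)
})
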