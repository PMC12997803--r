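test_that("feature table joins and builds interaction products", {
  guilds <- data.frame(sample_id = c("s1", "s2", "s3"),
                       methanogen = c(1, 2, 5), methanotroph = c(3, 4, 6))
  geochem <- data.frame(sample_id = c("s1", "s2"), F1Hg = c(10, 20))
  ft <- build_feature_table(guilds, geochem, standardize = FALSE)
  # inner join drops s3; product column is elementwise
  expect_identical(ft$sample_id, c("s1", "s2"))
  expect_equal(ft$methanogen_x_methanotroph, c(3, 8))
  # standardized products are centered-deviation products
  fts <- build_feature_table(guilds, geochem)
  a <- (c(1, 2) - 1.5) / stats::sd(c(1, 2))
  b <- (c(3, 4) - 3.5) / stats::sd(c(3, 4))
  expect_equal(fts$methanogen_x_methanotroph, a * b, tolerance = 1e-12)
  # empty interaction list leaves the join untouched
  ft0 <- build_feature_table(guilds, geochem, interactions = list())
  expect_identical(names(ft0), c("sample_id", "methanogen", "methanotroph", "F1Hg"))
  expect_error(build_feature_table(guilds, geochem, list(c("methanogen", "nope"))),
               "nope", class = "paddyMeHg_schema_error")
})

test_that("protocol finds an exactly predictive variable and is reproducible", {
  set.seed(3)
  n <- 200
  feats <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
  feats$y <- feats$A
  cfg <- rf_protocol_config(n_trees = 301, mtry = 2, n_splits = 10,
                            n_null_perms = 30, null_trees = 301, seed = 17)
  res <- run_rf_protocol(feats, "y", cfg)
  ranked <- rank_variables(res)
  expect_identical(ranked$variable[1], "A")
  expect_equal(ranked$significance_rate[1], 1)
  expect_gte(mean(res$splits$r2), 0.9)
  # bit-identical rerun under the same config seed
  res2 <- run_rf_protocol(feats, "y", cfg)
  expect_identical(res$importance, res2$importance)
  expect_identical(res$splits, res2$splits)
  # CIs contain the means
  expect_true(all(res$importance$ci_lo <= res$importance$mean_incmse &
                    res$importance$mean_incmse <= res$importance$ci_hi))
})

test_that("protocol rejects degenerate inputs", {
  feats <- data.frame(A = rnorm(40), B = rnorm(40), y = 1)
  expect_error(run_rf_protocol(feats, "y", rf_protocol_config(mtry = 2, n_splits = 2)),
               "constant", class = "paddyMeHg_data_error")
  feats$y <- rnorm(40)
  expect_error(run_rf_protocol(feats, "y",
                               rf_protocol_config(mtry = 5, n_splits = 2)),
               "mtry", class = "paddyMeHg_config_error")
  expect_error(run_rf_protocol(feats, "z", rf_protocol_config()),
               class = "paddyMeHg_schema_error")
})

test_that("tied importances rank adjacently with a deterministic break", {
  imp <- data.frame(variable = c("b", "a", "c"),
                    mean_incmse = c(1, 1, 5),
                    ci_lo = 0, ci_hi = 2,
                    significance_rate = c(0.5, 0.5, 1), mean_p = 0.1,
                    stringsAsFactors = FALSE)
  fake <- structure(list(importance = imp), class = "rf_attribution")
  ranked <- rank_variables(fake)
  expect_identical(ranked$variable, c("c", "a", "b"))
  one <- rank_variables(structure(list(importance = imp[3, ]),
                                  class = "rf_attribution"))
  expect_identical(one$rank, 1L)
})
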