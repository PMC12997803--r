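test_that("bray_curtis matches the direct formula and its invariances", {
  m <- rbind(a = c(2, 1), b = c(1, 1), c = c(2, 1))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.2, tolerance = 1e-12)   # (|2-1|+0)/(3+2)
  expect_equal(d["a", "c"], 0, tolerance = 1e-12)
  expect_equal(d["a", "b"], d["b", "a"], tolerance = 1e-15)
  # disjoint communities are maximally dissimilar
  dj <- as.matrix(bray_curtis(rbind(c(1, 0), c(0, 1))))
  expect_equal(dj[1, 2], 1, tolerance = 1e-12)
  # taxon column order and all-zero taxa do not matter
  expect_equal(as.matrix(bray_curtis(m[, c(2, 1)])), d, tolerance = 1e-15)
  expect_equal(as.matrix(bray_curtis(cbind(m, 0))), d, tolerance = 1e-15)
  expect_error(bray_curtis(rbind(c(1, -1), c(1, 1))), class = "paddyMeHg_domain_error")
  expect_error(bray_curtis(rbind(z = c(0, 0), c(1, 1))), "z",
               class = "paddyMeHg_data_error")
})

test_that("pcoa reproduces closed forms and Euclidean round-trips", {
  # three equidistant points: two equal positive eigenvalues (regular simplex)
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  p3 <- pcoa(d3)
  expect_identical(length(p3$eigenvalues), 2L)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-9)
  # all-zero distances: nothing retained
  p0 <- pcoa(stats::as.dist(matrix(0, 4, 4)))
  expect_identical(length(p0$eigenvalues), 0L)
  # Euclidean distances are reproduced exactly by the embedding
  set.seed(11)
  xy <- matrix(rnorm(20), 10, 2)
  emb <- pcoa(stats::dist(xy))
  expect_equal(as.matrix(stats::dist(emb$points)),
               as.matrix(stats::dist(xy)), tolerance = 1e-9)
  expect_error(pcoa(stats::dist(matrix(rnorm(4), 2))), class = "paddyMeHg_data_error")
})

test_that("db_rda detects a generating gradient and bounds its fraction", {
  set.seed(42)
  grad <- seq(0, 1, length.out = 20)
  comm <- cbind(10 * grad + 1, 10 * (1 - grad) + 1,
                matrix(runif(40, 0.5, 1.5), 20))
  d <- bray_curtis(comm)
  res <- db_rda(d, data.frame(grad = grad), n_perm = 199, seed = 3)
  expect_equal(res$overall$p, 1 / 200, tolerance = 1e-12)
  expect_gte(res$constrained_fraction, 0)
  expect_lte(res$constrained_fraction, 1)
  # collinear environment columns are named
  env2 <- data.frame(grad = grad, twice = 2 * grad)
  expect_error(db_rda(d, env2, n_perm = 199), "twice|grad",
               class = "paddyMeHg_data_error")
})

test_that("permanova separates translated clouds and corrects pairwise tests", {
  set.seed(7)
  x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 10, 10))
  d <- stats::dist(x)
  g <- rep(c("g1", "g2"), each = 10)
  res <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(res$overall$p, 1 / 200, tolerance = 1e-12)
  # relabeling group names leaves the test untouched
  res2 <- permanova(d, ifelse(g == "g1", "north", "south"), n_perm = 199, seed = 5)
  expect_equal(res$overall$pseudo_F, res2$overall$pseudo_F, tolerance = 1e-12)
  expect_equal(res$overall$p, res2$overall$p, tolerance = 1e-12)
  # pairwise Bonferroni: p multiplied by number of comparisons, capped at 1
  set.seed(8)
  x3 <- rbind(matrix(rnorm(16), 8), matrix(rnorm(16), 8), matrix(rnorm(16), 8))
  g3 <- rep(c("a", "b", "c"), each = 8)
  pr <- permanova(stats::dist(x3), g3, n_perm = 199, seed = 5, pairwise = TRUE)
  expect_identical(nrow(pr$pairwise), 3L)
  expect_equal(pr$pairwise$p_bonferroni,
               pmin(1, pr$pairwise$p_raw * 3), tolerance = 1e-12)
  expect_error(permanova(d, c("a", rep("b", 19)), n_perm = 99),
               class = "paddyMeHg_data_error")
})
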