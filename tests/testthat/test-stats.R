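test_that("signed-rank z follows the no-continuity-correction convention", {
  # all 7 differences positive, distinct magnitudes: W = 28, z = 14/sqrt(35)
  res <- wilcoxon_signed_rank_z(c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(res$statistic, 14 / sqrt(35), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 2.366)
  expect_equal(round(res$p, 3), 0.018)
  # n = 8, only the smallest-magnitude difference negative: W = 35
  res8 <- wilcoxon_signed_rank_z(c(-1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(res8$statistic, 17 / sqrt(51), tolerance = 1e-12)
  expect_equal(round(res8$statistic, 2), 2.38)
  # n = 7, one opposed
  res7 <- wilcoxon_signed_rank_z(c(-1, 2, 3, 4, 5, 6, 7))
  expect_equal(res7$statistic, 13 / sqrt(35), tolerance = 1e-12)
  expect_equal(round(res7$statistic, 3), 2.197)
})

test_that("signed-rank z is antisymmetric and zero for balanced signs", {
  d <- c(-3, -1, 1, 3, -2, 2)
  expect_equal(wilcoxon_signed_rank_z(d)$statistic, 0)
  set.seed(21)
  for (i in 1:10) {
    d <- rnorm(9)
    expect_equal(wilcoxon_signed_rank_z(-d)$statistic,
                 -wilcoxon_signed_rank_z(d)$statistic, tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank_z(rep(0, 8)), ">= 5 non-zero")
  expect_error(wilcoxon_signed_rank_z(c(1, 2, 3, 0)), ">= 5 non-zero")
})

test_that("z -> d chain reproduces every reference (z, n, d) triple", {
  triples <- list(
    list(z = 1.96, n = 8, d = 1.922),
    list(z = 2.028, n = 7, d = 2.387),
    list(z = 2.1, n = 8, d = 2.217),
    list(z = 2.197, n = 7, d = 2.981),
    list(z = 2.24, n = 8, d = 2.594),
    list(z = 2.366, n = 7, d = 3.996),
    list(z = 2.38, n = 8, d = 3.115))
  for (tr in triples) {
    expect_equal(cohens_d_from_z(tr$z, tr$n), tr$d, tolerance = 0.001)
    # d is a magnitude: sign of z does not change it
    expect_equal(cohens_d_from_z(-tr$z, tr$n), cohens_d_from_z(tr$z, tr$n))
  }
  expect_equal(cohens_d_from_z(0, 8), 0)
  # strictly increasing in |z| for fixed n
  zs <- seq(0, 2.6, by = 0.1)
  expect_true(all(diff(cohens_d_from_z(zs, 8)) > 0))
  expect_error(cohens_d_from_z(3, 8), "sqrt")
})

test_that("Kruskal-Wallis H and the Bonferroni post hoc behave canonically", {
  res <- kruskal_wallis_bonferroni(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                                   rep(c("a", "b", "c"), each = 3))
  expect_equal(res$omnibus$statistic, 7.2, tolerance = 1e-12)
  expect_equal(nrow(res$posthoc), 3)  # omnibus p = 0.027 opens the gate
  expect_equal(res$posthoc$p_adj, pmin(1, res$posthoc$p_raw * 3))

  same <- kruskal_wallis_bonferroni(rep(c(1, 2, 3), times = 3),
                                    rep(c("a", "b", "c"), each = 3))
  expect_equal(same$omnibus$statistic, 0)
  expect_equal(same$omnibus$p, 1)
  expect_equal(nrow(same$posthoc), 0)  # gate closed

  four <- kruskal_wallis_bonferroni(c(1:3, 11:13, 21:23, 31:33),
                                    rep(letters[1:4], each = 3))
  expect_equal(nrow(four$posthoc), 6)
  expect_equal(four$posthoc$p_adj, pmin(1, four$posthoc$p_raw * 6))
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(33)
  v <- rnorm(24)
  g <- rep(letters[1:4], each = 6)
  h0 <- kruskal_wallis_bonferroni(v, g)$omnibus$statistic
  expect_equal(kruskal_wallis_bonferroni(exp(v), g)$omnibus$statistic, h0)
  expect_equal(kruskal_wallis_bonferroni(v^3, g)$omnibus$statistic, h0)
})

test_that("Spearman interaction classifies by magnitude thresholds", {
  res <- spearman_interaction(1:10, (1:10)^2)
  expect_equal(res$statistic, 1)
  expect_equal(res$class, "strong")
  expect_equal(classify_correlation(0.45), "moderate")
  expect_equal(classify_correlation(-0.543), "strong")
  expect_equal(classify_correlation(0.29), "negligible")
  expect_equal(classify_correlation(-0.504), "strong")
  # invariance under monotone transforms of either margin
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- spearman_interaction(x, y)$statistic
  expect_equal(spearman_interaction(exp(x), y)$statistic, r0)
  expect_equal(spearman_interaction(x, y^3)$statistic, r0)
  expect_error(spearman_interaction(1:4, 1:5), "equal length")
  expect_error(spearman_interaction(1:5, 5:1), ">= 6")
})
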