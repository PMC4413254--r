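test_that("ensonified area is the cone base", {
  expect_equal(ensonified_area(9.1, 1), 0.0199, tolerance = 1e-3)
  expect_equal(ensonified_area(15.1, 1), 0.0552, tolerance = 1e-3)
  # quadratic in range
  expect_equal(ensonified_area(9.1, 2), 4 * ensonified_area(9.1, 1))
  expect_error(ensonified_area(0, 1))
  expect_error(ensonified_area(9, -1))
})

test_that("area ratios cancel range and match the tangent-squared form", {
  bw <- c(9.1, 9.1, 9.1, 15.1, 12)
  rng <- c(3, 2.5, 4, 0.8, 1.2)
  ratio <- area_ratio_series(bw, rng)
  expect_equal(attr(ratio, "reference_deg"), 9.1)
  expect_equal(ratio[1], 1)
  expect_equal(ratio[4],
               (tan(15.1 / 2 * pi / 180) / tan(9.1 / 2 * pi / 180))^2,
               tolerance = 1e-9)
  expect_lt(ratio[4], 3)  # the printed widening stays below three-fold
  # range does not enter: permuting ranges leaves ratios unchanged
  ratio2 <- area_ratio_series(bw, c(4, 3, 2.5, 1.9, 0.6))
  expect_equal(as.numeric(ratio2), as.numeric(ratio))
  expect_error(area_ratio_series(c(9, 10), c(1, 1.5)), "long-range")
})

test_that("detection range follows the active sonar equation", {
  expect_equal(detection_range(125), 35.48, tolerance = 1e-3)
  # SL = DT - TS gives the 1 m reference range
  expect_equal(detection_range(63), 1)
  # +40 dB on SL multiplies the range by 10
  expect_equal(detection_range(165) / detection_range(125), 10)
  # monotonicities
  expect_true(all(diff(detection_range(seq(100, 160, 10))) > 0))
  expect_gt(detection_range(125, target_strength_db = -30),
            detection_range(125, target_strength_db = -36))
  expect_lt(detection_range(125, detection_threshold_db = 33),
            detection_range(125, detection_threshold_db = 27))
})

test_that("regression recovers a built-in negative slope", {
  set.seed(8)
  n <- 500
  rng <- runif(n, 0.5, 7)
  bw <- 14 - 1.2 * rng + rnorm(n, 0, 1.5)
  fit <- beamwidth_range_regression(bw, rng)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.001)
  expect_equal(fit$slope, -1.2, tolerance = 0.1)
  # perfectly collinear data: R^2 = 1
  fit2 <- beamwidth_range_regression(10 - 2 * rng, rng)
  expect_equal(fit2$r_squared, 1)
  expect_error(beamwidth_range_regression(c(1, 2), c(1, 2)), "3")
  expect_error(beamwidth_range_regression(c(1, 2, 3), c(1, 1, 1)),
               "variance")
})

test_that("null regressions keep nominal type-I error", {
  set.seed(9)
  p <- vapply(1:60, function(i) {
    rng <- runif(60, 0.5, 7)
    bw <- 10 + rnorm(60, 0, 2)
    beamwidth_range_regression(bw, rng)$p_value
  }, numeric(1))
  expect_gt(mean(p > 0.05), 0.85)
  # p roughly uniform: median not far from 0.5
  expect_gt(median(p), 0.25)
  expect_lt(median(p), 0.75)
})

test_that("cluster ANOVA separates constructed beamwidth groups", {
  set.seed(10)
  bw <- c(rnorm(40, 8, 0.3), rnorm(40, 12, 0.3), rnorm(40, 18, 0.3))
  rng <- c(rnorm(40, 4, 0.4), rnorm(40, 2, 0.4), rnorm(40, 0.7, 0.2))
  res <- cluster_anova(bw, rng)
  expect_false(res$degenerate)
  expect_equal(sort(unique(res$clusters)), 1:3)
  expect_lt(res$anova_p, 0.01)
  # widest-beam cluster (3) emitted significantly closer than the
  # narrowest (1): Tukey-Kramer pairwise p < 0.01
  row <- res$tukey["3-1", ]
  expect_lt(row[["p adj"]], 0.01)
  expect_lt(res$cluster_means$range_m[3], res$cluster_means$range_m[1])
  # labels invariant to input order
  perm <- sample(length(bw))
  res2 <- cluster_anova(bw[perm], rng[perm])
  expect_equal(res2$clusters, res$clusters[perm])
  # degenerate input
  expect_true(cluster_anova(c(5, 5, 5), c(1, 2, 3))$degenerate)
})

test_that("identical group means keep ANOVA quiet on null data", {
  set.seed(11)
  hits <- vapply(1:40, function(i) {
    bw <- c(rnorm(25, 8, 0.3), rnorm(25, 12, 0.3), rnorm(25, 18, 0.3))
    rng <- rnorm(75, 2, 0.5)  # no distance effect
    cluster_anova(bw, rng)$anova_p
  }, numeric(1))
  expect_gte(mean(hits > 0.05), 0.85)
})

test_that("phase summary splits buzz and regular clicks", {
  s <- beamwidth_phase_summary(c(9, 10, 15, 16), c(FALSE, FALSE, TRUE,
                                                   TRUE))
  expect_equal(s$mean[s$phase == "regular"], 9.5)
  expect_equal(s$mean[s$phase == "buzz"], 15.5)
})
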