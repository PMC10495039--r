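test_that("paired SMD identities, hand cases and antisymmetry", {
  a <- c(43.2, 50.1, 38.7, 55.4, 47.0)
  expect_identical(paired_smd(a, a)$smd, 0)
  # hand toy: differences (1, 0, -1) have mean 0
  expect_equal(paired_smd(c(1, 2, 3), c(0, 2, 4))$smd, 0, tolerance = 1e-15)
  # shifting every difference by one SD-unit gives SMD exactly 1
  set.seed(91)
  b <- a + rnorm(5)
  d <- a - b
  b1 <- b - stats::sd(d)
  expect_equal(paired_smd(a, b1)$smd, mean(d) / stats::sd(d) + 1,
               tolerance = 1e-12)
  s <- paired_smd(a, b)
  expect_equal(paired_smd(b, a)$smd, -s$smd, tolerance = 1e-12)
  expect_equal(paired_smd(a + 5, b + 5)$smd, s$smd, tolerance = 1e-12)
  expect_equal(s$ci[2] - s$smd, 1.96 * sqrt(1 / 5 + s$smd^2 / 10),
               tolerance = 1e-12)
  expect_error(paired_smd(a, b[1:3]), "mismatch")
  expect_error(paired_smd(a, a + 2), "degenerate")
})

test_that("bootstrap CI brackets the point estimate", {
  set.seed(92)
  a <- rnorm(200, 50, 8)
  b <- a + rnorm(200, 1, 3)
  s <- paired_smd(a, b, ci_type = "bootstrap", B = 500, seed = 5)
  expect_lt(s$ci[1], s$smd)
  expect_gt(s$ci[2], s$smd)
})

test_that("Bland-Altman summary behaves on constructed cases", {
  a <- c(40, 45, 50, 55, 60)
  ba0 <- suppressWarnings(bland_altman(a, a))  # lm on a perfect fit warns
  expect_equal(ba0$loa_low, 0, tolerance = 1e-12)
  expect_equal(ba0$loa_high, 0, tolerance = 1e-12)
  ba2 <- bland_altman(a, a + 2)
  expect_equal(ba2$mean_diff, -2, tolerance = 1e-12)
  expect_equal(ba2$trend_slope, 0, tolerance = 1e-12)
  # heteroscedastic: difference grows with the average
  set.seed(93)
  avg <- rnorm(2000, 50, 10)
  d <- 0.2 * (avg - 50) + rnorm(2000, 0, 2)
  ba3 <- bland_altman(avg + d / 2, avg - d / 2)
  expect_gt(ba3$trend_slope, 0.1)
  expect_lt(ba3$trend_p, 0.001)
})

test_that("limits of agreement contain about 95% of normal differences", {
  set.seed(94)
  a <- rnorm(5000, 50, 9)
  b <- a + rnorm(5000, 0.5, 3)
  ba <- bland_altman(a, b)
  cover <- mean(a - b >= ba$loa_low & a - b <= ba$loa_high)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("subgroup agreement labels effect sizes at the 0.2/0.5/0.8 cuts", {
  set.seed(95)
  n <- 400
  strata <- rep(c("g1", "g2"), each = n / 2)
  a <- rnorm(n, 50, 8)
  b <- a
  out <- subgroup_agreement(a, b, strata)
  expect_true(all(out$smd == 0))
  expect_true(all(out$label == "negligible"))
  expect_identical(perfolink:::.smd_label(0.19), "negligible")
  expect_identical(perfolink:::.smd_label(0.2), "small")
  expect_identical(perfolink:::.smd_label(-0.6), "medium")
  expect_identical(perfolink:::.smd_label(0.85), "large")
  # a stratum of size 2 is reported without SMD/CI
  out2 <- subgroup_agreement(a, b, c(rep("big", n - 2), "tiny", "tiny"))
  tiny <- out2[out2$stratum == "tiny", ]
  expect_equal(tiny$n, 2)
  expect_true(is.na(tiny$smd) && is.na(tiny$ci_low))
})

test_that("ceiling rates expose the shorter instrument's restricted range", {
  expect_equal(ceiling_floor(c(5, 5, 5), 5, 0)$ceiling, 1)
  expect_equal(ceiling_floor(c(1, 2, 3), 5, 0)$ceiling, 0)
  expect_equal(ceiling_floor(c(1, 2, 3), 5, 0)$floor, 0)
  # identical items split 4 vs 9: only length differs, so the short form
  # must saturate sooner in a high-ability population
  bank <- item_bank(sprintf("it%02d", 1:13),
                    rep(c("anchor", "new"), c(4, 9)),
                    rep(1.8, 13), rep(list(c(-2, -1, 0, 1)), 13),
                    rep(c(TRUE, FALSE), c(4, 9)))
  rm <- simulate_unidimensional(bank, 2000, theta_mean = 2, seed = 96)
  sum_a <- rowSums(rm$responses[, 1:4])
  sum_n <- rowSums(rm$responses[, 5:13])
  ca <- ceiling_floor(sum_a, 16, 0)
  cn <- ceiling_floor(sum_n, 36, 0)
  expect_gt(ca$ceiling, cn$ceiling + 0.1)   # 4 items saturate before 9
})

test_that("difference-covariate correlations close the generator loop", {
  covs <- data.frame(x = rnorm(100))
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(unname(diff_covariate_corr(a, b, data.frame(d = a - b))["d"]), 1,
               tolerance = 1e-12)
  expect_error(diff_covariate_corr(a, b, data.frame(k = rep(1, 100))),
               "constant")
  bank <- study_bank(seed = 27)
  rm <- simulate_unidimensional(bank, 5000, seed = 97)
  rm <- attach_difference_covariates(rm, bank, c(dep = 0.28), seed = 98)
  az <- rowMeans(scale(rm$responses[, anchor_part(bank)]))
  bz <- rowMeans(scale(rm$responses[, new_part(bank)]))
  r <- diff_covariate_corr(az, bz, rm$covariates["dep"])
  expect_lt(abs(unname(r) - 0.28), 0.04)
})
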