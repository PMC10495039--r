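test_that("unidimensional simulation follows the generating GRM", {
  bank <- item_bank("x", "new", 2, list(0), FALSE)
  # theta = +5 with a = 2, b = 0: P(top) = plogis(10) > 0.99
  rm_hi <- simulate_unidimensional(bank, 1000, theta_mean = 5, theta_sd = 1e-9,
                                   seed = 2)
  expect_gt(mean(rm_hi$responses[, 1] == 1L), 0.99)
  # theta_sd -> 0 at the threshold: symmetric split
  b1 <- item_bank("x", "new", 1, list(0), FALSE)
  rm0 <- simulate_unidimensional(b1, 20000, theta_mean = 0, theta_sd = 1e-12,
                                 seed = 3)
  expect_equal(mean(rm0$responses[, 1]), 0.5, tolerance = 0.02)
  expect_identical(simulate_unidimensional(bank, 50, seed = 9)$responses,
                   simulate_unidimensional(bank, 50, seed = 9)$responses)
  expect_error(simulate_unidimensional(bank[0, ], 10), "empty|invalid")
})

test_that("generated category frequencies match analytic marginals", {
  bank <- study_bank(seed = 5)
  rm <- simulate_unidimensional(bank, 10000, seed = 6)
  grid <- make_grid(201, 6)
  th <- bank_thresholds(bank)
  pvals <- vapply(seq_len(nrow(bank)), function(j) {
    marg <- colSums(grm_category_probs(bank$slope[j], th[[j]], grid$nodes) *
                      grid$weights)
    obs <- tabulate(rm$responses[, j] + 1L, nbins = bank$n_cat[j])
    suppressWarnings(stats::chisq.test(obs, p = marg)$p.value)
  }, numeric(1))
  # goodness-of-fit non-rejection at alpha = 0.01 (joint over 13 items,
  # allow a single excursion)
  expect_lte(sum(pvals < 0.01), 1L)
})

test_that("bifactor simulation reduces to unidimensional when specifics vanish", {
  bank <- study_bank(seed = 2)
  part <- default_partition(bank)
  sc0 <- sim_scenario(4000, rep(0.7, 13), rep(0, 13), part, seed = 4)
  rm0 <- simulate_bifactor(bank, sc0)
  # same marginal construction without any specific factor
  z_only <- simulate_bifactor(bank, sim_scenario(4000, rep(0.7, 13), rep(0, 13),
                                                 list(), seed = 8))
  for (j in c(1, 7, 13)) {
    tab <- rbind(tabulate(rm0$responses[, j] + 1L, 5),
                 tabulate(z_only$responses[, j] + 1L, 5))
    expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  }
  expect_identical(simulate_bifactor(bank, sc0)$responses, rm0$responses)
})

test_that("specific factors induce within-group residual association", {
  bank <- study_bank(seed = 2)
  part <- default_partition(bank)
  sc <- sim_scenario(6000, rep(0.6, 13), rep(0.55, 13), part, seed = 10)
  rmx <- simulate_bifactor(bank, sc)
  G <- rmx$true_theta
  # partial out the general factor; within-group residual correlation positive
  res <- apply(rmx$responses, 2, function(x) stats::residuals(stats::lm(x ~ G)))
  grp1 <- part[[2]]
  within <- stats::cor(res[, grp1])
  between <- stats::cor(res[, grp1[1]], res[, part[[3]][1]])
  expect_true(all(within[upper.tri(within)] > 0.1))
  expect_lt(abs(between), 0.1)
})

test_that("scenario communality constraint is enforced", {
  expect_error(sim_scenario(100, c(0.9), c(0.5), list(1)), "communality")
  expect_error(sim_scenario(100, c(1.0), c(0), list(1)), "loadings")
})

test_that("difference covariates hit their target correlations", {
  bank <- study_bank(seed = 3)
  rm <- simulate_unidimensional(bank, 5000, seed = 12)
  rm <- attach_difference_covariates(rm, bank,
                                     c(zero = 0, pain = 0.22, depression = 0.28),
                                     seed = 13)
  a <- rowMeans(scale(rm$responses[, anchor_part(bank)]))
  b <- rowMeans(scale(rm$responses[, new_part(bank)]))
  d <- a - b
  expect_lt(abs(stats::cor(d, rm$covariates$zero)), 0.04)
  expect_lt(abs(stats::cor(d, rm$covariates$pain) - 0.22), 0.04)
  expect_lt(abs(stats::cor(d, rm$covariates$depression) - 0.28), 0.04)
  expect_error(attach_difference_covariates(rm, bank, c(x = 1.2)), "target_r")
})

test_that("MCAR missingness hits the requested rate and mask", {
  bank <- study_bank(seed = 4)
  rm <- simulate_unidimensional(bank, 1000, seed = 14)
  expect_identical(apply_missingness(rm, 0), rm)
  out <- apply_missingness(rm, 0.1, items = new_part(bank), seed = 15)
  n_miss <- sum(is.na(out$responses[, new_part(bank)]))
  expect_equal(n_miss, 900, tolerance = 0.12)   # binomial mean 9000 * 0.1
  expect_false(anyNA(out$responses[, anchor_part(bank)]))
  expect_identical(apply_missingness(rm, 0.1, seed = 15)$responses,
                   apply_missingness(rm, 0.1, seed = 15)$responses)
  expect_error(apply_missingness(rm, 1), "rate")
})

test_that("response CSV round-trips preserve codes, missing cells and covariates", {
  bank <- study_bank(seed = 6)
  rm <- simulate_unidimensional(bank, 60, seed = 16)
  rm <- apply_missingness(rm, 0.2, seed = 17)
  rm$covariates <- data.frame(sex = rep(c("f", "m"), 30), pain = rnorm(60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, path)
  back <- read_responses(path, bank = bank)
  expect_identical(back$responses[, bank$item_id], rm$responses[, bank$item_id])
  expect_equal(back$covariates$pain, rm$covariates$pain, tolerance = 1e-12)
  expect_identical(back$covariates$sex, rm$covariates$sex)
  # a code outside the category range is rejected with location info
  bad <- rm
  bad$responses[3, 2] <- 9L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(bad, path2)
  expect_error(read_responses(path2, bank = bank), "out of range")
})
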