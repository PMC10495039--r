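test_that("GRM category probabilities match direct logistic evaluation", {
  expect_equal(as.numeric(grm_category_probs(1, 0, 0)), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(grm_category_probs(1, c(-1, 1), 0)),
               c(0.26894, 0.46212, 0.26894), tolerance = 1e-5)
  # theta at any threshold: cumulative probability exactly 1/2
  b <- c(-0.7, 0.2, 1.4)
  for (k in seq_along(b)) {
    p <- grm_category_probs(1.7, b, b[k])
    expect_equal(sum(p[1, (k + 1):4]), 0.5, tolerance = 1e-12)
  }
  theta <- seq(-6, 6, length.out = 25)
  P <- grm_category_probs(2.2, c(-2, -0.5, 0.5, 2), theta)
  expect_equal(rowSums(P), rep(1, 25), tolerance = 1e-12)
})

test_that("pattern log-likelihood is additive and handles missingness", {
  bank <- toy_bank3()
  expect_equal(pattern_loglik(rep(NA_integer_, 3), bank, c(-1, 0, 2)),
               c(0, 0, 0), tolerance = 1e-15)
  th <- 0.4
  ll1 <- pattern_loglik(c(1L, NA, NA), bank, th)
  expect_equal(ll1, log(grm_category_probs(bank$slope[1],
                                           bank_thresholds(bank)[[1]], th)[1, 2]),
               tolerance = 1e-12)
  ll_all <- pattern_loglik(c(1L, 0L, 2L), bank, th)
  ll_sum <- ll1 + pattern_loglik(c(NA, 0L, 2L), bank, th)
  expect_equal(ll_all, ll_sum, tolerance = 1e-12)
  expect_error(pattern_loglik(c(5L, 0L, 0L), bank, 0), "out of range")
})

test_that("the quadrature grid carries a normalized symmetric normal prior", {
  g <- make_grid(61, 6)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_equal(g$weights, rev(g$weights), tolerance = 1e-12)
  expect_equal(sum(g$weights * g$nodes), 0, tolerance = 1e-12)
  expect_error(make_grid(2), "n_nodes")
})

test_that("Lord-Wingersky recursion matches exhaustive pattern enumeration", {
  bank <- toy_bank3()
  th <- bank_thresholds(bank)
  for (theta in c(-1.3, 0.37, 2.1)) {
    pr <- lapply(1:3, function(j) grm_category_probs(bank$slope[j], th[[j]], theta))
    enum <- numeric(7)
    for (a in 0:2) for (b in 0:2) for (cc in 0:2) {
      s <- a + b + cc
      enum[s + 1] <- enum[s + 1] + pr[[1]][a + 1] * pr[[2]][b + 1] * pr[[3]][cc + 1]
    }
    lw <- lw_sumscore_dist(bank, theta)
    expect_equal(as.numeric(lw), enum, tolerance = 1e-12)
    expect_equal(sum(lw), 1, tolerance = 1e-12)
  }
  one <- bank[1, ]; class(one) <- c("item_bank", "data.frame")
  expect_equal(as.numeric(lw_sumscore_dist(one, 0.5)),
               as.numeric(grm_category_probs(bank$slope[1], th[[1]], 0.5)),
               tolerance = 1e-15)
})

test_that("EAP agrees with a fine-grid integration oracle", {
  bank <- study_bank(seed = 17)
  rm <- simulate_unidimensional(bank, 20, seed = 71)
  grid <- make_grid(61, 6)
  fine <- make_grid(8001, 6)
  got <- eap_score(rm, bank, grid)
  for (i in 1:20) {
    ll <- pattern_loglik(rm$responses[i, ], bank, fine$nodes)
    w <- exp(ll - max(ll)) * fine$weights
    expect_equal(got$theta_eap[i], sum(fine$nodes * w) / sum(w),
                 tolerance = 1e-6)
  }
})

test_that("EAP prior behaviour, T transform and SE shrinkage", {
  bank <- study_bank(seed = 17)
  sc <- eap_score(rep(NA_integer_, 13), bank)
  expect_equal(sc$theta_eap, 0, tolerance = 1e-9)
  expect_equal(sc$t_score, 50, tolerance = 1e-8)
  expect_equal(sc$se_eap, 1, tolerance = 0.01)
  expect_equal(sc$items_used, 0L)
  expect_equal(to_tscore(0), 50)
  expect_equal(to_tscore(1), 60)
  expect_equal(to_tscore(-2.8), 22)
  # adding informative items never inflates the posterior SD (nested patterns)
  pat <- rep(NA_integer_, 13)
  prev <- sc$se_eap
  resp <- simulate_unidimensional(bank, 1, seed = 72)$responses[1, ]
  for (j in c(1, 4, 7, 10, 13)) {
    pat[j] <- resp[j]
    se <- eap_score(pat, bank)$se_eap
    expect_lte(se, prev + 1e-8)
    prev <- se
  }
})

test_that("raising a response never lowers the EAP estimate", {
  bank <- toy_bank3()
  grid <- make_grid(61, 6)
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  colnames(pats) <- bank$item_id
  th <- eap_score(pats, bank, grid)$theta_eap
  for (i in seq_len(nrow(pats))) {
    for (j in 1:3) {
      if (pats[i, j] < 2) {
        up <- pats[i, ]; up[j] <- up[j] + 1L
        k <- which(apply(pats, 1, function(r) all(r == up)))
        expect_gte(th[k], th[i])
      }
    }
  }
})

test_that("EM calibration with everything fixed returns the bank unchanged", {
  bank <- study_bank(seed = 18)
  rm <- simulate_unidimensional(bank, 300, seed = 73)
  cal <- grm_calibrate(rm, bank, fixed = rep(TRUE, 13))
  expect_identical(cal$bank_out$slope, bank$slope)
  expect_equal(cal$n_cycles, 0L)
  expect_true(cal$converged)
  expect_length(cal$loglik_trace, 1L)
})

test_that("the marginal log-likelihood never decreases across EM cycles", {
  bank <- study_bank(seed = 18)
  rm <- simulate_unidimensional(bank, 800, seed = 74)
  cal <- grm_calibrate(rm, bank, tol = 1e-4, max_cycles = 100)
  expect_true(all(diff(cal$loglik_trace) > -1e-8))
  expect_true(cal$converged)
})

test_that("EM is stationary at the generating parameters", {
  bank <- study_bank(seed = 19)
  rm <- simulate_unidimensional(bank, 10000, seed = 75)
  cal <- grm_calibrate(rm, bank, fixed = bank$fixed, tol = 1e-9,
                       max_cycles = 1, start_from_data = FALSE)
  # one cycle from the truth moves parameters only within sampling error
  free <- !bank$fixed
  est <- coef(cal)[free, ]
  tru <- cbind(bank$slope, as.matrix(bank[paste0("b", 1:4)]))[free, ]
  expect_lt(mean(abs(est - tru)), 0.02)
  expect_lt(cal$max_param_change, 0.05)
})

test_that("S-X2 detects constructed misfit and stays non-negative", {
  bank <- study_bank(seed = 20)
  rm <- simulate_unidimensional(bank, 2000, seed = 76)
  fit <- s_x2_itemfit(rm, bank)
  expect_true(all(fit$s_x2 >= 0))
  expect_true(all(fit$df[!is.na(fit$p)] >= 1))
  # an item generated steep but scored flat must misfit grossly
  wrong <- bank
  j <- match("NEW_5", bank$item_id)
  steep <- bank; steep$slope[j] <- 3
  flat <- bank; flat$slope[j] <- 0.8
  rm2 <- simulate_unidimensional(steep, 2000, seed = 77)
  fit2 <- s_x2_itemfit(rm2, flat)
  expect_lt(fit2$p[j], 0.001)
})

test_that("category collapsing recodes unobserved categories of free items", {
  bank <- study_bank(seed = 21)
  rm <- simulate_unidimensional(bank, 400, seed = 78)
  x <- rm$responses
  j <- match("NEW_1", colnames(x))
  x[, j][x[, j] == 4L] <- 3L   # empty the top category
  cal <- grm_calibrate(x, bank, max_cycles = 30)
  expect_false(is.null(cal$collapse_maps[["NEW_1"]]))
  expect_equal(cal$bank_out$n_cat[j], 4L)
})
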