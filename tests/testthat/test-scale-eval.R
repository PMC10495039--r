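toy_table <- function() {
  cbind(i1 = c(0, 1, 2, 3), i2 = c(1, 1, 2, 2), i3 = c(0, 2, 2, 3))
}

test_that("alpha matches the hand-computed variance arithmetic", {
  X <- toy_table()
  res <- cronbach_alpha(X)
  expect_equal(res$alpha, 0.897196261682243, tolerance = 1e-12)
  expect_equal(unname(res$alpha_if_deleted),
               c(-0.211481975967957, 0.062803738317757, -0.097196261682243),
               tolerance = 1e-12)
})

test_that("alpha reaches 1 for duplicated items and 0 for independent ones", {
  x <- c(0, 1, 2, 3, 4, 2, 1, 3)
  X <- cbind(a = x, b = x, c = x)
  expect_equal(cronbach_alpha(X)$alpha, 1, tolerance = 1e-12)
  set.seed(1)
  Xi <- matrix(sample(0:4, 5000 * 6, TRUE), 5000, 6,
               dimnames = list(NULL, paste0("r", 1:6)))
  expect_lt(abs(cronbach_alpha(Xi)$alpha), 0.05)
})

test_that("alpha is invariant to code shifts and item order", {
  X <- toy_table()
  Xs <- X; Xs[, 2] <- Xs[, 2] + 7
  expect_equal(cronbach_alpha(Xs)$alpha, cronbach_alpha(X)$alpha,
               tolerance = 1e-12)
  expect_equal(cronbach_alpha(X[, c(3, 1, 2)])$alpha, cronbach_alpha(X)$alpha,
               tolerance = 1e-12)
  expect_error(cronbach_alpha(X[, 1, drop = FALSE]), "2 items")
  expect_error(cronbach_alpha(cbind(a = rep(1, 4), b = rep(2, 4))),
               "variance")
})

test_that("corrected item-total correlations match direct computation", {
  X <- toy_table()
  r <- corrected_item_total(X)
  expect_equal(unname(r),
               c(0.982707629823991, 0.808290376865476, 0.870571500132014),
               tolerance = 1e-12)
  x <- c(0, 1, 2, 0, 3, 1)
  expect_equal(unname(corrected_item_total(cbind(a = x, b = x))),
               c(1, 1), tolerance = 1e-12)
  w <- capture_warnings(r2 <- corrected_item_total(cbind(a = x, b = rep(2, 6))))
  expect_true(any(grepl("constant", w)))
  expect_true(anyNA(r2))
})

test_that("Loevinger H matches brute-force covmax enumeration on a toy table", {
  x <- c(0, 0, 1, 2, 2, 1)
  y <- c(1, 0, 1, 2, 1, 0)
  # exhaustive pairing oracle: max covariance over all permutations of y
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  covpop <- function(a, b) mean(a * b) - mean(a) * mean(b)
  cmax <- max(vapply(perms(y), function(p) covpop(x, p), numeric(1)))
  h <- loevinger_h(cbind(i1 = x, i2 = y))
  expect_equal(h$H_pair[1, 2], covpop(x, y) / cmax, tolerance = 1e-12)
  expect_equal(h$H_scale, covpop(x, y) / cmax, tolerance = 1e-12)
})

test_that("Guttman patterns scale perfectly and independent items do not", {
  # items as step functions of a common ordering: perfect Guttman scale
  s <- 0:9
  X <- cbind(g1 = as.integer(s >= 3), g2 = as.integer(s >= 5),
             g3 = as.integer(s >= 8))
  expect_equal(loevinger_h(X)$H_scale, 1, tolerance = 1e-12)
  set.seed(2)
  Xi <- matrix(sample(0:4, 5000 * 5, TRUE), 5000, 5,
               dimnames = list(NULL, paste0("r", 1:5)))
  expect_lt(abs(loevinger_h(Xi)$H_scale), 0.05)
})

test_that("H_scale lies between the item coefficients and respects order invariance", {
  bank <- study_bank(seed = 8)
  rm <- simulate_unidimensional(bank, 1500, seed = 20)
  h <- loevinger_h(rm)
  expect_gte(h$H_scale, min(h$H_item) - 1e-12)
  expect_lte(h$H_scale, max(h$H_item) + 1e-12)
  h2 <- loevinger_h(rm$responses[, rev(bank$item_id)])
  expect_equal(h2$H_scale, h$H_scale, tolerance = 1e-12)
  expect_equal(h2$H_item[bank$item_id], h$H_item[bank$item_id],
               tolerance = 1e-12)
})

test_that("GRM data show no systematic monotonicity violations", {
  bank <- study_bank(seed = 9)
  rm <- simulate_unidimensional(bank, 2000, seed = 21)
  mono <- check_monotonicity(rm)
  expect_lte(sum(mono$active_violations), 1L)
})

test_that("a reversed item triggers active monotonicity violations", {
  bank <- study_bank(seed = 9)
  rm <- simulate_unidimensional(bank, 2000, seed = 22)
  x <- rm$responses
  x[, "NEW_4"] <- 4L - x[, "NEW_4"]   # equivalent to a negative slope
  mono <- check_monotonicity(x)
  expect_gte(mono$active_violations[mono$item_id == "NEW_4"], 1L)
})

test_that("a single rest-score group yields a warning, not violations", {
  X <- matrix(sample(0:1, 40, TRUE), 20, 2, dimnames = list(NULL, c("a", "b")))
  w <- capture_warnings(mono <- check_monotonicity(X, min_group = 100))
  expect_true(any(grepl("one rest-score", w)))
  expect_true(all(mono$violations == 0))
})
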