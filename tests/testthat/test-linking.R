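test_that("fixed-anchor linking keeps anchors byte-identical and needs free items", {
  bank <- study_bank(seed = 23)
  anch <- bank[bank$instrument == "anchor", ]
  class(anch) <- c("item_bank", "data.frame")
  rm <- simulate_unidimensional(bank, 600, seed = 81)
  cal <- fixed_anchor_link(rm, anch, new_part(bank))
  out_anch <- cal$bank_out[cal$bank_out$item_id %in% anch$item_id, ]
  expect_identical(out_anch$slope, anch$slope)
  expect_identical(as.matrix(out_anch[paste0("b", 1:4)]),
                   as.matrix(anch[paste0("b", 1:4)]))
  expect_error(fixed_anchor_link(rm, anch, character(0)), "no free items")
  expect_error(fixed_anchor_link(rm, anch, "GHOST"), "absent")
})

test_that("the estimated metric follows the anchors (translation equivariance)", {
  bank <- study_bank(seed = 23)
  anch <- bank[bank$instrument == "anchor", ]
  class(anch) <- c("item_bank", "data.frame")
  rm <- simulate_unidimensional(bank, 2000, seed = 82)
  cal0 <- fixed_anchor_link(rm, anch, new_part(bank))
  anch_shift <- anch
  anch_shift[paste0("b", 1:4)] <- anch_shift[paste0("b", 1:4)] + 1
  cal1 <- fixed_anchor_link(rm, anch_shift, new_part(bank))
  b0 <- as.matrix(cal0$bank_out[!cal0$fixed, paste0("b", 1:4)])
  b1 <- as.matrix(cal1$bank_out[!cal1$fixed, paste0("b", 1:4)])
  # the metric follows the anchors; the fixed N(0,1) prior damps the shift
  # below the full +1 when only 4 of 13 items carry the reference metric
  shift <- mean(b1 - b0)
  expect_gt(shift, 0.5)
  expect_lt(shift, 1.05)
})

test_that("crosswalk rows equal pattern EAP for a single item", {
  bank <- toy_bank3()[1, ]
  class(bank) <- c("item_bank", "data.frame")
  grid <- make_grid(61, 6)
  xw <- build_crosswalk(bank, grid)
  for (k in 0:2) {
    sc <- eap_score(matrix(k, 1, 1, dimnames = list(NULL, bank$item_id)),
                    bank, grid)
    expect_equal(xw$theta[k + 1], sc$theta_eap, tolerance = 1e-12)
    expect_equal(xw$se[k + 1], sc$se_eap, tolerance = 1e-12)
  }
})

test_that("crosswalk matches brute-force Bayes grouped by sum score", {
  bank <- toy_bank3()
  grid <- make_grid(61, 6)
  xw <- build_crosswalk(bank, grid)
  expect_equal(nrow(xw), 7L)
  expect_true(!is.unsorted(xw$theta, strictly = TRUE))
  expect_equal(xw$t_score, 10 * xw$theta + 50, tolerance = 1e-12)
  # enumerate all 27 patterns; posterior over nodes given S = s
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  s <- rowSums(pats)
  lik <- sapply(seq_len(nrow(pats)), function(i) {
    exp(pattern_loglik(pats[i, ], bank, grid$nodes))
  })   # nodes x patterns
  for (score in 0:6) {
    mass <- rowSums(lik[, s == score, drop = FALSE]) * grid$weights
    expect_equal(xw$theta[score + 1], sum(grid$nodes * mass) / sum(mass),
                 tolerance = 1e-10)
  }
})

test_that("crosswalk round-trips through CSV and rebuilds identically", {
  bank <- study_bank(seed = 24)
  nb <- bank[bank$instrument == "new", ]
  class(nb) <- c("item_bank", "data.frame")
  grid <- make_grid(61, 6)
  xw <- build_crosswalk(nb, grid)
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_item_bank(nb, bpath)
  xw2 <- build_crosswalk(read_item_bank(bpath), grid)
  expect_identical(xw$theta, xw2$theta)
  expect_identical(attr(xw, "bank_hash"), attr(xw2, "bank_hash"))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_crosswalk(xw, cpath)
  back <- read_crosswalk(cpath)
  expect_equal(back$theta, xw$theta, tolerance = 1e-12)
  expect_identical(attr(back, "item_subset"), attr(xw, "item_subset"))
})

test_that("score conversion uses the table when complete, pattern EAP otherwise", {
  bank <- study_bank(seed = 24)
  nb <- bank[bank$instrument == "new", ]
  class(nb) <- c("item_bank", "data.frame")
  grid <- make_grid(61, 6)
  xw <- build_crosswalk(nb, grid)
  rm <- simulate_unidimensional(nb, 200, seed = 83)
  rm <- apply_missingness(rm, 0.08, seed = 84)
  sc <- convert_scores(rm, xw, bank = nb, grid = grid)
  complete <- !apply(is.na(rm$responses), 1, any)
  expect_true(all(sc$method[complete] == "crosswalk"))
  expect_true(all(sc$method[!complete] == "pattern_eap"))
  i <- which(complete)[1]
  expect_equal(sc$t_score[i],
               xw$t_score[xw$sum_score == sum(rm$responses[i, ])],
               tolerance = 1e-12)
  # all-lowest responses map to the lowest tabulated T
  lo <- convert_scores(rep(0, 1) * xw$sum_score[1], xw)
  expect_equal(lo$t_score, min(xw$t_score), tolerance = 1e-12)
  expect_error(convert_scores(999, xw), "outside")
})

test_that("T-to-sum conversion is nearest with ties to the lower score", {
  xw <- data.frame(sum_score = 0:2, theta = c(-1, 0, 1), se = 1,
                   t_score = c(40, 50, 60))
  class(xw) <- c("crosswalk", "data.frame")
  expect_identical(tscore_to_sumscore(c(41, 55, 44.9, 60.3), xw),
                   c(0L, 1L, 0L, 2L))
})

test_that("pattern EAP and summed-score EAP agree closely on real patterns", {
  bank <- study_bank(seed = 24)
  nb <- bank[bank$instrument == "new", ]
  class(nb) <- c("item_bank", "data.frame")
  grid <- make_grid(61, 6)
  xw <- build_crosswalk(nb, grid)
  rm <- simulate_unidimensional(nb, 500, seed = 85)
  pat <- eap_score(rm, nb, grid)$theta_eap
  sums <- rowSums(rm$responses)
  tab <- xw$theta[match(sums, xw$sum_score)]
  expect_lt(sqrt(mean((pat - tab)^2)), 0.15)
})
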