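#' Expected a posteriori (EAP) trait scores on the T metric
#'
#' For each response pattern, the posterior over the quadrature nodes is
#' proportional to the pattern likelihood times the standard-normal prior
#' weights; the EAP estimate is the posterior mean, its standard error the
#' posterior standard deviation, and the T-score is \code{10 * theta + 50}.
#' An all-missing pattern returns the prior mean (theta 0, T 50).
#'
#' @param responses a [response_matrix()], an integer matrix (0-based codes,
#'   \code{NA} missing, columns covering the bank), or a single pattern
#'   vector of length \code{nrow(bank)}.
#' @param bank an [item_bank()].
#' @param grid a [make_grid()] grid.
#' @return A data frame with one row per person: \code{theta_eap},
#'   \code{se_eap}, \code{t_score}, \code{items_used}.
#' @export
eap_score <- function(responses, bank, grid = make_grid()) {
  if (inherits(responses, "response_matrix")) responses <- responses$responses
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L,
                                                   dimnames = list(NULL, bank$item_id))
  responses <- responses[, bank$item_id, drop = FALSE]
  .check_codes(responses, bank)
  ll <- .loglik_matrix(responses, bank, grid$nodes)
  lw <- sweep(ll, 2L, log(grid$weights), "+")
  mx <- apply(lw, 1L, max)
  post <- exp(lw - mx)
  post <- post / rowSums(post)
  theta <- as.numeric(post %*% grid$nodes)
  m2 <- as.numeric(post %*% (grid$nodes^2))
  se <- sqrt(pmax(m2 - theta^2, 0))
  data.frame(theta_eap = theta,
             se_eap = se,
             t_score = to_tscore(theta),
             items_used = as.integer(rowSums(!is.na(responses))))
}

#' Generalized S-X2 item fit
#'
#' Orlando-Thissen style fit statistic for each item: observed category
#' frequencies cross-classified by the rest score (sum over the remaining
#' items) are compared to their model-expected counterparts, where the
#' expected conditional category probabilities integrate the GRM category
#' curve against the rest-score likelihood (via the Lord-Wingersky
#' recursion) and the normal prior. Adjacent category cells with expected
#' count below \code{min_expected} are collapsed toward the nearer tail.
#' Persons with any missing response among the analyzed items are excluded
#' (the statistic conditions on complete sum scores).
#'
#' @param rm a [response_matrix()] or response matrix.
#' @param bank the calibrated [item_bank()].
#' @param grid a [make_grid()] grid.
#' @param min_expected cell-collapse threshold (default 1).
#' @return A data frame with one row per item: \code{item_id}, \code{s_x2},
#'   \code{df}, \code{p}, \code{collapsed_cells}. \code{p} is \code{NA} when
#'   \code{df <= 0} after collapsing.
#' @export
s_x2_itemfit <- function(rm, bank, grid = make_grid(), min_expected = 1) {
  responses <- if (inherits(rm, "response_matrix")) rm$responses else as.matrix(rm)
  responses <- responses[, bank$item_id, drop = FALSE]
  cc <- stats::complete.cases(responses)
  responses <- responses[cc, , drop = FALSE]
  if (nrow(responses) < 50L) {
    warning("fewer than 50 complete cases for S-X2")
  }
  nodes <- grid$nodes
  w <- grid$weights
  out <- vector("list", nrow(bank))
  for (j in seq_len(nrow(bank))) {
    rest <- bank[-j, , drop = FALSE]
    class(rest) <- c("item_bank", "data.frame")
    m <- bank$n_cat[j]
    rest_score <- rowSums(responses[, -j, drop = FALSE])
    f_rest <- lw_sumscore_dist(rest, nodes)            # q x S
    Pj <- grm_category_probs(bank$slope[j], bank_thresholds(bank)[[j]], nodes)
    S <- ncol(f_rest)
    # expected conditional P(X_j = k | rest = s): S x m
    num <- t(f_rest * w) %*% Pj                        # S x m
    den <- as.numeric(t(f_rest) %*% w)
    Econd <- num / pmax(den, .Machine$double.xmin)
    obs_levels <- which(tabulate(rest_score + 1L, nbins = S) > 0L)
    stat <- 0
    cells <- 0L
    levels_used <- 0L
    collapsed <- 0L
    for (s in obs_levels) {
      idx <- rest_score == (s - 1L)
      Ns <- sum(idx)
      O <- tabulate(responses[idx, j] + 1L, nbins = m)
      E <- Ns * Econd[s, ]
      grp <- .collapse_cells(E, min_expected)
      collapsed <- collapsed + (m - length(unique(grp)))
      Oc <- as.numeric(tapply(O, grp, sum))
      Ec <- as.numeric(tapply(E, grp, sum))
      keep <- Ec > 0
      Oc <- Oc[keep]; Ec <- Ec[keep]
      if (length(Ec) >= 2L) {
        stat <- stat + sum((Oc - Ec)^2 / Ec)
        cells <- cells + length(Ec)
        levels_used <- levels_used + 1L
      }
    }
    npar <- bank$n_cat[j]   # slope + (m-1) thresholds
    df <- cells - levels_used - npar
    p <- if (df >= 1L) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
    out[[j]] <- data.frame(item_id = bank$item_id[j], s_x2 = stat,
                           df = df, p = p, collapsed_cells = collapsed,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# group adjacent cells so each merged cell's expected count reaches the
# threshold, collapsing toward the nearer tail
.collapse_cells <- function(E, min_expected) {
  m <- length(E)
  grp <- seq_len(m)
  repeat {
    Eg <- tapply(E, grp, sum)
    ids <- as.integer(names(Eg))
    small <- which(Eg < min_expected)
    if (!length(small) || length(Eg) == 1L) break
    i <- small[1L]
    # merge with the neighbor toward the nearer tail of the grouped cells
    target <- if (i <= length(Eg) / 2) max(1L, i - 1L) else min(length(Eg), i + 1L)
    if (target == i) target <- if (i == 1L) 2L else length(Eg) - 1L
    grp[grp == ids[i]] <- ids[target]
  }
  match(grp, unique(grp))
}
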