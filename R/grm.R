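#' Graded response model category probabilities
#'
#' Under the logistic GRM the cumulative probability of responding in
#' category \code{k} or above is \code{P*(X >= k | theta) =
#' 1 / (1 + exp(-a (theta - b_k)))}, with \code{P*(X >= 0) = 1} and
#' \code{P*(X >= m) = 0}; category probabilities are adjacent differences.
#' Categories are 0-based (0..m-1).
#'
#' @param slope item discrimination \code{a > 0}.
#' @param thresholds strictly increasing numeric vector \code{b_1 < ... <
#'   b_{m-1}}.
#' @param theta numeric vector of latent trait values.
#' @return A \code{length(theta) x m} matrix of category probabilities; rows
#'   sum to 1.
#' @examples
#' grm_category_probs(1, c(-1, 1), theta = 0)
#' @export
grm_category_probs <- function(slope, thresholds, theta) {
  m <- length(thresholds) + 1L
  cum <- stats::plogis(outer(theta, thresholds, function(t, b) slope * (t - b)))
  full <- cbind(1, cum, 0)
  p <- full[, seq_len(m), drop = FALSE] - full[, seq_len(m) + 1L, drop = FALSE]
  # guard against 0 from extreme theta so logs stay finite
  pmax(p, .Machine$double.xmin)
}

#' Normal-prior quadrature grid
#'
#' Equally spaced nodes on \code{[-span, span]} with weights proportional to
#' the standard normal density, normalized to sum to one. This grid carries
#' the N(0,1) reference-population prior used throughout calibration and EAP
#' scoring.
#'
#' @param n_nodes number of nodes (>= 3); default 61.
#' @param span half-width of the grid; default 6.
#' @return A list of class \code{quadrature_grid} with \code{nodes} and
#'   \code{weights}.
#' @export
make_grid <- function(n_nodes = 61L, span = 6) {
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  nodes <- seq(-span, span, length.out = n_nodes)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "quadrature_grid")
}

# per-item list of node x category probability matrices
.bank_prob_tables <- function(bank, nodes) {
  th <- bank_thresholds(bank)
  lapply(seq_len(nrow(bank)), function(j) {
    grm_category_probs(bank$slope[j], th[[j]], nodes)
  })
}

#' Log-likelihood of a response pattern at given trait values
#'
#' Sums log GRM category probabilities over the non-missing entries of a
#' response pattern. An all-missing pattern has log-likelihood 0 (likelihood
#' 1) at every theta.
#'
#' @param pattern integer vector of 0-based responses, \code{NA} = missing;
#'   one entry per bank item, in bank order.
#' @param bank an [item_bank()].
#' @param theta numeric vector of trait values.
#' @return Numeric vector of log-likelihoods, one per theta.
#' @export
pattern_loglik <- function(pattern, bank, theta) {
  if (length(pattern) != nrow(bank)) stop("pattern length must equal bank size")
  ll <- numeric(length(theta))
  th <- bank_thresholds(bank)
  for (j in seq_along(pattern)) {
    x <- pattern[j]
    if (is.na(x)) next
    if (x < 0 || x >= bank$n_cat[j]) {
      stop("response code ", x, " out of range for item ", bank$item_id[j])
    }
    p <- grm_category_probs(bank$slope[j], th[[j]], theta)
    ll <- ll + log(p[, x + 1L])
  }
  ll
}

# persons x nodes log-likelihood matrix for a whole response matrix.
# responses: integer matrix with NA missing, columns in bank order.
.loglik_matrix <- function(responses, bank, nodes) {
  n <- nrow(responses)
  q <- length(nodes)
  tabs <- .bank_prob_tables(bank, nodes)
  ll <- matrix(0, n, q)
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    obs <- !is.na(x)
    if (!any(obs)) next
    lp <- log(tabs[[j]])                  # q x m
    ll[obs, ] <- ll[obs, ] + t(lp[, x[obs] + 1L, drop = FALSE])
  }
  ll
}

#' Map latent trait estimates to the T-score metric
#'
#' The reference metric is a T-score scale with mean 50 and standard
#' deviation 10 in the reference population: \code{T = 10 * theta + 50}.
#'
#' @param theta numeric vector.
#' @return \code{10 * theta + 50}.
#' @export
to_tscore <- function(theta) 10 * theta + 50

#' Lord-Wingersky summed-score distribution
#'
#' Computes the exact distribution of the sum score over a set of GRM items
#' at each trait value by the Lord-Wingersky recursion
#' \code{f_j(s | theta) = sum_k f_{j-1}(s - k | theta) P_j(k | theta)}.
#'
#' @param bank an [item_bank()] (the subset whose sum score is wanted).
#' @param theta numeric vector of trait values.
#' @return A \code{length(theta) x (1 + sum(n_cat - 1))} matrix; row
#'   \code{i}, column \code{s + 1} is \code{P(S = s | theta_i)}. Rows sum
#'   to 1.
#' @export
lw_sumscore_dist <- function(bank, theta) {
  if (nrow(bank) < 1L) stop("empty bank subset")
  tabs <- .bank_prob_tables(bank, theta)
  f <- tabs[[1L]]
  if (nrow(bank) > 1L) {
    for (j in 2:nrow(bank)) {
      p <- tabs[[j]]
      mj <- ncol(p)
      smax <- ncol(f) + mj - 1L
      g <- matrix(0, length(theta), smax)
      for (k in seq_len(mj)) {
        idx <- seq_len(ncol(f)) + (k - 1L)
        g[, idx] <- g[, idx] + f * p[, k]
      }
      f <- g
    }
  }
  colnames(f) <- as.character(0:(ncol(f) - 1L))
  f
}
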