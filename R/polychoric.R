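#' Polychoric correlation matrix
#'
#' Two-step polychoric estimation for ordinal items: per-item thresholds are
#' the inverse-normal of cumulative marginal proportions; each pairwise
#' correlation then maximizes the bivariate-normal contingency-table
#' likelihood over pairwise-complete observations, bounded in
#' (-0.999, 0.999). Bivariate normal rectangle probabilities use a
#' Gauss-Legendre quadrature of the single-integral reduction of the
#' bivariate CDF. A pair whose likelihood maximization fails falls back to
#' the Pearson correlation with a warning.
#'
#' @param rm a [response_matrix()] or integer matrix.
#' @param items item ids/indices (default all).
#' @return A list of class \code{polychoric_matrix}: \code{rho} (item x item,
#'   unit diagonal), \code{avar} (asymptotic variance of each rho from the
#'   observed information of the pairwise likelihood), \code{thresholds}
#'   (per-item normal thresholds), \code{pairwise_n}.
#' @export
polychoric_matrix <- function(rm, items = NULL) {
  X <- .item_matrix(rm, items)
  J <- ncol(X)
  thresholds <- vector("list", J)
  names(thresholds) <- colnames(X)
  for (j in seq_len(J)) {
    # work on the ranks of the observed categories so codes with gaps
    # (categories nobody used) still align with the threshold cells
    lev <- sort(unique(X[, j][!is.na(X[, j])]))
    if (length(lev) < 2L) stop("item ", colnames(X)[j],
                               " shows fewer than 2 observed categories")
    X[, j] <- match(X[, j], lev)
    tab <- tabulate(X[, j][!is.na(X[, j])], length(lev))
    cum <- cumsum(tab) / sum(tab)
    thresholds[[j]] <- stats::qnorm(cum[-length(cum)])
  }
  rho <- diag(1, J); dimnames(rho) <- list(colnames(X), colnames(X))
  avar <- matrix(NA_real_, J, J, dimnames = dimnames(rho))
  pn <- matrix(0L, J, J, dimnames = dimnames(rho))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      pn[i, j] <- pn[j, i] <- sum(ok)
      est <- .polychoric_pair(X[ok, i], X[ok, j], thresholds[[i]], thresholds[[j]],
                              colnames(X)[c(i, j)])
      rho[i, j] <- rho[j, i] <- est$rho
      avar[i, j] <- avar[j, i] <- est$avar
    }
  }
  structure(list(rho = rho, avar = avar, thresholds = thresholds,
                 pairwise_n = pn),
            class = "polychoric_matrix")
}

.polychoric_pair <- function(x, y, tx, ty, ids) {
  # x, y hold 1-based category ranks aligned with tx, ty
  tab <- table(factor(x, levels = seq_len(length(tx) + 1L)),
               factor(y, levels = seq_len(length(ty) + 1L)))
  a <- c(-Inf, tx, Inf); b <- c(-Inf, ty, Inf)
  negll_full <- function(r) {
    P <- .bvn_cell_probs(a, b, r)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  fit <- tryCatch(stats::optimize(negll_full, c(-0.999, 0.999), tol = 1e-7),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("polychoric maximization failed for pair ", ids[1L], "/", ids[2L],
            "; falling back to Pearson")
    r <- stats::cor(x, y)
    return(list(rho = max(min(r, 0.999), -0.999), avar = (1 - r^2)^2 / length(x)))
  }
  r <- fit$minimum
  # observed information by central second difference of the pair loglik
  h <- 1e-4
  rl <- max(r - h, -0.999); ru <- min(r + h, 0.999)
  info <- (negll_full(ru) - 2 * negll_full(r) + negll_full(rl)) /
    (((ru - rl) / 2)^2)
  av <- if (is.finite(info) && info > 0) 1 / info else (1 - r^2)^2 / length(x)
  list(rho = r, avar = av)
}

# rectangle probabilities of a standard bivariate normal over the grid of
# thresholds a (rows) x b (cols); returns (length(a)-1) x (length(b)-1)
.bvn_cell_probs <- function(a, b, rho) {
  na <- length(a); nb <- length(b)
  Phi2 <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    Phi2[i, ] <- .pbvn(rep(a[i], nb), b, rho)
  }
  P <- Phi2[-1L, -1L, drop = FALSE] - Phi2[-na, -1L, drop = FALSE] -
    Phi2[-1L, -nb, drop = FALSE] + Phi2[-na, -nb, drop = FALSE]
  pmax(P, 0)
}

# bivariate normal CDF P(X <= h, Y <= k) via Gauss-Legendre quadrature of
# Phi2 = Phi(h)Phi(k) + (1/2pi) int_0^rho (1-r^2)^{-1/2}
#        exp(-(h^2 - 2 r h k + k^2) / (2 (1-r^2))) dr  (vectorized over h,k)
.pbvn <- function(h, k, rho) {
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(out)
  fin <- is.finite(h) & is.finite(k)
  if (any(!fin)) {
    # an infinite bound reduces to the univariate margin (or 0)
    out[!fin & (h == -Inf | k == -Inf)] <- 0
    out[!fin & h == Inf] <- stats::pnorm(k[!fin & h == Inf])
    out[!fin & k == Inf] <- stats::pnorm(h[!fin & k == Inf])
  }
  if (any(fin)) {
    gl <- .gauss_legendre(32L)
    r <- rho / 2 * (gl$nodes + 1)          # map [-1,1] -> [0, rho]
    wr <- rho / 2 * gl$weights
    hh <- h[fin]; kk <- k[fin]
    acc <- 0
    term <- vapply(seq_along(r), function(i) {
      om <- 1 - r[i]^2
      wr[i] / (2 * pi * sqrt(om)) *
        exp(-(hh^2 - 2 * r[i] * hh * kk + kk^2) / (2 * om))
    }, numeric(length(hh)))
    add <- if (is.matrix(term)) rowSums(term) else sum(term)
    out[fin] <- out[fin] + add
  }
  pmin(pmax(out, 0), 1)
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1], cached
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- beta
  Jm[cbind(i + 1L, i)] <- beta
  e <- eigen(Jm, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1L, ]^2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  .gl_cache[[key]] <- out
  out
}
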