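#' Confirmatory factor analysis of polychoric correlations (DWLS)
#'
#' Fits a simple-structure factor model (each item loads exactly one
#' factor; factors freely correlated) to a polychoric correlation matrix by
#' diagonally weighted least squares: the discrepancy
#' \code{sum_{i<j} (rho_ij - sigma_ij(lambda, phi))^2 / avar_ij} is
#' minimized, with diagonal weights the estimated asymptotic variances of
#' the polychorics. Fit indices come from the discrepancy-based chi-square
#' against the independence baseline (CFI, TLI), the noncentrality (RMSEA),
#' and the root mean squared residual correlation (SRMSR).
#'
#' @param pm a [polychoric_matrix()].
#' @param pattern integer (or factor) vector, one entry per item, giving
#'   each item's factor index (1..K).
#' @return A list of class \code{factor_solution}: \code{loadings},
#'   \code{factor_corr}, \code{residual_corr}, \code{fit} (chisq, df, CFI,
#'   TLI, RMSEA, SRMSR), \code{converged}, \code{heywood}.
#' @export
fit_factor_model <- function(pm, pattern) {
  stopifnot(inherits(pm, "polychoric_matrix"))
  R <- pm$rho
  J <- nrow(R)
  f <- as.integer(factor(pattern))
  if (length(f) != J) stop("pattern must assign every item to a factor")
  K <- max(f)
  if (any(tabulate(f, K) < 2L)) {
    stop("unidentified model: every factor needs at least 2 items")
  }
  npairs <- J * (J - 1L) / 2L
  npar <- J + K * (K - 1L) / 2L
  if (npairs - npar < 0L) stop("unidentified model: negative degrees of freedom")
  W <- 1 / pm$avar
  ut <- upper.tri(R)

  implied <- function(lambda, phi_v) {
    Phi <- diag(1, K)
    if (K > 1L) { Phi[upper.tri(Phi)] <- phi_v; Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)] }
    S <- (lambda %o% lambda) * Phi[f, f]
    S
  }
  obj <- function(par) {
    lambda <- par[seq_len(J)]
    phi_v <- if (K > 1L) par[-seq_len(J)] else numeric(0)
    S <- implied(lambda, phi_v)
    sum(W[ut] * (R[ut] - S[ut])^2)
  }
  start <- c(rep(0.7, J), rep(0.3, K * (K - 1L) / 2L))
  lower <- c(rep(-1.5, J), rep(-0.99, K * (K - 1L) / 2L))
  upper <- c(rep(1.5, J), rep(0.99, K * (K - 1L) / 2L))
  fit <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 2000, factr = 1e4))
  lambda <- fit$par[seq_len(J)]
  phi_v <- if (K > 1L) fit$par[-seq_len(J)] else numeric(0)
  # sign convention: majority-positive loadings per factor
  for (k in seq_len(K)) {
    if (sum(lambda[f == k]) < 0) {
      lambda[f == k] <- -lambda[f == k]
      if (K > 1L) {
        Phi <- diag(1, K); Phi[upper.tri(Phi)] <- phi_v
        Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
        Phi[k, -k] <- -Phi[k, -k]; Phi[-k, k] <- -Phi[-k, k]
        phi_v <- Phi[upper.tri(Phi)]
      }
    }
  }
  S <- implied(lambda, phi_v)
  resid <- R - S; diag(resid) <- 0
  Tstat <- fit$value
  df <- npairs - npar
  Tbase <- sum(W[ut] * R[ut]^2)
  dfb <- npairs
  n_eff <- mean(pm$pairwise_n[ut])
  cfi <- 1 - max(Tstat - df, 0) / max(Tbase - dfb, Tstat - df, .Machine$double.eps)
  tli <- if (df > 0 && dfb > 0 && Tbase / dfb > 1) {
    min(1, (Tbase / dfb - Tstat / df) / (Tbase / dfb - 1))
  } else NA_real_
  rmsea <- if (df > 0) sqrt(max((Tstat - df) / (df * (n_eff - 1)), 0)) else 0
  srmsr <- sqrt(mean(resid[ut]^2))
  Phi <- diag(1, K)
  if (K > 1L) { Phi[upper.tri(Phi)] <- phi_v; Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)] }
  L <- matrix(0, J, K, dimnames = list(rownames(R), paste0("F", seq_len(K))))
  L[cbind(seq_len(J), f)] <- lambda
  structure(list(loadings = L, factor_corr = Phi, residual_corr = resid,
                 fit = c(chisq = Tstat, df = df, CFI = cfi, TLI = tli,
                         RMSEA = rmsea, SRMSR = srmsr),
                 converged = fit$convergence == 0,
                 heywood = any(abs(lambda) > 1)),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("DWLS factor solution\n")
  print(round(x$loadings, 3))
  if (ncol(x$loadings) > 1L) {
    cat("Factor correlations:\n"); print(round(x$factor_corr, 3))
  }
  cat(sprintf("CFI %.3f  TLI %.3f  RMSEA %.3f  SRMSR %.3f%s\n",
              x$fit["CFI"], x$fit["TLI"], x$fit["RMSEA"], x$fit["SRMSR"],
              if (x$heywood) "  [Heywood case]" else ""))
  invisible(x)
}

#' Latent correlation between two instruments
#'
#' Two-factor DWLS fit with each instrument on its own factor; returns the
#' estimated factor correlation — the correlation between the latent
#' variables underlying the two item sets.
#'
#' @param rm a [response_matrix()] or matrix.
#' @param anchor_items,new_items item id vectors (each of length >= 2).
#' @return The factor correlation (scalar), with the full
#'   \code{factor_solution} attached as attribute \code{"solution"}.
#' @export
latent_instrument_correlation <- function(rm, anchor_items, new_items) {
  if (length(anchor_items) < 2L || length(new_items) < 2L) {
    stop("each instrument needs at least 2 items")
  }
  pm <- polychoric_matrix(rm, items = c(anchor_items, new_items))
  pattern <- rep(1:2, c(length(anchor_items), length(new_items)))
  sol <- fit_factor_model(pm, pattern)
  structure(sol$factor_corr[1L, 2L], solution = sol)
}
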