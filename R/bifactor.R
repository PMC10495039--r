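#' Percentage of uncontaminated correlations (PUC)
#'
#' Fraction of item pairs not sharing a specific factor:
#' \code{PUC = (C(J,2) - sum_s C(J_s,2)) / C(J,2)} for a partition with
#' group sizes \code{J_s}.
#'
#' @param group_sizes integer vector of specific-group sizes.
#' @param n_items total number of items (default \code{sum(group_sizes)};
#'   items outside every group count toward uncontaminated pairs).
#' @return PUC in [0, 1].
#' @examples
#' puc(c(4, 3, 3, 3))  # 63/78
#' @export
puc <- function(group_sizes, n_items = sum(group_sizes)) {
  if (n_items < 2L) stop("need at least 2 items")
  (choose(n_items, 2) - sum(choose(group_sizes, 2))) / choose(n_items, 2)
}

#' Bifactor indices from a fixed loading matrix
#'
#' Closed-form explained common variance and omega-hierarchical for given
#' general and specific loadings:
#' \code{ECV = sum g^2 / (sum g^2 + sum lambda_s^2)};
#' \code{omegaH = (sum g)^2 / ((sum g)^2 + sum_s (sum_j lambda_js)^2 +
#' sum (1 - h2_j))} with \code{h2_j} the item communality.
#'
#' @param general numeric vector of general-factor loadings.
#' @param specific items x specific-factors loading matrix.
#' @param specific_groups optional partition (list of item index/id vectors)
#'   for the PUC count.
#' @return Named list \code{ECV}, \code{omegaH}, and \code{PUC} when a
#'   partition is given.
#' @export
bifactor_indices_from_loadings <- function(general, specific,
                                           specific_groups = NULL) {
  specific <- as.matrix(specific)
  h2 <- general^2 + rowSums(specific^2)
  ecv <- sum(general^2) / (sum(general^2) + sum(specific^2))
  omega_h <- sum(general)^2 /
    (sum(general)^2 + sum(colSums(specific)^2) + sum(1 - h2))
  out <- list(ECV = ecv, omegaH = omega_h)
  if (!is.null(specific_groups)) {
    out$PUC <- puc(lengths(specific_groups), n_items = length(general))
  }
  out
}

# iterated principal-axis factoring of a correlation matrix; attaches the
# final reduced-matrix eigenvalues as attribute "eigenvalues"
.paf <- function(R, nfactors, max_iter = 200L, tol = 1e-6) {
  J <- nrow(R)
  h2 <- tryCatch(pmin(pmax(1 - 1 / diag(solve(R)), 0.05), 0.95),
                 error = function(e) {
                   m <- abs(R); diag(m) <- 0
                   pmin(pmax(apply(m, 1L, max), 0.05), 0.95)
                 })
  L <- NULL
  ev <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- e$values
    v <- pmax(ev[seq_len(nfactors)], 0)
    L <- e$vectors[, seq_len(nfactors), drop = FALSE] %*% diag(sqrt(v), nfactors)
    h2_new <- pmin(rowSums(L^2), 0.998)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  rownames(L) <- rownames(R)
  attr(L, "eigenvalues") <- ev
  L
}

#' Exploratory bifactor indices via Schmid-Leiman orthogonalization
#'
#' First-order factors are extracted from the polychoric matrix by iterated
#' principal-axis factoring, rotated obliquely (promax); a single
#' second-order factor is then extracted from the first-order factor
#' correlations (again by principal axis), and the Schmid-Leiman
#' transformation orthogonalizes the solution into one general factor plus
#' uncorrelated specific factors: \code{g = P gamma}, \code{lambda_s =
#' P_s sqrt(1 - gamma_s^2)}. ECV and omegaH follow from the resulting
#' loadings; PUC is the counting formula on the supplied partition.
#'
#' @param pm a [polychoric_matrix()] (or a plain correlation matrix).
#' @param specific_groups list of item-id/index vectors partitioning the
#'   items (used for the PUC count and reported with the solution).
#' @param n_specific number of specific factors to extract (default: number
#'   of groups).
#' @param eigen_cut relative eigenvalue cut: first-order factors whose
#'   reduced-matrix eigenvalue falls below \code{eigen_cut} times the first
#'   eigenvalue carry no real common variance and are dropped before
#'   rotation (rotating null factors would smear the general factor across
#'   them). With a single surviving factor the solution is pure general.
#' @return A list of class \code{bifactor_solution}:
#'   \code{general_loadings}, \code{specific_loadings} (items x factors),
#'   \code{ECV}, \code{omegaH}, \code{PUC}, \code{specific_groups},
#'   \code{second_order}, \code{n_retained}.
#' @export
bifactor_indices <- function(pm, specific_groups,
                             n_specific = length(specific_groups),
                             eigen_cut = 0.05) {
  R <- if (inherits(pm, "polychoric_matrix")) pm$rho else as.matrix(pm)
  if (n_specific < 2L) stop("need at least 2 specific factors")
  ids <- rownames(R) %||% as.character(seq_len(nrow(R)))
  covered <- unlist(lapply(specific_groups, function(g) {
    if (is.character(g)) match(g, ids) else as.integer(g)
  }))
  if (anyNA(covered)) stop("unknown item in specific_groups")
  if (anyDuplicated(covered)) stop("specific_groups must not overlap")
  if (length(covered) != nrow(R)) stop("partition must cover all items")

  L1 <- .paf(R, n_specific)
  ev <- attr(L1, "eigenvalues")
  k_eff <- sum(ev[seq_len(n_specific)] > eigen_cut * ev[1L])
  if (k_eff < 2L) {
    g <- as.numeric(.paf(R, 1L))
    if (sum(g) < 0) g <- -g
    spec <- matrix(0, nrow(R), n_specific, dimnames = list(ids, NULL))
    idx <- bifactor_indices_from_loadings(g, spec, specific_groups)
    return(structure(list(general_loadings = stats::setNames(g, ids),
                          specific_loadings = spec,
                          ECV = idx$ECV, omegaH = idx$omegaH, PUC = idx$PUC,
                          specific_groups = specific_groups,
                          second_order = 1, n_retained = 1L),
                     class = "bifactor_solution"))
  }
  if (k_eff < n_specific) L1 <- .paf(R, k_eff)
  rot <- tryCatch(stats::promax(L1, m = 4), error = function(e) NULL)
  if (is.null(rot) || inherits(try(solve(crossprod(rot$rotmat)), silent = TRUE),
                               "try-error")) {
    # rotation degenerate (e.g. essentially 1 real factor): orthogonal solution
    P <- L1
    Phi <- diag(1, k_eff)
  } else {
    P <- unclass(rot$loadings)
    Phi <- solve(crossprod(rot$rotmat))
    # rescale to unit-variance factors
    d <- sqrt(diag(Phi))
    Phi <- Phi / (d %o% d)
    P <- P * rep(d, each = nrow(P))
  }
  # second-order general factor on the first-order correlations
  gamma <- as.numeric(.paf(Phi, 1L))
  if (sum(gamma) < 0) gamma <- -gamma
  g <- as.numeric(P %*% gamma)
  spec <- P * rep(sqrt(pmax(1 - gamma^2, 0)), each = nrow(P))
  if (sum(g) < 0) g <- -g
  idx <- bifactor_indices_from_loadings(g, spec, specific_groups)
  structure(list(general_loadings = stats::setNames(g, ids),
                 specific_loadings = spec,
                 ECV = idx$ECV, omegaH = idx$omegaH, PUC = idx$PUC,
                 specific_groups = specific_groups,
                 second_order = gamma, n_retained = k_eff),
            class = "bifactor_solution")
}

#' @export
print.bifactor_solution <- function(x, ...) {
  cat(sprintf("Schmid-Leiman bifactor solution: ECV %.3f, omegaH %.3f, PUC %.3f\n",
              x$ECV, x$omegaH, x$PUC))
  cat("General loadings:\n")
  print(round(x$general_loadings, 3))
  invisible(x)
}
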