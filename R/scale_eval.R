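#' Cronbach's alpha with deletion deltas
#'
#' \code{alpha = (J/(J-1)) (1 - sum var(X_j) / var(sum X))} over complete
#' cases on the selected items. Deletion deltas are
#' \code{alpha_without_j - alpha}: a non-positive delta means the item does
#' not hurt internal consistency.
#'
#' @param rm a [response_matrix()] or numeric matrix.
#' @param items item ids or indices (default: all columns).
#' @return A list with \code{alpha} and named \code{alpha_if_deleted}
#'   deltas.
#' @export
cronbach_alpha <- function(rm, items = NULL) {
  X <- .item_matrix(rm, items)
  J <- ncol(X)
  if (J < 2L) stop("need at least 2 items")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2L) stop("fewer than 2 complete rows")
  tv <- stats::var(rowSums(X))
  if (tv < 1e-12) stop("zero total-score variance")
  alpha1 <- function(M) {
    (ncol(M) / (ncol(M) - 1)) * (1 - sum(apply(M, 2L, stats::var)) /
                                   stats::var(rowSums(M)))
  }
  a <- alpha1(X)
  deltas <- vapply(seq_len(J), function(j) alpha1(X[, -j, drop = FALSE]) - a,
                   numeric(1L))
  names(deltas) <- colnames(X)
  list(alpha = a, alpha_if_deleted = deltas)
}

#' Corrected item-total correlations
#'
#' Pearson correlation of each item with the sum of the remaining items
#' (complete cases). Constant items yield \code{NA} with a warning rather
#' than being dropped.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector \code{r_itc}.
#' @export
corrected_item_total <- function(rm, items = NULL) {
  X <- .item_matrix(rm, items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 items")
  out <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    rest <- rowSums(X[, -j, drop = FALSE])
    if (stats::sd(x) < 1e-12 || stats::sd(rest) < 1e-12) {
      warning("constant item or rest score: r_itc undefined for ", colnames(X)[j])
      return(NA_real_)
    }
    stats::cor(x, rest)
  }, numeric(1L))
  names(out) <- colnames(X)
  out
}

#' Loevinger's scalability coefficients H
#'
#' Mokken scalability: for an item pair, \code{H_ij = cov(X_i, X_j) /
#' covmax(X_i, X_j)} where \code{covmax} is the largest covariance
#' attainable under the two items' observed marginal category distributions
#' (the comonotone coupling of the two marginals). Item and scale
#' coefficients are ratio-of-sums aggregates: \code{H_i = sum_j cov_ij /
#' sum_j covmax_ij} over pairs containing \code{i}, and \code{H = sum cov /
#' sum covmax} over all pairs.
#'
#' @inheritParams cronbach_alpha
#' @return A list with \code{H_scale}, named \code{H_item}, and the matrix
#'   \code{H_pair}.
#' @export
loevinger_h <- function(rm, items = NULL) {
  X <- .item_matrix(rm, items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  J <- ncol(X)
  if (J < 2L) stop("need at least 2 items")
  covm <- stats::cov(X) * (nrow(X) - 1) / nrow(X)   # population covariance
  cmax <- matrix(NA_real_, J, J, dimnames = dimnames(covm))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      cm <- .covmax(X[, i], X[, j])
      if (cm < 1e-12) stop("constant item: covmax zero for pair ",
                           colnames(X)[i], ", ", colnames(X)[j])
      cmax[i, j] <- cmax[j, i] <- cm
    }
  }
  H_pair <- covm / cmax
  diag(H_pair) <- NA_real_
  num_i <- rowSums(covm * !diag(J))
  den_i <- rowSums(cmax, na.rm = TRUE)
  H_item <- num_i / den_i
  ut <- upper.tri(covm)
  list(H_scale = sum(covm[ut]) / sum(cmax[ut]),
       H_item = stats::setNames(H_item, colnames(X)),
       H_pair = H_pair)
}

# maximum covariance given both marginals: population covariance of the
# comonotone (sorted-against-sorted) coupling
.covmax <- function(x, y) {
  n <- length(x)
  mean(sort(x) * sort(y)) - mean(x) * mean(y)
}

#' Monotonicity check via rest-score groups
#'
#' For each item, persons are pooled into rest-score groups (rest score =
#' total over the other items), adjacent rest scores being merged until each
#' group holds at least \code{min_group} persons. For every category
#' boundary \code{k >= 1} the estimated \code{P(X >= k)} must be
#' non-decreasing across groups; a decreasing ordered pair of groups whose
#' drop exceeds \code{minvi} counts as a violation, and a violation is
#' "active" when a one-sided two-proportion z-test additionally rejects
#' equality at \code{alpha}. Complete cases only.
#'
#' @inheritParams cronbach_alpha
#' @param min_group minimum rest-score group size; default
#'   \code{max(50, n/10)}.
#' @param alpha significance level of the violation test.
#' @param minvi minimum violation size (drop in the estimated proportion)
#'   before a decrease is counted — screens out trivially small sampling
#'   wiggles; 0.03 is the conventional Mokken default.
#' @return A data frame per item: \code{item_id}, \code{n_groups},
#'   \code{violations} (all decreasing pairs), \code{active_violations}
#'   (significant ones).
#' @export
check_monotonicity <- function(rm, items = NULL, min_group = NULL,
                               alpha = 0.05, minvi = 0.03) {
  X <- .item_matrix(rm, items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (is.null(min_group)) min_group <- max(50, floor(n / 10))
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    rest <- rowSums(X[, -j, drop = FALSE])
    grp <- .rest_groups(rest, min_group)
    G <- max(grp)
    if (G < 2L) {
      warning("only one rest-score group for item ", colnames(X)[j],
              ": monotonicity not assessable")
      out[[j]] <- data.frame(item_id = colnames(X)[j], n_groups = G,
                             violations = 0L, active_violations = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    ng <- tabulate(grp, G)
    viol <- 0L; active <- 0L
    for (k in seq_len(max(x))) {
      p <- vapply(seq_len(G), function(g) mean(x[grp == g] >= k), numeric(1L))
      for (g1 in seq_len(G - 1L)) {
        for (g2 in (g1 + 1L):G) {
          if (p[g1] - p[g2] > minvi) {
            viol <- viol + 1L
            # one-sided z-test for p_g1 > p_g2 (higher group should be higher)
            pp <- (p[g1] * ng[g1] + p[g2] * ng[g2]) / (ng[g1] + ng[g2])
            se <- sqrt(pp * (1 - pp) * (1 / ng[g1] + 1 / ng[g2]))
            if (se > 0) {
              z <- (p[g1] - p[g2]) / se
              if (stats::pnorm(z, lower.tail = FALSE) < alpha) active <- active + 1L
            }
          }
        }
      }
    }
    out[[j]] <- data.frame(item_id = colnames(X)[j], n_groups = G,
                           violations = viol, active_violations = active,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# merge adjacent rest scores (ascending) until each group reaches min_group
.rest_groups <- function(rest, min_group) {
  lev <- sort(unique(rest))
  counts <- vapply(lev, function(l) sum(rest == l), numeric(1L))
  grp_of_lev <- integer(length(lev))
  g <- 1L; acc <- 0
  for (i in seq_along(lev)) {
    grp_of_lev[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_group && i < length(lev)) { g <- g + 1L; acc <- 0 }
  }
  # fold a trailing under-sized group into its neighbor
  if (acc < min_group && g > 1L) grp_of_lev[grp_of_lev == g] <- g - 1L
  grp <- grp_of_lev[match(rest, lev)]
  match(grp, sort(unique(grp)))
}

#' Classical test theory and Mokken summary for an item set
#'
#' Convenience wrapper bundling [cronbach_alpha()],
#' [corrected_item_total()], [loevinger_h()] and [check_monotonicity()]
#' into one report.
#'
#' @inheritParams check_monotonicity
#' @return A list of class \code{scale_eval_report} with elements
#'   \code{alpha}, \code{alpha_if_deleted}, \code{item_total_corr},
#'   \code{H_scale}, \code{H_item}, \code{H_pair}, \code{monotonicity}.
#' @export
scale_eval <- function(rm, items = NULL, min_group = NULL, alpha = 0.05,
                       minvi = 0.03) {
  ca <- cronbach_alpha(rm, items)
  h <- loevinger_h(rm, items)
  structure(list(alpha = ca$alpha,
                 alpha_if_deleted = ca$alpha_if_deleted,
                 item_total_corr = corrected_item_total(rm, items),
                 H_scale = h$H_scale, H_item = h$H_item, H_pair = h$H_pair,
                 monotonicity = check_monotonicity(rm, items, min_group, alpha,
                                                   minvi)),
            class = "scale_eval_report")
}

#' @export
print.scale_eval_report <- function(x, ...) {
  cat(sprintf("Cronbach's alpha: %.3f   Loevinger's H: %.3f\n", x$alpha, x$H_scale))
  df <- data.frame(item_id = names(x$item_total_corr),
                   r_itc = round(x$item_total_corr, 3),
                   H_i = round(x$H_item, 3),
                   alpha_delta = round(x$alpha_if_deleted, 4),
                   active_viol = x$monotonicity$active_violations)
  print(df, row.names = FALSE)
  invisible(x)
}

.item_matrix <- function(rm, items = NULL) {
  X <- if (inherits(rm, "response_matrix")) rm$responses else as.matrix(rm)
  if (!is.null(items)) {
    jj <- if (is.character(items)) match(items, colnames(X)) else as.integer(items)
    if (anyNA(jj)) stop("unknown item in selection")
    X <- X[, jj, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}
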