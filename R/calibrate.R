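#' Fit a graded response model with fixable item parameters (MML-EM)
#'
#' The central fitting function of the package. Estimates GRM item
#' parameters by marginal maximum likelihood via the EM algorithm, holding
#' any subset of items ("anchors") fixed at their supplied values. The
#' latent prior stays standard normal throughout — with anchors fixed at
#' parameters published on a reference metric this is exactly fixed-anchor
#' linking: the free items are placed on the anchors' metric.
#'
#' The E-step computes each person's posterior mass over the quadrature
#' nodes; the M-step maximizes every free item's expected complete-data
#' multinomial log-likelihood by quasi-Newton ascent with analytic
#' gradients, parameterized as \code{(log a, b_1, log increments)} so
#' threshold order is preserved by construction. Free items with unobserved
#' categories are collapsed first (recoding map recorded); anchor items are
#' never collapsed.
#'
#' @param rm a [response_matrix()] or integer response matrix (0-based
#'   codes, \code{NA} missing) whose columns cover the bank's items.
#' @param bank an [item_bank()] providing structure, anchor values and
#'   starting values; items with \code{fixed = TRUE} (or per
#'   \code{fixed}) are not updated.
#' @param grid a [make_grid()] quadrature grid.
#' @param fixed logical mask overriding \code{bank$fixed}.
#' @param tol convergence tolerance: maximum absolute parameter change.
#' @param max_cycles maximum EM cycles.
#' @param start_from_data if \code{TRUE} (default), free-item starting
#'   values are derived from observed cumulative proportions rather than
#'   taken from \code{bank}.
#' @return An object of class \code{grm_calibration}: a list with
#'   \code{bank_out} (fixed rows identical to input), \code{loglik_trace},
#'   \code{n_cycles}, \code{converged}, \code{max_param_change},
#'   \code{collapse_maps}, \code{grid}, \code{fixed}, \code{responses}.
#' @seealso [fixed_anchor_link()], [eap_score()], [s_x2_itemfit()]
#' @export
grm_calibrate <- function(rm, bank, grid = make_grid(), fixed = bank$fixed,
                          tol = 1e-4, max_cycles = 500L,
                          start_from_data = TRUE) {
  validate_item_bank(bank)
  responses <- if (inherits(rm, "response_matrix")) rm$responses else as.matrix(rm)
  if (!all(bank$item_id %in% colnames(responses))) {
    stop("response matrix is missing bank items: ",
         paste(setdiff(bank$item_id, colnames(responses)), collapse = ", "))
  }
  responses <- responses[, bank$item_id, drop = FALSE]
  .check_codes(responses, bank)
  fixed <- as.logical(fixed)
  stopifnot(length(fixed) == nrow(bank))
  free <- which(!fixed)

  # collapse unobserved categories of free items; anchors are external
  collapse_maps <- vector("list", nrow(bank))
  names(collapse_maps) <- bank$item_id
  for (j in free) {
    obs <- sort(unique(responses[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) < 2L) stop("free item ", bank$item_id[j],
                               " has fewer than 2 observed categories")
    if (length(obs) < bank$n_cat[j]) {
      map <- match(responses[, j], obs) - 1L
      responses[, j] <- as.integer(map)
      collapse_maps[[j]] <- stats::setNames(seq_along(obs) - 1L, obs)
      bank$n_cat[j] <- length(obs)
    }
  }

  th <- bank_thresholds(bank)
  if (start_from_data) {
    for (j in free) th[[j]] <- .start_values(responses[, j], bank$n_cat[j])
  }
  if (start_from_data && length(free)) bank$slope[free] <- 1

  psi <- lapply(seq_len(nrow(bank)), function(j) {
    .to_psi(bank$slope[j], th[[j]])
  })
  # fixed items bypass the reparameterization round-trip entirely
  fixed_vals <- lapply(which(fixed), function(j) list(a = bank$slope[j], b = th[[j]]))
  names(fixed_vals) <- as.character(which(fixed))

  nodes <- grid$nodes
  logw <- log(grid$weights)
  trace <- numeric(0)
  converged <- FALSE
  max_change <- Inf
  cycle <- 0L

  repeat {
    cur_bank <- .psi_bank(bank, psi, fixed_vals)
    ll <- .loglik_matrix(responses, cur_bank, nodes)
    lw <- sweep(ll, 2L, logw, "+")
    mx <- apply(lw, 1L, max)
    post <- exp(lw - mx)
    rs <- rowSums(post)
    trace <- c(trace, sum(mx + log(rs)))
    post <- post / rs
    if (!length(free) || cycle >= max_cycles) {
      converged <- !length(free)
      break
    }
    cycle <- cycle + 1L
    change <- 0
    for (j in free) {
      x <- responses[, j]
      obsr <- !is.na(x)
      m <- bank$n_cat[j]
      # expected category counts at each node: q x m
      R <- vapply(0:(m - 1L), function(k) colSums(post[obsr & x == k, , drop = FALSE]),
                  numeric(length(nodes)))
      old_nat <- .from_psi(psi[[j]])
      opt <- stats::optim(psi[[j]], fn = .item_negll, gr = .item_neggrad,
                          R = R, nodes = nodes, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12))
      psi[[j]] <- opt$par
      new_nat <- .from_psi(psi[[j]])
      change <- max(change, max(abs(new_nat - old_nat)))
    }
    max_change <- change
    if (change < tol) {
      # one final E-step below records the post-update loglik
      cur_bank <- .psi_bank(bank, psi, fixed_vals)
      ll <- .loglik_matrix(responses, cur_bank, nodes)
      lw <- sweep(ll, 2L, logw, "+")
      mx <- apply(lw, 1L, max)
      trace <- c(trace, sum(mx + log(rowSums(exp(lw - mx)))))
      converged <- TRUE
      break
    }
  }

  out_bank <- .psi_bank(bank, psi, fixed_vals)
  # fixed rows byte-identical to the input
  structure(list(bank_out = out_bank,
                 loglik_trace = trace,
                 n_cycles = cycle,
                 converged = converged,
                 max_param_change = max_change,
                 collapse_maps = collapse_maps,
                 grid = grid,
                 fixed = fixed,
                 responses = responses,
                 call = match.call()),
            class = "grm_calibration")
}

# reparameterization: psi = (log a, b1, log diff(b))
.to_psi <- function(a, b) {
  if (length(b) > 1L) c(log(a), b[1L], log(diff(b))) else c(log(a), b[1L])
}
.psi_params <- function(psi) {
  a <- exp(psi[1L])
  b <- psi[2L]
  if (length(psi) > 2L) b <- b + c(0, cumsum(exp(psi[-(1:2)])))
  list(a = a, b = b)
}
.from_psi <- function(psi) {
  p <- .psi_params(psi)
  c(p$a, p$b)
}
.psi_bank <- function(bank, psi, fixed_vals = list()) {
  th <- vector("list", nrow(bank))
  for (j in seq_len(nrow(bank))) {
    fv <- fixed_vals[[as.character(j)]]
    if (!is.null(fv)) {
      bank$slope[j] <- fv$a
      th[[j]] <- fv$b
    } else {
      p <- .psi_params(psi[[j]])
      bank$slope[j] <- p$a
      th[[j]] <- p$b
    }
  }
  bcols <- grep("^b[0-9]+$", names(bank), value = TRUE)
  bm <- matrix(NA_real_, nrow(bank), length(bcols))
  for (j in seq_len(nrow(bank))) bm[j, seq_along(th[[j]])] <- th[[j]]
  bank[bcols] <- bm
  bank
}

# expected complete-data negative loglik for one item and its gradient.
# R: q x m expected counts; params psi.
.item_negll <- function(psi, R, nodes) {
  p <- .psi_params(psi)
  P <- grm_category_probs(p$a, p$b, nodes)
  -sum(R * log(P))
}

.item_neggrad <- function(psi, R, nodes) {
  p <- .psi_params(psi)
  a <- p$a; b <- p$b
  m <- length(b) + 1L
  P <- grm_category_probs(a, b, nodes)        # q x m
  W <- R / P                                   # q x m
  Fk <- stats::plogis(outer(nodes, b, function(t, bb) a * (t - bb)))  # q x (m-1)
  fk <- Fk * (1 - Fk)
  # dg/dF_k = W[, k+1] - W[, k]  (category columns are 1-based: cat k -> col k+1)
  dF <- W[, 2:m, drop = FALSE] - W[, 1:(m - 1L), drop = FALSE]  # q x (m-1)
  g_b <- colSums(dF * (-a) * fk)                                # dg/db_k
  g_a <- sum(dF * fk * outer(nodes, b, "-"))
  g_psi <- numeric(length(psi))
  g_psi[1L] <- a * g_a
  g_psi[2L] <- sum(g_b)
  if (length(psi) > 2L) {
    for (i in seq_len(length(psi) - 2L)) {
      g_psi[i + 2L] <- exp(psi[i + 2L]) * sum(g_b[(i + 1L):(m - 1L)])
    }
  }
  -g_psi
}

# monotone starting thresholds from observed cumulative proportions (a = 1)
.start_values <- function(x, m) {
  x <- x[!is.na(x)]
  n <- length(x)
  b <- vapply(seq_len(m - 1L), function(k) {
    p <- mean(x >= k)
    stats::qlogis(min(max(p, 1 / (n + 1)), n / (n + 1)))
  }, numeric(1L))
  b <- -b
  # enforce strict increase
  for (i in seq_along(b)[-1L]) b[i] <- max(b[i], b[i - 1L] + 1e-3)
  b
}

#' Fixed-anchor linking of new items onto a reference metric
#'
#' Convenience wrapper around [grm_calibrate()]: combines a supplied anchor
#' bank (parameters on the reference metric, held fixed) with free new
#' items whose starting values are derived from the data, and calibrates.
#' Because the latent prior is the reference population N(0,1) and the
#' anchors are immovable, the estimated new-item parameters land on the
#' anchors' metric.
#'
#' @param rm a [response_matrix()] containing both item sets.
#' @param anchor_bank an [item_bank()] of anchors (slopes/thresholds on the
#'   reference metric).
#' @param free_item_ids character vector of new item ids present in
#'   \code{rm}.
#' @param n_cat number of categories for the free items (default 5).
#' @param grid,tol,max_cycles passed to [grm_calibrate()].
#' @return A \code{grm_calibration}.
#' @export
fixed_anchor_link <- function(rm, anchor_bank, free_item_ids, n_cat = 5L,
                              grid = make_grid(), tol = 1e-4,
                              max_cycles = 500L) {
  validate_item_bank(anchor_bank)
  if (length(free_item_ids) < 1L) stop("no free items to calibrate")
  responses <- if (inherits(rm, "response_matrix")) rm$responses else as.matrix(rm)
  missing_anchor <- setdiff(anchor_bank$item_id, colnames(responses))
  if (length(missing_anchor)) {
    stop("anchor item absent from data: ", paste(missing_anchor, collapse = ", "))
  }
  if (!all(free_item_ids %in% colnames(responses))) {
    stop("free item absent from data: ",
         paste(setdiff(free_item_ids, colnames(responses)), collapse = ", "))
  }
  free_bank <- item_bank(item_id = free_item_ids,
                         instrument = rep("new", length(free_item_ids)),
                         slope = rep(1, length(free_item_ids)),
                         thresholds = rep(list(seq(-1.5, 1.5,
                                                   length.out = n_cat - 1L)),
                                          length(free_item_ids)),
                         fixed = rep(FALSE, length(free_item_ids)))
  anchor_bank$fixed <- TRUE
  bank <- rbind(anchor_bank, free_bank)
  class(bank) <- c("item_bank", "data.frame")
  grm_calibrate(rm, bank, grid = grid, tol = tol, max_cycles = max_cycles)
}

#' @export
print.grm_calibration <- function(x, ...) {
  nf <- sum(!x$fixed)
  cat("Fixed-anchor GRM calibration\n")
  cat(sprintf("  %d items (%d fixed, %d free), %d persons\n",
              nrow(x$bank_out), sum(x$fixed), nf, nrow(x$responses)))
  cat(sprintf("  %d EM cycles, %s (max parameter change %.2g)\n",
              x$n_cycles, if (x$converged) "converged" else "NOT converged",
              x$max_param_change))
  cat(sprintf("  marginal log-likelihood: %.3f\n", utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' @export
summary.grm_calibration <- function(object, ...) {
  b <- object$bank_out
  b$fixed <- object$fixed
  structure(list(bank = b, converged = object$converged,
                 n_cycles = object$n_cycles,
                 loglik = utils::tail(object$loglik_trace, 1),
                 collapsed = Filter(Negate(is.null), object$collapse_maps)),
            class = "summary.grm_calibration")
}

#' @export
print.summary.grm_calibration <- function(x, ...) {
  cat("Item parameters (reference metric):\n")
  print(as.data.frame(x$bank), row.names = FALSE)
  cat(sprintf("\nlog-likelihood %.3f after %d cycles (%s)\n", x$loglik,
              x$n_cycles, if (x$converged) "converged" else "not converged"))
  if (length(x$collapsed)) {
    cat("Collapsed categories:", paste(names(x$collapsed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.grm_calibration <- function(object, ...) {
  b <- object$bank_out
  bcols <- grep("^b[0-9]+$", names(b), value = TRUE)
  out <- as.matrix(b[, c("slope", bcols)])
  rownames(out) <- b$item_id
  out
}

#' @export
logLik.grm_calibration <- function(object, ...) {
  npar <- sum((object$bank_out$n_cat[!object$fixed]))  # a + (m-1) thresholds each
  structure(utils::tail(object$loglik_trace, 1), df = npar,
            nobs = nrow(object$responses), class = "logLik")
}

#' @export
predict.grm_calibration <- function(object, newdata = NULL, ...) {
  resp <- if (is.null(newdata)) object$responses
          else if (inherits(newdata, "response_matrix")) newdata$responses
          else as.matrix(newdata)
  eap_score(resp, object$bank_out, object$grid)
}

#' @importFrom stats simulate
#' @export
simulate.grm_calibration <- function(object, nsim = 1, seed = NULL,
                                     n = nrow(object$responses), ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_unidimensional(object$bank_out, n = n,
                            seed = (seed %||% 1L) + i - 1L)
  })
  if (nsim == 1) out[[1L]] else out
}

#' @export
plot.grm_calibration <- function(x, type = c("trace", "icc"), item = 1L, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                   xlab = "EM cycle", ylab = "marginal log-likelihood", ...)
  } else {
    b <- x$bank_out
    j <- if (is.character(item)) match(item, b$item_id) else item
    th <- bank_thresholds(b)[[j]]
    theta <- seq(-4, 4, length.out = 201)
    P <- grm_category_probs(b$slope[j], th, theta)
    graphics::matplot(theta, P, type = "l", lty = 1,
                      xlab = expression(theta), ylab = "category probability",
                      main = b$item_id[j], ...)
  }
  invisible(x)
}
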