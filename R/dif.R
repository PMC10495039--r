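#' Proportional-odds (cumulative logit) model fit
#'
#' Maximum-likelihood fit of the ordinal logistic regression used for DIF
#' screening, via \code{MASS::polr}. Covariate matrices are checked for
#' rank deficiency before fitting; an intercept-only fit is supported (its
#' log-likelihood equals the saturated-margins multinomial value
#' \code{sum n_k log(n_k / n)}). Coefficients larger than \code{sep_bound}
#' in absolute value trigger a separation warning.
#'
#' @param y ordinal response vector (integer codes or ordered factor) with
#'   at least 2 observed categories.
#' @param X covariate data frame / matrix, or \code{NULL} for
#'   intercept-only.
#' @param sep_bound separation detection bound on |coefficient|.
#' @return A list: \code{coefficients}, \code{cutpoints}, \code{loglik},
#'   \code{fitted_model}, \code{converged}.
#' @export
fit_proportional_odds <- function(y, X = NULL, sep_bound = 15) {
  yf <- if (is.ordered(y)) droplevels(y) else factor(y, ordered = TRUE)
  yf <- droplevels(yf)
  if (nlevels(yf) < 2L) stop("y must show at least 2 categories")
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0L)) {
    n_k <- table(yf)
    n <- sum(n_k)
    fit <- MASS::polr(yf ~ 1)
    return(list(coefficients = numeric(0), cutpoints = fit$zeta,
                loglik = as.numeric(stats::logLik(fit)),
                fitted_model = fit, converged = fit$convergence == 0))
  }
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  if (any(apply(mm[, -1L, drop = FALSE], 2L, function(c) stats::sd(c) < 1e-12))) {
    stop("constant covariate")
  }
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient covariate matrix")
  dat <- cbind(data.frame(.y = yf), X)
  fit <- MASS::polr(.y ~ ., data = dat)
  if (any(abs(stats::coef(fit)) > sep_bound)) {
    warning("possible separation: coefficient exceeds ", sep_bound)
  }
  list(coefficients = stats::coef(fit), cutpoints = fit$zeta,
       loglik = as.numeric(stats::logLik(fit)),
       fitted_model = fit, converged = fit$convergence == 0)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared rescaled to a unit maximum:
#' \code{R2 = (1 - exp((2/n)(ll0 - ll1))) / (1 - exp((2/n) ll0))}.
#'
#' @param loglik_model,loglik_null model and null log-likelihoods
#'   (\code{loglik_model >= loglik_null}).
#' @param n sample size.
#' @return R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_model < loglik_null - 1e-8) {
    stop("loglik_model must be >= loglik_null")
  }
  (1 - exp((2 / n) * (loglik_null - loglik_model))) /
    (1 - exp((2 / n) * loglik_null))
}

#' Differential item functioning scan by ordinal logistic regression
#'
#' Per item, three nested proportional-odds models are fitted: m1 (trait),
#' m2 (trait + group), m3 (trait + group + trait:group). Likelihood-ratio
#' p-values test uniform (m2 vs m1), non-uniform (m3 vs m2) and total
#' (m3 vs m1) DIF; the effect size is the Nagelkerke pseudo R-squared
#' change \code{R2(m3) - R2(m1)} (both against the intercept-only null),
#' and items with change above \code{threshold} are flagged. Multi-level
#' groups enter as indicator sets, so the R-squared change is joint.
#'
#' @param rm a [response_matrix()] or matrix.
#' @param items item ids/indices to scan (default all).
#' @param group grouping variable: a vector, or the name of a covariate
#'   column of \code{rm}.
#' @param trait_scores per-person conditioning trait scores (typically the
#'   EAP scores from the fixed-anchor calibration).
#' @param threshold flagging threshold on the R-squared change
#'   (default 0.03).
#' @return A data frame, one row per item: log-likelihoods, LR p-values,
#'   \code{r2_m1}, \code{r2_m3}, \code{r2_change}, \code{flagged}.
#' @export
dif_scan <- function(rm, items = NULL, group, trait_scores, threshold = 0.03) {
  X <- .item_matrix(rm, items)
  if (is.character(group) && length(group) == 1L) {
    if (!inherits(rm, "response_matrix") || is.null(rm$covariates[[group]])) {
      stop("covariate '", group, "' not found")
    }
    group <- rm$covariates[[group]]
  }
  g <- factor(group)
  if (nlevels(g) < 2L) stop("group must have at least 2 levels")
  if (any(table(g) < 10L)) warning("group level with fewer than 10 respondents")
  if (length(trait_scores) != nrow(X)) stop("trait_scores must match persons")
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    ok <- !is.na(X[, j]) & !is.na(trait_scores) & !is.na(g)
    y <- factor(X[ok, j], ordered = TRUE)
    y <- droplevels(y)
    d <- data.frame(theta = trait_scores[ok], g = droplevels(g[ok]))
    n <- sum(ok)
    ll0 <- fit_proportional_odds(y, NULL)$loglik
    m1 <- MASS::polr(y ~ theta, data = d)
    m2 <- MASS::polr(y ~ theta + g, data = d)
    m3 <- MASS::polr(y ~ theta * g, data = d)
    ll1 <- as.numeric(stats::logLik(m1))
    ll2 <- as.numeric(stats::logLik(m2))
    ll3 <- as.numeric(stats::logLik(m3))
    dfg <- nlevels(d$g) - 1L
    r2_1 <- nagelkerke_r2(ll1, ll0, n)
    r2_3 <- nagelkerke_r2(max(ll3, ll1), ll0, n)
    r2c <- max(r2_3 - r2_1, 0)
    out[[j]] <- data.frame(
      item_id = colnames(X)[j],
      loglik_m1 = ll1, loglik_m2 = ll2, loglik_m3 = ll3,
      lr_p_uniform = stats::pchisq(2 * max(ll2 - ll1, 0), dfg, lower.tail = FALSE),
      lr_p_nonuniform = stats::pchisq(2 * max(ll3 - ll2, 0), dfg, lower.tail = FALSE),
      lr_p_total = stats::pchisq(2 * max(ll3 - ll1, 0), 2L * dfg, lower.tail = FALSE),
      r2_m1 = r2_1, r2_m3 = r2_3, r2_change = r2c,
      flagged = r2c > threshold,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
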