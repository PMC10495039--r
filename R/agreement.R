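#' Paired standardized mean difference
#'
#' \code{SMD = mean(a - b) / sd(a - b)} — the mean paired difference in
#' units of the SD of the paired differences (stated prominently because
#' pooled-SD variants of the paired SMD differ). The 95\% CI uses the
#' normal approximation \code{smd +/- 1.96 sqrt(1/n + smd^2 / (2n))}; a
#' nonparametric bootstrap CI is available as an option. Identical inputs
#' give SMD exactly 0 (perfect agreement).
#'
#' @param a,b paired score vectors of equal length.
#' @param ci_type \code{"normal"} (default) or \code{"bootstrap"}.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return A list: \code{smd}, \code{ci} (length 2), \code{n}.
#' @export
paired_smd <- function(a, b, ci_type = c("normal", "bootstrap"), B = 2000L,
                       seed = 1L) {
  ci_type <- match.arg(ci_type)
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s < 1e-12) {
    if (abs(mean(d)) < 1e-12) return(list(smd = 0, ci = c(0, 0), n = n))
    stop("degenerate difference SD with nonzero mean difference")
  }
  smd <- mean(d) / s
  ci <- if (ci_type == "normal") {
    smd + c(-1, 1) * 1.96 * sqrt(1 / n + smd^2 / (2 * n))
  } else {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    reps <- replicate(B, {
      i <- sample.int(n, replace = TRUE)
      di <- d[i]
      if (stats::sd(di) < 1e-12) 0 else mean(di) / stats::sd(di)
    })
    as.numeric(stats::quantile(reps, c(0.025, 0.975)))
  }
  list(smd = smd, ci = ci, n = n)
}

#' Bland-Altman agreement summary
#'
#' Mean difference, SD of differences, 95\% limits of agreement
#' (mean +/- 1.96 SD), and the least-squares trend of the difference on the
#' pair average (a proportional-bias check) with its p-value.
#'
#' @inheritParams paired_smd
#' @return A list: \code{mean_diff}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{trend_slope}, \code{trend_p}.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  avg <- (a + b) / 2
  md <- mean(d); s <- stats::sd(d)
  if (stats::sd(avg) < 1e-12 || s < 1e-12) {
    # constant differences or constant averages: no trend to estimate
    slope <- 0; p <- NA_real_
  } else {
    fit <- stats::lm(d ~ avg)
    cf <- summary(fit)$coefficients
    slope <- cf["avg", "Estimate"]
    p <- cf["avg", "Pr(>|t|)"]
  }
  list(mean_diff = md, sd_diff = s,
       loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       trend_slope = slope, trend_p = p)
}

.smd_label <- function(smd) {
  s <- abs(smd)
  if (s < 0.2) "negligible" else if (s < 0.5) "small"
  else if (s < 0.8) "medium" else "large"
}

#' Subgroup agreement report
#'
#' Paired SMD with CI for the full sample and within each stratum, with
#' effect-size labels at the conventional 0.2 / 0.5 / 0.8 cuts (negligible,
#' small, medium, large). Strata smaller than 3 are reported with their n
#' but without SMD/CI.
#'
#' @inheritParams paired_smd
#' @param strata per-person stratum labels.
#' @return A data frame: \code{stratum}, \code{n}, \code{mean_a},
#'   \code{mean_b}, \code{smd}, \code{ci_low}, \code{ci_high},
#'   \code{label}.
#' @export
subgroup_agreement <- function(a, b, strata) {
  if (length(a) != length(b) || length(strata) != length(a)) {
    stop("length mismatch")
  }
  strata <- factor(strata)
  one <- function(idx, name) {
    n <- sum(idx)
    if (n < 3L) {
      return(data.frame(stratum = name, n = n, mean_a = mean(a[idx]),
                        mean_b = mean(b[idx]), smd = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        label = NA_character_, stringsAsFactors = FALSE))
    }
    s <- paired_smd(a[idx], b[idx])
    data.frame(stratum = name, n = n, mean_a = mean(a[idx]),
               mean_b = mean(b[idx]), smd = s$smd, ci_low = s$ci[1L],
               ci_high = s$ci[2L], label = .smd_label(s$smd),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(rep(TRUE, length(a)), "Full sample"),
               do.call(rbind, lapply(levels(strata),
                                     function(l) one(strata == l, l))))
  rownames(out) <- NULL
  out
}

#' Ceiling and floor rates
#'
#' Fraction of persons at the instrument's maximum (ceiling) and minimum
#' (floor) attainable score. Short instruments saturate sooner: a high
#' ceiling rate signals a restricted measurement range.
#'
#' @param scores per-person scores.
#' @param max_score,min_score the attainable extremes (from the item bank).
#' @param tol numeric tolerance for "at the bound".
#' @return A list \code{ceiling}, \code{floor} (proportions in [0, 1]).
#' @export
ceiling_floor <- function(scores, max_score, min_score, tol = 1e-8) {
  list(ceiling = mean(scores >= max_score - tol),
       floor = mean(scores <= min_score + tol))
}

#' Correlation of score differences with covariates
#'
#' Pearson correlation of the paired difference \code{a - b} with each
#' covariate — a check for nuisance variables (e.g. pain, depression) that
#' bias self-report relative to performance.
#'
#' @inheritParams paired_smd
#' @param covariates data frame aligned to persons.
#' @return Named numeric vector of correlations.
#' @export
diff_covariate_corr <- function(a, b, covariates) {
  d <- a - b
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(d)) stop("covariates must align to persons")
  out <- vapply(covariates, function(x) {
    if (stats::sd(x, na.rm = TRUE) < 1e-12) stop("constant covariate")
    stats::cor(d, x, use = "complete.obs")
  }, numeric(1L))
  out
}
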