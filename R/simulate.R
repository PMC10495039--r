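#' Construct a response matrix object
#'
#' Bundles a persons x items matrix of 0-based ordinal codes (\code{NA} =
#' missing) with optional person covariates and, for synthetic data, the true
#' latent traits used to generate it.
#'
#' @param responses integer matrix, columns named by item id.
#' @param covariates optional data frame with one row per person.
#' @param true_theta optional numeric vector (or matrix of general/specific
#'   factor scores) of generating trait values.
#' @return A list of class \code{response_matrix}.
#' @export
response_matrix <- function(responses, covariates = NULL, true_theta = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses))) stop("responses must have item-id column names")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(responses)) stop("covariates must match persons")
  }
  structure(list(responses = responses, covariates = covariates,
                 true_theta = true_theta),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d persons x %d items, %.1f%% missing%s%s>\n",
              nrow(x$responses), ncol(x$responses),
              100 * mean(is.na(x$responses)),
              if (!is.null(x$covariates))
                paste0(", covariates: ", paste(names(x$covariates), collapse = ", "))
              else "",
              if (!is.null(x$true_theta)) ", true theta stored" else ""))
  invisible(x)
}

.check_codes <- function(responses, bank) {
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    bad <- which(!is.na(x) & (x < 0 | x >= bank$n_cat[j]))
    if (length(bad)) {
      stop("response code out of range at row ", bad[1L], ", item ",
           colnames(responses)[j])
    }
  }
  invisible(TRUE)
}

#' Simulate responses from a unidimensional logistic GRM
#'
#' Draws latent traits from \code{N(theta_mean, theta_sd^2)} and, for each
#' person and item, a 0-based category from the GRM category probabilities at
#' that trait value.
#'
#' @param bank an [item_bank()].
#' @param n number of persons.
#' @param theta_mean,theta_sd latent trait distribution; defaults to the
#'   reference population N(0, 1).
#' @param seed integer seed; output is reproducible given the seed.
#' @return A [response_matrix()] with \code{true_theta} stored.
#' @export
simulate_unidimensional <- function(bank, n, theta_mean = 0, theta_sd = 1,
                                    seed = 1L) {
  validate_item_bank(bank)
  if (nrow(bank) < 1L) stop("empty bank")
  if (theta_sd < 0) stop("theta_sd must be >= 0")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  theta <- stats::rnorm(n, theta_mean, theta_sd)
  resp <- .draw_grm(bank, theta)
  response_matrix(resp, true_theta = theta)
}

.draw_grm <- function(bank, theta) {
  th <- bank_thresholds(bank)
  n <- length(theta)
  resp <- matrix(NA_integer_, n, nrow(bank),
                 dimnames = list(NULL, bank$item_id))
  for (j in seq_len(nrow(bank))) {
    # X_ij = #{k : U < P*(>= k)} via one uniform per person (inverse cdf)
    cum <- stats::plogis(outer(theta, th[[j]], function(t, b) bank$slope[j] * (t - b)))
    u <- stats::runif(n)
    resp[, j] <- as.integer(rowSums(u < cum))
  }
  resp
}

#' Simulation scenario for bifactor-structured ordinal data
#'
#' Describes a general + specific ("bifactor") latent structure: each item's
#' standardized propensity is \code{lambda_g G + lambda_s S_{g(j)} + u e}
#' with \code{G}, the \code{S}'s and \code{e} independent standard normal and
#' \code{u = sqrt(1 - lambda_g^2 - lambda_s^2)}, then cut at the item
#' thresholds into ordinal codes (a normal-ogive formulation, natural for the
#' loading parameterization consumed by factor-analytic diagnostics).
#'
#' @param n_persons number of persons.
#' @param general_loadings per-item loadings on the general factor, in [0,1).
#' @param specific_loadings per-item loadings on the item's specific factor,
#'   in [0,1); per item the squared loadings must sum to < 1.
#' @param specific_groups list of item-id (or index) vectors partitioning the
#'   items into specific factors; items left out load on no specific factor.
#' @param seed integer seed.
#' @return A list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(n_persons, general_loadings, specific_loadings,
                         specific_groups, seed = 1L) {
  if (any(general_loadings < 0 | general_loadings >= 1) ||
      any(specific_loadings < 0 | specific_loadings >= 1)) {
    stop("loadings must lie in [0, 1)")
  }
  if (any(general_loadings^2 + specific_loadings^2 >= 1)) {
    stop("communality constraint violated: lambda_g^2 + lambda_s^2 must be < 1")
  }
  structure(list(n_persons = n_persons, general_loadings = general_loadings,
                 specific_loadings = specific_loadings,
                 specific_groups = specific_groups, seed = seed),
            class = "sim_scenario")
}

#' Simulate ordinal responses with bifactor structure
#'
#' @param bank an [item_bank()] supplying thresholds (cut points on the
#'   standardized propensity scale) and item ids.
#' @param scenario a [sim_scenario()].
#' @return A [response_matrix()]; \code{true_theta} stores the general factor
#'   scores, with specific factor scores as an attribute
#'   \code{"specific_scores"}.
#' @export
simulate_bifactor <- function(bank, scenario) {
  validate_item_bank(bank)
  J <- nrow(bank)
  lg <- rep_len(scenario$general_loadings, J)
  ls <- rep_len(scenario$specific_loadings, J)
  if (any(lg^2 + ls^2 >= 1)) stop("communality constraint violated")
  groups <- scenario$specific_groups
  gidx <- rep(NA_integer_, J)
  for (s in seq_along(groups)) {
    members <- groups[[s]]
    jj <- if (is.character(members)) match(members, bank$item_id) else as.integer(members)
    if (anyNA(jj)) stop("unknown item in specific_groups")
    if (any(!is.na(gidx[jj]))) stop("specific_groups must not overlap")
    gidx[jj] <- s
  }
  n <- scenario$n_persons
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(scenario$seed))
  G <- stats::rnorm(n)
  S <- matrix(stats::rnorm(n * length(groups)), n, max(1L, length(groups)))
  th <- bank_thresholds(bank)
  resp <- matrix(NA_integer_, n, J, dimnames = list(NULL, bank$item_id))
  for (j in seq_len(J)) {
    sj <- if (is.na(gidx[j])) 0 else ls[j] * S[, gidx[j]]
    u <- sqrt(1 - lg[j]^2 - (if (is.na(gidx[j])) 0 else ls[j]^2))
    z <- lg[j] * G + sj + u * stats::rnorm(n)
    resp[, j] <- as.integer(rowSums(outer(z, th[[j]], ">")))
  }
  out <- response_matrix(resp, true_theta = G)
  attr(out$true_theta, "specific_scores") <- S
  out
}

#' Attach covariates correlated with the PRO-PerfO score difference
#'
#' Builds, for each requested covariate, a standard-normal-marginal variable
#' whose population correlation with the person's standardized
#' (anchor-instrument minus new-instrument) score difference equals
#' \code{target_r}. The difference is operationalized as the z-scored
#' difference of the two instruments' standardized mean item scores, so it is
#' defined for any response matrix.
#'
#' @param rm a [response_matrix()] containing both instruments.
#' @param bank the generating [item_bank()] (supplies the instrument split).
#' @param target_r named numeric vector of target correlations, e.g.
#'   \code{c(pain = 0.22, depression = 0.28)}; each in (-1, 1).
#' @param seed integer seed.
#' @return The response matrix with the covariates appended.
#' @export
attach_difference_covariates <- function(rm, bank, target_r, seed = 1L) {
  if (any(abs(target_r) >= 1)) stop("|target_r| must be < 1")
  d <- .instrument_difference(rm, bank)
  if (stats::sd(d) < 1e-12) stop("degenerate PRO-PerfO difference variance")
  z <- as.numeric(scale(d))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  covs <- as.data.frame(lapply(target_r, function(r) {
    r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  }))
  names(covs) <- names(target_r)
  rm$covariates <- if (is.null(rm$covariates)) covs else cbind(rm$covariates, covs)
  rm
}

# standardized mean-score difference anchor minus new, complete-data per side
.instrument_difference <- function(rm, bank) {
  a_ids <- bank$item_id[bank$instrument == "anchor"]
  n_ids <- bank$item_id[bank$instrument == "new"]
  if (!length(a_ids) || !length(n_ids)) stop("bank must contain both instruments")
  za <- rowMeans(scale(rm$responses[, a_ids, drop = FALSE]), na.rm = TRUE)
  zn <- rowMeans(scale(rm$responses[, n_ids, drop = FALSE]), na.rm = TRUE)
  za - zn
}

#' Remove responses completely at random
#'
#' @param rm a [response_matrix()].
#' @param rate missingness probability in [0, 1) applied independently per
#'   cell.
#' @param items item ids (or indices) eligible for missingness; default all.
#' @param seed integer seed.
#' @return The response matrix with cells blanked.
#' @export
apply_missingness <- function(rm, rate, items = colnames(rm$responses), seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(rm)
  jj <- if (is.character(items)) match(items, colnames(rm$responses)) else as.integer(items)
  if (anyNA(jj)) stop("unknown item in items")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  n <- nrow(rm$responses)
  for (j in jj) {
    drop <- stats::runif(n) < rate
    rm$responses[drop, j] <- NA_integer_
  }
  rm
}

#' Read / write response matrices
#'
#' Responses are exchanged as CSV with a header row of item ids; missing
#' cells are empty fields. Covariate columns (any column whose name is not a
#' bank item id, when a bank is supplied, or names listed in
#' \code{covariate_cols}) are carried alongside.
#'
#' @param rm a [response_matrix()].
#' @param path file path.
#' @param bank optional [item_bank()] used to validate codes on read and to
#'   split item from covariate columns.
#' @param covariate_cols optional character vector naming covariate columns.
#' @return \code{read_responses} returns a [response_matrix()].
#' @export
write_responses <- function(rm, path) {
  df <- as.data.frame(rm$responses)
  if (!is.null(rm$covariates)) df <- cbind(df, rm$covariates)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, bank = NULL, covariate_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(bank)) {
    item_cols <- intersect(bank$item_id, names(df))
    if (length(item_cols) != nrow(bank)) {
      stop("response file is missing items: ",
           paste(setdiff(bank$item_id, names(df)), collapse = ", "))
    }
    cov_cols <- setdiff(names(df), item_cols)
  } else {
    cov_cols <- covariate_cols %||% character(0)
    item_cols <- setdiff(names(df), cov_cols)
  }
  resp <- as.matrix(df[item_cols])
  if (!is.numeric(resp)) stop("non-numeric response codes in ", path)
  storage.mode(resp) <- "integer"
  out <- response_matrix(resp,
                         covariates = if (length(cov_cols)) df[cov_cols] else NULL)
  if (!is.null(bank)) .check_codes(out$responses[, bank$item_id, drop = FALSE], bank)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
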