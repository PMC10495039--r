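#' Build a sum-score to T-score crosswalk table
#'
#' Summed-score EAP tabulation: for each attainable sum score \code{s} over
#' the designated item subset, the posterior over the quadrature nodes is
#' proportional to \code{P(S = s | theta_q) w_q} with \code{P(S = s |
#' theta)} from the Lord-Wingersky recursion; the table records the
#' posterior mean (theta), posterior SD (se) and \code{T = 10 theta + 50}.
#' Crosswalk thetas are strictly increasing in the sum score (the GRM sum
#' score is monotone-likelihood-ratio in theta); this is asserted on every
#' built table.
#'
#' @param bank an [item_bank()] restricted to the crosswalk's item subset
#'   (calibrated on the reference metric).
#' @param grid a [make_grid()] grid.
#' @return A data frame of class \code{crosswalk} with columns
#'   \code{sum_score}, \code{theta}, \code{se}, \code{t_score}; attributes
#'   \code{item_subset}, \code{bank_hash}, \code{grid_settings}.
#' @export
build_crosswalk <- function(bank, grid = make_grid()) {
  validate_item_bank(bank)
  f <- lw_sumscore_dist(bank, grid$nodes)       # q x S
  mass <- f * grid$weights
  tot <- colSums(mass)
  theta <- as.numeric(crossprod(mass, grid$nodes)) / tot
  m2 <- as.numeric(crossprod(mass, grid$nodes^2)) / tot
  se <- sqrt(pmax(m2 - theta^2, 0))
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("crosswalk theta not strictly increasing in sum score")
  }
  out <- data.frame(sum_score = 0:(ncol(f) - 1L), theta = theta, se = se,
                    t_score = to_tscore(theta))
  attr(out, "item_subset") <- bank$item_id
  attr(out, "bank_hash") <- bank_hash(bank)
  attr(out, "grid_settings") <- c(n_nodes = length(grid$nodes),
                                  span = max(grid$nodes))
  class(out) <- c("crosswalk", "data.frame")
  out
}

#' Convert raw responses or sum scores to linked T-scores
#'
#' Persons with complete responses on the crosswalk's item subset are scored
#' by table lookup of their sum score; persons with incomplete subsets are
#' scored by pattern EAP under the same bank (method recorded per person).
#' A plain numeric vector of sum scores is always scored by lookup.
#'
#' @param x a [response_matrix()], response matrix, or numeric vector of sum
#'   scores.
#' @param crosswalk a [build_crosswalk()] table.
#' @param bank the [item_bank()] for the crosswalk subset (required for the
#'   pattern-EAP fallback).
#' @param grid a [make_grid()] grid for the fallback.
#' @return A data frame: \code{sum_score} (NA when incomplete),
#'   \code{theta_eap}, \code{se_eap}, \code{t_score}, \code{method}
#'   (\code{"crosswalk"} or \code{"pattern_eap"}).
#' @export
convert_scores <- function(x, crosswalk, bank = NULL, grid = make_grid()) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (any(!(x %in% crosswalk$sum_score))) stop("sum score outside table range")
    i <- match(x, crosswalk$sum_score)
    return(data.frame(sum_score = x, theta_eap = crosswalk$theta[i],
                      se_eap = crosswalk$se[i], t_score = crosswalk$t_score[i],
                      method = "crosswalk", stringsAsFactors = FALSE))
  }
  responses <- if (inherits(x, "response_matrix")) x$responses else as.matrix(x)
  items <- attr(crosswalk, "item_subset")
  if (!all(items %in% colnames(responses))) {
    stop("responses are missing crosswalk items")
  }
  responses <- responses[, items, drop = FALSE]
  complete <- !apply(is.na(responses), 1L, any)
  out <- data.frame(sum_score = rep(NA_integer_, nrow(responses)),
                    theta_eap = NA_real_, se_eap = NA_real_,
                    t_score = NA_real_, method = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(complete)) {
    s <- rowSums(responses[complete, , drop = FALSE])
    i <- match(s, crosswalk$sum_score)
    out$sum_score[complete] <- as.integer(s)
    out$theta_eap[complete] <- crosswalk$theta[i]
    out$se_eap[complete] <- crosswalk$se[i]
    out$t_score[complete] <- crosswalk$t_score[i]
    out$method[complete] <- "crosswalk"
  }
  if (any(!complete)) {
    if (is.null(bank)) stop("bank required to score incomplete patterns")
    sc <- eap_score(responses[!complete, , drop = FALSE], bank, grid)
    out$theta_eap[!complete] <- sc$theta_eap
    out$se_eap[!complete] <- sc$se_eap
    out$t_score[!complete] <- sc$t_score
    out$method[!complete] <- "pattern_eap"
  }
  out
}

#' Convert T-scores back to the nearest attainable sum score
#'
#' Serves the reverse direction of the crosswalk: each T-score maps to the
#' sum score whose tabulated T is nearest in absolute difference, ties going
#' to the lower sum score.
#'
#' @param t_scores numeric vector.
#' @param crosswalk a [build_crosswalk()] table.
#' @return Integer vector of sum scores.
#' @export
tscore_to_sumscore <- function(t_scores, crosswalk) {
  vapply(t_scores, function(t) {
    d <- abs(crosswalk$t_score - t)
    crosswalk$sum_score[which(d == min(d))[1L]]
  }, integer(1L))
}

#' Read / write crosswalk tables
#'
#' CSV with leading \code{#} comment lines recording the item subset, the
#' anchor-bank hash and the grid settings for provenance.
#'
#' @param crosswalk a \code{crosswalk}.
#' @param path file path.
#' @return \code{read_crosswalk} returns a \code{crosswalk} (provenance
#'   attributes restored).
#' @export
write_crosswalk <- function(crosswalk, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# item_subset: ", paste(attr(crosswalk, "item_subset"), collapse = ",")),
    paste0("# bank_hash: ", attr(crosswalk, "bank_hash")),
    paste0("# grid: n_nodes=", attr(crosswalk, "grid_settings")[["n_nodes"]],
           " span=", attr(crosswalk, "grid_settings")[["span"]])), con)
  utils::write.csv(.format_full(as.data.frame(crosswalk)), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  out <- utils::read.csv(path, comment.char = "#")
  pick <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1L]) else NA_character_
  }
  attr(out, "item_subset") <- strsplit(pick("item_subset"), ",")[[1L]]
  attr(out, "bank_hash") <- pick("bank_hash")
  class(out) <- c("crosswalk", "data.frame")
  out
}
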