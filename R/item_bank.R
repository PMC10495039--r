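#' Construct an item bank
#'
#' An item bank holds, for every item, the graded-response-model (GRM)
#' parameters on the reference metric: a positive logistic discrimination
#' (slope) \code{a_j} and strictly increasing category thresholds
#' \code{b_j1 < ... < b_j,m-1} for an item with \code{m} ordered categories.
#' Items flagged \code{fixed} are anchors whose parameters are held at their
#' supplied values during calibration; free items are (re-)estimated.
#'
#' @param item_id character vector of unique item identifiers.
#' @param instrument character vector, one of \code{"anchor"} or \code{"new"}
#'   per item.
#' @param slope positive numeric vector of discriminations.
#' @param thresholds list of numeric vectors, one per item, each strictly
#'   increasing; item \code{j} then has \code{length(thresholds[[j]]) + 1}
#'   response categories.
#' @param fixed logical vector; \code{TRUE} for items whose parameters are
#'   anchored.
#'
#' @return A data frame of class \code{item_bank} with columns
#'   \code{item_id}, \code{instrument}, \code{n_cat}, \code{slope},
#'   \code{b1..b<k>} (threshold columns, \code{NA}-padded for items with fewer
#'   categories) and \code{fixed}.
#' @seealso [make_item_bank()], [read_item_bank()], [grm_category_probs()]
#' @export
item_bank <- function(item_id, instrument, slope, thresholds, fixed) {
  n <- length(item_id)
  if (anyDuplicated(item_id)) stop("duplicate item_id")
  if (length(instrument) != n || length(slope) != n ||
      length(thresholds) != n || length(fixed) != n) {
    stop("all item bank fields must have one entry per item")
  }
  if (!all(instrument %in% c("anchor", "new"))) {
    stop("instrument must be 'anchor' or 'new'")
  }
  if (any(!is.finite(slope)) || any(slope <= 0)) stop("slopes must be positive")
  n_cat <- vapply(thresholds, length, integer(1L)) + 1L
  if (any(n_cat < 2L)) stop("each item needs at least one threshold (>= 2 categories)")
  ok <- vapply(thresholds, function(b) all(is.finite(b)) && !is.unsorted(b, strictly = TRUE),
               logical(1L))
  if (!all(ok)) stop("thresholds must be finite and strictly increasing")
  kmax <- max(n_cat) - 1L
  bmat <- t(vapply(thresholds, function(b) c(b, rep(NA_real_, kmax - length(b))),
                   numeric(kmax)))
  colnames(bmat) <- paste0("b", seq_len(kmax))
  out <- data.frame(item_id = as.character(item_id),
                    instrument = instrument,
                    n_cat = n_cat,
                    slope = as.numeric(slope),
                    bmat,
                    fixed = as.logical(fixed),
                    stringsAsFactors = FALSE)
  class(out) <- c("item_bank", "data.frame")
  out
}

#' Extract per-item threshold vectors from an item bank
#'
#' @param bank an \code{item_bank}.
#' @return Named list of numeric threshold vectors, one per item.
#' @export
bank_thresholds <- function(bank) {
  bcols <- grep("^b[0-9]+$", names(bank), value = TRUE)
  bm <- as.matrix(bank[bcols])
  out <- lapply(seq_len(nrow(bank)), function(j) {
    b <- bm[j, seq_len(bank$n_cat[j] - 1L)]
    as.numeric(b)
  })
  names(out) <- bank$item_id
  out
}

validate_item_bank <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  th <- bank_thresholds(bank)
  ok <- vapply(th, function(b) all(is.finite(b)) && !is.unsorted(b, strictly = TRUE),
               logical(1L))
  if (!all(ok)) stop("invalid item bank: thresholds not strictly increasing")
  if (any(bank$slope <= 0)) stop("invalid item bank: non-positive slope")
  invisible(bank)
}

#' Generate a random item bank fixture
#'
#' Draws a bank of \code{n_anchor} anchor (fixed) items followed by
#' \code{n_new} free items, each with \code{n_cat} ordered categories. Slopes
#' are drawn uniformly within \code{slope_range}; each item's thresholds are
#' \code{n_cat - 1} sorted uniform draws within \code{threshold_span}.
#'
#' @param n_anchor,n_new item counts (either may be zero, not both).
#' @param n_cat number of response categories (>= 2), common to all items.
#' @param slope_range length-2 positive interval for slopes.
#' @param threshold_span length-2 interval for threshold draws.
#' @param seed integer seed; the bank is reproducible given the seed.
#' @param min_gap minimum spacing enforced between adjacent thresholds so
#'   generated categories are never degenerate.
#' @return An [item_bank()].
#' @examples
#' bank <- make_item_bank(4, 9, 5, c(0.8, 2.5), c(-2.5, 2.5), seed = 1)
#' table(bank$fixed)
#' @export
make_item_bank <- function(n_anchor, n_new, n_cat = 5L,
                           slope_range = c(0.8, 2.5),
                           threshold_span = c(-2.5, 2.5),
                           seed = 1L, min_gap = 0.25) {
  if (n_anchor < 0 || n_new < 0 || n_anchor + n_new < 1) {
    stop("need a positive total number of items")
  }
  if (n_cat < 2) stop("n_cat must be >= 2")
  if (slope_range[1] <= 0 || slope_range[2] < slope_range[1]) {
    stop("slope_range must be a positive, ordered interval")
  }
  if (threshold_span[2] < threshold_span[1]) stop("threshold_span inverted")
  n <- as.integer(n_anchor + n_new)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  slope <- stats::runif(n, slope_range[1], slope_range[2])
  k <- n_cat - 1L
  thresholds <- lapply(seq_len(n), function(j) {
    b <- sort(stats::runif(k, threshold_span[1], threshold_span[2]))
    # enforce spacing so no category is vanishingly rare
    if (k > 1L) {
      for (i in 2:k) b[i] <- max(b[i], b[i - 1L] + min_gap)
    }
    b
  })
  ids <- c(if (n_anchor > 0) sprintf("ANCH_%d", seq_len(n_anchor)),
           if (n_new > 0) sprintf("NEW_%d", seq_len(n_new)))
  item_bank(item_id = ids,
            instrument = rep(c("anchor", "new"), c(n_anchor, n_new)),
            slope = slope,
            thresholds = thresholds,
            fixed = rep(c(TRUE, FALSE), c(n_anchor, n_new)))
}

#' Create a focal-group bank variant with uniform DIF on one item
#'
#' Returns a copy of the bank in which all thresholds of \code{item_id} are
#' shifted by \code{+shift} (uniform differential item functioning: at equal
#' trait level the focal group finds every step of that item harder, so its
#' expected item score is lower for positive shifts). The reference bank is
#' left untouched.
#'
#' @param bank an \code{item_bank}.
#' @param item_id id of the item receiving the shift.
#' @param shift threshold shift for the focal group.
#' @return The focal-group \code{item_bank}.
#' @export
inject_dif <- function(bank, item_id, shift) {
  validate_item_bank(bank)
  j <- match(item_id, bank$item_id)
  if (is.na(j)) stop("unknown item: ", item_id)
  bcols <- paste0("b", seq_len(bank$n_cat[j] - 1L))
  bank[j, bcols] <- bank[j, bcols] + shift
  bank
}

#' Read / write item banks
#'
#' Banks are exchanged as CSV (columns \code{item_id, instrument, n_cat,
#' slope, b1..bK, fixed}) or JSON. Round-trips are lossless for finite values.
#'
#' @param bank an \code{item_bank}.
#' @param path file path; format chosen by extension (\code{.json} for JSON,
#'   anything else is CSV).
#' @return \code{read_item_bank} returns an \code{item_bank};
#'   \code{write_item_bank} returns \code{path} invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(bank), path, digits = NA, na = "null")
  } else {
    utils::write.csv(.format_full(as.data.frame(bank)), path, row.names = FALSE)
  }
  invisible(path)
}

# render numeric columns with full binary round-trip precision so that
# CSV -> memory -> CSV cycles are bit-identical
.format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  df
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("item_id", "instrument", "n_cat", "slope", "fixed")
  if (!all(need %in% names(df))) {
    stop("malformed item bank file: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  th <- lapply(seq_len(nrow(df)), function(j) {
    b <- as.numeric(df[j, bcols])
    b <- b[!is.na(b)]
    if (length(b) != df$n_cat[j] - 1L) {
      stop("row ", j, ": expected ", df$n_cat[j] - 1L, " thresholds, found ", length(b))
    }
    b
  })
  item_bank(df$item_id, df$instrument, df$slope, th, as.logical(df$fixed))
}

# FNV-1a hash of an item bank's parameter payload; used to stamp crosswalk
# provenance without a digest dependency.
bank_hash <- function(bank) {
  th <- bank_thresholds(bank)
  payload <- paste(bank$item_id, bank$n_cat, sprintf("%.12g", bank$slope),
                   vapply(th, function(b) paste(sprintf("%.12g", b), collapse = ","),
                          character(1L)),
                   collapse = ";")
  bytes <- utf8ToInt(payload)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
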