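## Core containers: dissimilarity tables and letter codes.

#' Construct a dissimilarity table
#'
#' A dissimilarity table records one value per unordered pair of items
#' (letters or strings). Pairs are stored in canonical order
#' (`item_a <= item_b`), so the representation is symmetric by construction.
#'
#' @param item_a,item_b Character vectors of item names (any order per row).
#' @param d Numeric dissimilarities, one per pair; must be finite.
#' @param n_trials Optional integer count of trials behind each value.
#' @return A `data.frame` of class `dissimilarity_table` with columns
#'   `item_a`, `item_b`, `d` and (if supplied) `n_trials`.
#' @examples
#' dissimilarity_table(c("B", "A"), c("A", "C"), c(1, 2))
#' @export
dissimilarity_table <- function(item_a, item_b, d, n_trials = NULL) {
  if (length(item_a) != length(item_b) || length(item_a) != length(d))
    stop_input("item_a, item_b and d must have equal length")
  if (any(!is.finite(d)))
    stop_input("dissimilarities must be finite")
  out <- canonical_pairs(item_a, item_b)
  if (any(out$item_a == out$item_b))
    stop_input("a pair must consist of two distinct items")
  out$d <- as.numeric(d)
  if (!is.null(n_trials)) out$n_trials <- as.integer(n_trials)
  key <- pair_key(out$item_a, out$item_b)
  if (anyDuplicated(key))
    stop_input("duplicate pair rows: %s",
               paste(sub("\r", "-", key[duplicated(key)]), collapse = ", "))
  class(out) <- c("dissimilarity_table", "data.frame")
  out
}

#' Convert a dissimilarity table to a full symmetric matrix
#'
#' @param dtab A [dissimilarity_table()].
#' @param items Optional item ordering; defaults to sorted unique items.
#' @param require_complete Error if any off-diagonal entry is missing.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
dissim_matrix <- function(dtab, items = NULL, require_complete = TRUE) {
  if (is.null(items)) items <- sort(unique(c(dtab$item_a, dtab$item_b)))
  m <- matrix(NA_real_, length(items), length(items),
              dimnames = list(items, items))
  diag(m) <- 0
  ia <- match(dtab$item_a, items)
  ib <- match(dtab$item_b, items)
  if (anyNA(ia) || anyNA(ib))
    stop_input("dissimilarity table contains items outside `items`")
  m[cbind(ia, ib)] <- dtab$d
  m[cbind(ib, ia)] <- dtab$d
  if (require_complete && anyNA(m)) {
    miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop_input("incomplete dissimilarity table; missing pairs: %s",
               paste(items[miss[, 1L]], items[miss[, 2L]], sep = "-",
                     collapse = ", "))
  }
  m
}

# Inverse of dissim_matrix: upper triangle as a table.
matrix_to_dissim <- function(m) {
  items <- rownames(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  dissimilarity_table(items[ut[, 1L]], items[ut[, 2L]], m[ut])
}

#' Construct a letter code
#'
#' A letter code is a bank of artificial neurons tuned to single letters:
#' row `k` of `responses` holds neuron `k`'s response to every letter.
#' Pairwise Euclidean distances between letter columns reproduce (or
#' approximate) the perceptual dissimilarities the code was built from.
#'
#' @param responses Numeric matrix, neurons x letters.
#' @param letters Character vector naming the columns.
#' @param eigenvalues Optional per-dimension variances (from MDS).
#' @return An object of class `letter_code`.
#' @export
letter_code <- function(responses, letters = colnames(responses),
                        eigenvalues = NULL) {
  responses <- as.matrix(responses)
  if (is.null(letters) || length(letters) != ncol(responses))
    stop_input("`letters` must name every column of `responses`")
  if (any(!is.finite(responses)))
    stop_input("letter responses must be finite")
  colnames(responses) <- letters
  rownames(responses) <- paste0("neuron", seq_len(nrow(responses)))
  structure(list(letters = letters, responses = responses,
                 eigenvalues = eigenvalues, n_dims = nrow(responses)),
            class = "letter_code")
}

#' @export
print.letter_code <- function(x, ...) {
  cat(sprintf("Letter code: %d neurons x %d letters (%s%s)\n",
              x$n_dims, length(x$letters),
              paste(head(x$letters, 6L), collapse = ""),
              if (length(x$letters) > 6L) "..." else ""))
  invisible(x)
}

#' @export
print.dissimilarity_table <- function(x, ...) {
  cat(sprintf("Dissimilarity table: %d pairs over %d items\n", nrow(x),
              length(unique(c(x$item_a, x$item_b)))))
  NextMethod()
}
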