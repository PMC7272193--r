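## Internal helpers shared across modules.

#' @importFrom stats as.dist cmdscale cor dist lm.fit mad median optim
#'   rnorm runif sd setNames var wilcox.test
#' @importFrom utils adist combn head
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL means "use the current stream".
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Canonical unordered-pair representation: item_a <= item_b lexicographically.
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(item_a = a, item_b = b, stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  p <- canonical_pairs(a, b)
  paste(p$item_a, p$item_b, sep = "\r")
}

#' All unordered pairs of a set of items
#'
#' Convenience enumerator for search designs: every unordered pair of
#' distinct items, in canonical order.
#'
#' @param items Character vector of at least two items.
#' @return Data frame with columns `item_a`, `item_b` (`choose(n, 2)` rows).
#' @examples
#' all_pairs(c("A", "B", "C"))
#' @export
all_pairs <- function(items) {
  items <- as.character(items)
  stopifnot(length(items) >= 2L)
  idx <- combn(length(items), 2L)
  data.frame(item_a = items[idx[1L, ]], item_b = items[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
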