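#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor ecdf rnorm runif sd setNames quantile
#' @importFrom utils write.table read.table head
NULL

# Deterministic 31-bit seed for an unordered molecule pair, derived from the
# root seed and the sorted pair IDs so results do not depend on the order in
# which pairs are evaluated.
pair_seed <- function(root_seed, id_a, id_b) {
  ids <- sort(c(as.character(id_a), as.character(id_b)))
  s <- paste(ids, collapse = "\r")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer((h * 1000003 + as.numeric(root_seed)) %% 2147483647)
}

# Canonical unordered pair key: endpoints sorted, tab-joined.
pair_key <- function(a, b) {
  swap <- b < a
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "\t")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical keys for unordered molecule pairs
#'
#' Sorts each pair's endpoints and joins them, so that a pair compares equal
#' regardless of endpoint order. Useful for set operations on edge lists.
#'
#' @param pairs data frame with columns \code{a} and \code{b}.
#' @return character vector of canonical keys.
#' @export
pair_keys <- function(pairs) pair_key(pairs$a, pairs$b)
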