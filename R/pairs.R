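#' Canonicalize protein pairs
#'
#' Every unordered protein pair in the package is stored in a canonical form:
#' the lexicographically smaller identifier first. Canonicalization makes an
#' edge list order-insensitive, so `(A, B)` and `(B, A)` collapse to the same
#' pair. Self-pairs are rejected: a protein cannot be its own interaction
#' partner in a binary edge list.
#'
#' @param a,b Character vectors of protein identifiers (recycled to common
#'   length like base R arithmetic; usually equal length).
#' @return A tibble with columns `protein_a` and `protein_b` where
#'   `protein_a < protein_b` row-wise.
#' @examples
#' canonical_pairs(c("P2", "P1"), c("P1", "P2"))
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (any(is.na(a) | is.na(b) | a == "" | b == "")) {
    stop("protein identifiers must be non-empty and non-missing", call. = FALSE)
  }
  self <- a == b
  if (any(self)) {
    stop(
      "self-interactions are not allowed: ",
      paste(unique(a[self]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble(protein_a = pmin(a, b), protein_b = pmax(a, b))
}

#' Canonicalize the pair columns of a data frame
#'
#' Applies [canonical_pairs()] to the `protein_a`/`protein_b` columns of an
#' edge-list data frame, optionally dropping self-pairs and duplicates rather
#' than erroring (the behaviour wanted when cleaning curated source tables).
#'
#' @param pairs A data frame with columns `protein_a` and `protein_b`.
#' @param drop_self Drop self-pairs silently instead of erroring.
#' @param dedupe Keep only the first occurrence of each canonical pair.
#' @return A tibble with canonicalized pair columns; other columns preserved.
#'   The number of self-pairs dropped is attached as attribute
#'   `n_self_dropped`.
#' @export
canonicalize_pairs <- function(pairs, drop_self = TRUE, dedupe = FALSE) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  self <- pairs$protein_a == pairs$protein_b
  n_self <- sum(self)
  if (n_self > 0) {
    if (!drop_self) {
      stop("self-interactions are not allowed: ",
        paste(unique(pairs$protein_a[self]), collapse = ", "),
        call. = FALSE
      )
    }
    pairs <- pairs[!self, , drop = FALSE]
  }
  if (nrow(pairs) > 0) {
    canon <- canonical_pairs(pairs$protein_a, pairs$protein_b)
    pairs$protein_a <- canon$protein_a
    pairs$protein_b <- canon$protein_b
  }
  if (dedupe) {
    pairs <- pairs[!duplicated(pair_keys(pairs)), , drop = FALSE]
  }
  attr(pairs, "n_self_dropped") <- n_self
  pairs
}

# Internal string key for joining/set operations on canonical pairs.
# \x1f (ASCII unit separator) cannot occur in TSV-borne identifiers.
pair_keys <- function(pairs) {
  paste(pairs$protein_a, pairs$protein_b, sep = "\x1f")
}

#' All unordered pairs of a protein set
#'
#' Enumerates the complete candidate universe of canonical pairs over a
#' protein roster. Quadratic in the roster size; intended for the desk-scale
#' instances this package targets (hundreds to a few thousand proteins).
#'
#' @param proteins Character vector of protein identifiers (deduplicated).
#' @return Tibble of canonical pairs, lexicographically ordered.
#' @export
all_pairs <- function(proteins) {
  proteins <- sort(unique(as.character(proteins)))
  n <- length(proteins)
  if (n < 2) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  idx <- combn(n, 2)
  tibble(protein_a = proteins[idx[1, ]], protein_b = proteins[idx[2, ]])
}
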