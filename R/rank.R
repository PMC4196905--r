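#' Deterministic integer seeds derived from string keys
#'
#' Polynomial hash of the key components folded into the base seed, kept
#' below 2^31 so the result is a valid R integer seed.  Used to give every
#' gene / permutation round its own reproducible RNG stream.
#'
#' @param seed base integer seed.
#' @param ... key components (coerced to character).
#' @return an integer in `[0, 2^31)`.
#' @keywords internal
#' @noRd
mix_seed <- function(seed, ...) {
  h <- as.double(abs(as.integer(seed)) %% 2147483629)
  for (x in as.character(c(...))) {
    for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 2147483629
  }
  as.integer(h)
}

#' Rank-transform an expression profile
#'
#' Converts a numeric profile to strict ranks `1..n` (the copula transform
#' used by all estimators).  Ties are broken by a seeded shuffle, so repeated
#' calls with the same seed are identical; an all-constant profile still
#' yields a valid permutation but carries a `degenerate` attribute so callers
#' can exclude it from inference.
#'
#' @param x numeric vector, length at least 3, no missing values.
#' @param seed integer seed controlling tie-breaking.
#' @return integer vector of ranks (a permutation of `1..n`) with attribute
#'   `degenerate` (logical).
#' @examples
#' rank_transform(c(5, 1, 3))
#' @export
rank_transform <- function(x, seed = 1L) {
  if (length(x) < 3) abort("profile must have at least 3 samples")
  if (anyNA(x)) abort("profile contains missing values")
  n <- length(x)
  key <- withr::with_seed(mix_seed(seed, "ties"), sample.int(n))
  r <- integer(n)
  r[order(x, key)] <- seq_len(n)
  structure(r, degenerate = length(unique(x)) == 1L)
}

is_rank_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == as.integer(x)) &&
    all(sort(as.integer(x)) == seq_along(x))
}

# rank vector, from either raw profile or already-strict ranks
as_ranks <- function(x, seed) {
  if (is_rank_vector(x)) {
    r <- as.integer(x)
    attr(r, "degenerate") <- isTRUE(attr(x, "degenerate"))
    r
  } else {
    rank_transform(as.numeric(x), seed)
  }
}

#' Rank-transform every row of an expression matrix
#'
#' Each gene gets its own tie-breaking RNG stream keyed by `(seed, gene)`,
#' so adding or removing genes does not perturb the ranks of the others.
#'
#' @param mat numeric genes-by-samples matrix with rownames.
#' @param seed integer seed.
#' @return integer matrix of the same shape; attribute `degenerate` names
#'   the constant rows.
#' @export
rank_matrix <- function(mat, seed = 1L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  out <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  degen <- character(0)
  for (g in rownames(mat)) {
    r <- rank_transform(mat[g, ], mix_seed(seed, g))
    if (attr(r, "degenerate")) degen <- c(degen, g)
    out[g, ] <- r
  }
  attr(out, "degenerate") <- degen
  out
}
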