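#' Chi-square test for local uniformity of a subdivision
#'
#' Decides whether a cell of the adaptive partition should be subdivided:
#' the observed counts of its 2^d equal-expectation subcells are compared to
#' the uniform expectation `total / k` with a chi-square statistic on
#' `k - 1` degrees of freedom.
#'
#' @param cell_counts integer vector of subcell counts (length 4 for 2-D
#'   quadrants, 8 for 3-D octants).
#' @param alpha significance level of the test.
#' @return `TRUE` if the distribution is significantly non-uniform (i.e. the
#'   cell should be subdivided); an empty cell returns `FALSE`.
#' @examples
#' uniformity_test(c(25, 25, 25, 25)) # FALSE: perfectly uniform
#' uniformity_test(c(100, 0, 0, 0))   # TRUE
#' @export
uniformity_test <- function(cell_counts, alpha = 0.05) {
  k <- length(cell_counts)
  total <- sum(cell_counts)
  if (total == 0) return(FALSE)
  e <- total / k
  stat <- sum((cell_counts - e)^2 / e)
  stat > qchisq(1 - alpha, df = k - 1)
}

ap_crit <- function(alpha, d) qchisq(1 - alpha, df = 2^d - 1)

default_min_cell <- function(d) as.integer(2^d)

# resolution floor: scaled so small-sample inputs still receive the
# forced initial partitioning (without it a 3-D root below the absolute
# floor would never split on weak data and every estimate would be 0)
default_max_cell <- function(d, n) {
  if (d == 2L) 8L else max(8L, min(128L, n %/% 2L))
}

rank_input_list <- function(ranks, seed) {
  if (is.matrix(ranks)) ranks <- lapply(seq_len(ncol(ranks)), function(j) ranks[, j])
  if (!is.list(ranks) || !length(ranks) %in% c(2L, 3L))
    abort("`ranks` must be 2 or 3 rank vectors (list or matrix columns)")
  lapply(ranks, as_ranks, seed = seed)
}

#' Build an adaptive partition of 2-D or 3-D rank space
#'
#' Recursively subdivides rank space at the per-dimension lower median of the
#' points in each cell, continuing only where [uniformity_test()] rejects
#' local uniformity and the cell holds at least `min_cell` points.  The
#' leaves are pairwise-disjoint half-open boxes covering `[1, n+1)` per
#' dimension, with counts summing to `n`.
#'
#' @param ranks a list of 2 or 3 rank vectors (or a matrix with one rank
#'   vector per column); raw numeric profiles are rank-transformed.
#' @param alpha chi-square significance level for the subdivision test.
#' @param min_cell minimum occupancy for a cell to be considered for
#'   subdivision; defaults to `2^d`.
#' @param max_cell resolution floor: a cell holding at least this many points
#'   is always subdivided (the initial partitioning); defaults to 8 in 2-D
#'   and 128 in 3-D.
#' @param seed seed used only if raw profiles need rank-transforming.
#' @return a tibble with one row per leaf cell: `lo_1..lo_d`, `hi_1..hi_d`
#'   (half-open rank intervals) and `count`; attributes `n` and `dimension`.
#' @export
build_partition <- function(ranks, alpha = 0.05, min_cell = NULL,
                            max_cell = NULL, seed = 1L) {
  rv <- rank_input_list(ranks, seed)
  d <- length(rv)
  if (is.null(min_cell)) min_cell <- default_min_cell(d)
  if (is.null(max_cell)) max_cell <- default_max_cell(d, length(rv[[1]]))
  res <- .ap_partition_cpp(rv, ap_crit(alpha, d), as.integer(min_cell),
                           as.integer(max_cell))
  out <- as_tibble(setNames(
    c(lapply(seq_len(d), function(k) res$lo[, k]),
      lapply(seq_len(d), function(k) res$hi[, k]),
      list(res$count)),
    c(paste0("lo_", seq_len(d)), paste0("hi_", seq_len(d)), "count")
  ))
  structure(out, n = res$n, dimension = d,
            class = c("ap_partition", class(out)))
}

# canonical ordering so estimates are bit-for-bit symmetric in (x, y)
canonical_pair <- function(rx, ry) {
  d <- rx - ry
  i <- which(d != 0)
  if (length(i) && d[i[1]] > 0) list(ry, rx) else list(rx, ry)
}

#' Adaptive-partitioning mutual information estimate
#'
#' Plug-in estimate of I(X;Y) in nats over the adaptive partition of the
#' joint rank distribution: sum over leaves of
#' `(n_c/n) * log((n_c/n) / (p_x * p_y))`, where the marginal cell
#' probabilities are interval width / n (exact under rank marginals).
#' Because those marginals carry no estimation error, the joint term is the
#' only biased one and receives a Miller-Madow correction
#' `(occupied cells - 1) / (2n)`; the result is clamped at 0.
#' Inputs are canonically ordered first, so `estimate_mi(x, y)` and
#' `estimate_mi(y, x)` are identical to the last bit.
#'
#' @param x,y numeric profiles (rank-transformed internally) or strict rank
#'   vectors of common length n >= 3.
#' @param alpha chi-square level of the subdivision test.
#' @param min_cell minimum cell occupancy (default 4 in 2-D).
#' @param max_cell resolution floor; cells at least this large always split.
#' @param seed tie-breaking seed for the rank transform.
#' @return non-negative MI estimate in nats.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500)
#' estimate_mi(x, y)
#' @export
estimate_mi <- function(x, y, alpha = 0.05, min_cell = 4L, max_cell = 8L,
                        seed = 1L) {
  if (length(x) < 3) abort("estimators require n >= 3 samples")
  if (length(x) != length(y)) abort("profiles differ in length")
  rx <- as_ranks(x, seed)
  ry <- as_ranks(y, seed)
  p <- canonical_pair(rx, ry)
  .ap_mi_cpp(p[[1]], p[[2]], ap_crit(alpha, 2), as.integer(min_cell),
             as.integer(max_cell))
}

#' Adaptive-partitioning conditional mutual information estimate
#'
#' Plug-in estimate of I(TF;Tg|M) in nats over a 3-D adaptive partition:
#' sum over leaves of `p3 * log(pm * p3 / (p_tf_m * p_tg_m))`, where
#' `p3 = n_c/n`, the modulator marginal `pm` is interval width / n (exact
#' under rank marginals), and the 2-D marginals are obtained by counting all
#' n points inside each leaf's projected (TF,M) / (Tg,M) rectangle.  A
#' floating-point total below zero is clamped to 0.  Symmetric in (tf, tg)
#' bit-for-bit via canonical input ordering.
#'
#' @param tf,tg,m numeric profiles or strict rank vectors of common length.
#' @param alpha chi-square level of the subdivision test.
#' @param min_cell minimum cell occupancy (default 8 in 3-D).
#' @param max_cell resolution floor; cells at least this large always split
#'   (default: half the sample count, capped at 128).
#' @param seed tie-breaking seed for the rank transform.
#' @return non-negative CMI estimate in nats.
#' @export
estimate_cmi <- function(tf, tg, m, alpha = 0.05, min_cell = 8L,
                         max_cell = NULL, seed = 1L) {
  if (length(tf) < 3) abort("estimators require n >= 3 samples")
  if (length(tg) != length(tf) || length(m) != length(tf))
    abort("profiles differ in length")
  rtf <- as_ranks(tf, seed)
  rtg <- as_ranks(tg, seed)
  rm_ <- as_ranks(m, seed)
  if (is.null(max_cell)) max_cell <- default_max_cell(3L, length(rtf))
  p <- canonical_pair(rtf, rtg)
  .ap_cmi_cpp(p[[1]], p[[2]], rm_, ap_crit(alpha, 3), as.integer(min_cell),
              as.integer(max_cell))
}
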