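#' Fit an extended-exponential survival tail
#'
#' Models the upper tail of a null statistic's survival function as
#' `ln S(x) = a + b * x^c` (b < 0).  The fit uses the empirical survival
#' probabilities of the top 25% of values; the stretch exponent `c` is kept
#' at 1 unless optimizing it at least quarters the tail sum of squared
#' errors (a plain halving triggers spuriously on genuinely exponential
#' nulls).
#' This is the parametric form used to extrapolate p-values beyond the
#' resolution of a finite permutation null.
#'
#' @param x numeric vector of null statistics (at least 100 values).
#' @param tail_prop proportion of largest values used for the fit.
#' @return named list with elements `a`, `b`, `c`.
#' @export
fit_tail <- function(x, tail_prop = 0.25) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 100) abort("tail fit needs at least 100 null values")
  if (x[n] == x[1]) abort("degenerate null: all values identical")
  q <- x[ceiling((1 - tail_prop) * n)]
  ix <- which(x > q)
  if (length(ix) < 10) ix <- seq(n - 9, n)
  xt <- x[ix]
  ls <- log((n - ix + 0.5) / n)   # empirical log-survival at sorted order stats
  sse_for <- function(cc) {
    f <- lm(ls ~ I(xt^cc))
    sum(stats::residuals(f)^2)
  }
  fit1 <- lm(ls ~ xt)
  sse1 <- sum(stats::residuals(fit1)^2)
  a <- unname(coef(fit1)[1]); b <- unname(coef(fit1)[2]); cc <- 1
  if (sse1 > 0 && min(xt) > 0) {
    opt <- optimize(sse_for, interval = c(0.25, 4))
    if (opt$objective <= 0.25 * sse1) {
      cc <- opt$minimum
      f <- lm(ls ~ I(xt^cc))
      a <- unname(coef(f)[1]); b <- unname(coef(f)[2])
    }
  }
  if (!is.finite(b) || b >= 0) {
    warn("non-decreasing tail fit; forcing a flat exponential slope")
    b <- -1e-8
  }
  list(a = a, b = b, c = cc)
}

draw_pairs <- function(tfs, targets, n_pairs, seed) {
  nt <- length(tfs); ng <- length(targets)
  grid_n <- nt * ng
  self_n <- length(intersect(tfs, targets))
  avail <- grid_n - self_n
  if (avail < n_pairs) {
    warn(sprintf("only %d distinct (TF, Tg) combinations available; using all",
                 avail))
    n_pairs <- avail
  }
  withr::with_seed(mix_seed(seed, "pairs"), {
    got <- integer(0)
    while (length(got) < n_pairs) {
      k <- sample.int(grid_n, min(grid_n, n_pairs - length(got) + 50L))
      k <- k[tfs[(k - 1L) %/% ng + 1L] != targets[(k - 1L) %% ng + 1L]]
      got <- unique(c(got, k))
    }
    got <- got[seq_len(n_pairs)]
  })
  tibble(tf_id = tfs[(got - 1L) %/% ng + 1L],
         tg_id = targets[(got - 1L) %% ng + 1L])
}

#' Build the MI-stratified permutation null model for CMI
#'
#' Draws `n_pairs` distinct (TF, Tg) pairs, estimates their mutual
#' information, and for each pair computes `n_perm` CMI scores against
#' randomized modulators (a modulator profile drawn uniformly from
#' `modulators` with its sample order permuted -- this destroys any
#' three-way coupling while preserving the modulator's marginal).  The MI
#' range is then cut into `n_bins` equi-probable bins, each holding
#' `n_pairs / n_bins` pairs and `n_pairs / n_bins * n_perm` null CMI
#' values, and an extended-exponential tail is fitted per bin.  At the full
#' defaults (10^4 pairs, 1000 permutations, 100 bins) every bin holds 100
#' pairs and 10^5 CMI values.
#'
#' Conditioning the null on MI matters because permuted-modulator CMI grows
#' with the TF-Tg dependence itself: a strong pair's CMI must beat a
#' stochastically larger null than a weak pair's.
#'
#' @param mat expression matrix (genes x samples).
#' @param tfs,targets,modulators character vectors of gene ids (defaults:
#'   all genes).
#' @param n_pairs number of (TF, Tg) pairs sampled without replacement.
#' @param n_perm permuted-modulator CMI scores per pair.
#' @param n_bins number of equi-probable MI bins.
#' @param alpha,min_cell,max_cell estimator settings (see [estimate_cmi()]).
#' @param seed master seed; the model is fully reproducible from it.
#' @param mi_fun,cmi_fun optional replacement estimators
#'   (`function(rx, ry)` / `function(rtf, rtg, rm)` on rank vectors), used
#'   to exercise the null-model machinery at full scale with a cheap
#'   statistic.
#' @param ranks optional precomputed [rank_matrix()].
#' @return object of class `cmi_null`: list with `bin_edges` (length
#'   `n_bins + 1` MI quantiles), `bins` (per-bin tibble: pair count, null
#'   size, tail parameters, empirical range), `null_values` (per-bin sorted
#'   null CMI vectors), `pairs` (sampled pairs with MI and bin), and `meta`.
#' @export
build_cmi_null <- function(mat, tfs = rownames(mat), targets = rownames(mat),
                           modulators = rownames(mat),
                           n_pairs = 10000L, n_perm = 1000L, n_bins = 100L,
                           alpha = 0.05, min_cell = NULL, max_cell = NULL,
                           seed = 1L, mi_fun = NULL, cmi_fun = NULL,
                           ranks = NULL) {
  check_genes(mat, c(tfs, targets, modulators))
  n <- ncol(mat)
  if (is.null(ranks))
    ranks <- rank_matrix(mat[unique(c(tfs, targets, modulators)), , drop = FALSE],
                         seed)
  mc2 <- as.integer(min_cell %||% 4L)
  xc2 <- as.integer(max_cell %||% default_max_cell(2L, n))
  mc3 <- as.integer(min_cell %||% 8L)
  xc3 <- as.integer(max_cell %||% default_max_cell(3L, n))
  crit2 <- ap_crit(alpha, 2); crit3 <- ap_crit(alpha, 3)
  if (is.null(mi_fun))
    mi_fun <- function(rx, ry) {
      p <- canonical_pair(rx, ry)
      .ap_mi_cpp(p[[1]], p[[2]], crit2, mc2, xc2)
    }
  cmi_many <- if (is.null(cmi_fun)) {
    function(rtf, rtg, rms) {
      p <- canonical_pair(rtf, rtg)
      .ap_cmi_many_cpp(p[[1]], p[[2]], rms, crit3, mc3, xc3)
    }
  } else {
    function(rtf, rtg, rms) apply(rms, 2, function(rm) cmi_fun(rtf, rtg, rm))
  }

  pairs <- draw_pairs(tfs, targets, as.integer(n_pairs), seed)
  np <- nrow(pairs)
  mi <- numeric(np)
  nulls <- vector("list", np)
  for (i in seq_len(np)) {
    rtf <- ranks[pairs$tf_id[i], ]
    rtg <- ranks[pairs$tg_id[i], ]
    mi[i] <- mi_fun(rtf, rtg)
    perms <- withr::with_seed(
      mix_seed(seed, "perm", pairs$tf_id[i], pairs$tg_id[i]), {
        mods <- sample(modulators, n_perm, replace = TRUE)
        vapply(mods, function(m) ranks[m, ][sample.int(n)], integer(n))
      })
    nulls[[i]] <- cmi_many(rtf, rtg, perms)
  }
  if (length(unique(mi)) < n_bins)
    abort(sprintf("only %d distinct MI values for %d bins; use a smaller n_bins",
                  length(unique(mi)), n_bins))
  # equi-probable bins by MI rank, so every bin holds the same pair count
  bin <- ceiling(rank(mi, ties.method = "first") / (np / n_bins))
  bin_edges <- unname(quantile(mi, probs = seq(0, 1, length.out = n_bins + 1)))
  pairs$mi <- mi
  pairs$bin <- as.integer(bin)
  null_values <- lapply(seq_len(n_bins), function(b)
    sort(unlist(nulls[bin == b], use.names = FALSE)))
  bins <- purrr::map_dfr(seq_len(n_bins), function(bi) {
    fit <- fit_tail(null_values[[bi]])
    np_bin <- sum(bin == bi)
    tibble(bin = bi, n_pairs = np_bin,
           n_null = length(null_values[[bi]]),
           mi_lo = bin_edges[bi], mi_hi = bin_edges[bi + 1],
           a = fit$a, b = fit$b, c = fit$c,
           cmi_max = max(null_values[[bi]]))
  })
  structure(list(bin_edges = bin_edges, bins = bins,
                 null_values = null_values, pairs = pairs,
                 sorted_mi = sort(mi),
                 meta = list(n_pairs = np, n_perm = as.integer(n_perm),
                             n_bins = as.integer(n_bins),
                             n_samples = n, alpha = alpha, seed = as.integer(seed))),
            class = "cmi_null")
}

#' Convert (MI, CMI) pairs to p-values under a null model
#'
#' Locates the MI bin by the query's mid-rank among the model's pair MI
#' values (equivalent to quantile-edge lookup wherever the MI distribution
#' is continuous, and mapping a tied value -- e.g. the atom of exact-zero
#' estimates -- to the middle of its tied block of exchangeable strata;
#' queries outside the modelled range clamp to the end bins).  Uses the
#' bin's empirical survival function while the CMI lies inside the observed
#' null range, and switches to the fitted extended-exponential tail beyond
#' it.  P-values are upper-tail (large CMI significant), never exceed 1 and
#' are floored at 1e-30.
#'
#' @param model a [build_cmi_null()] object.
#' @param mi,cmi numeric vectors (recycled to common length), in nats.
#' @return numeric vector of p-values in (0, 1].
#' @export
cmi_pvalue <- function(model, mi, cmi) {
  stopifnot(inherits(model, "cmi_null"))
  k <- max(length(mi), length(cmi))
  mi <- rep_len(mi, k); cmi <- rep_len(cmi, k)
  nb <- model$meta$n_bins
  sm <- model$sorted_mi
  np <- length(sm)
  r_le <- findInterval(mi, sm)
  r_lt <- findInterval(mi, sm, left.open = TRUE)
  mid <- (r_lt + r_le + 1) / 2
  bins <- pmin(nb, pmax(1L, ceiling(mid / (np / nb))))
  out <- numeric(k)
  for (i in seq_len(k)) {
    nv <- model$null_values[[bins[i]]]
    nn <- length(nv)
    n_less <- findInterval(cmi[i], nv, left.open = TRUE)
    p <- (1 + nn - n_less) / (1 + nn)
    if (cmi[i] > nv[nn]) {
      pars <- model$bins[bins[i], ]
      p <- min(p, exp(pars$a + pars$b * cmi[i]^pars$c))
    }
    out[i] <- min(1, max(p, 1e-30))
  }
  out
}

#' Serialize / restore a CMI null model
#'
#' Writes the complete model (bin edges, tail parameters, stored null
#' values, metadata) to a single JSON document so an expensive null can be
#' reused across runs.
#'
#' @param model a `cmi_null` object.
#' @param path JSON file path.
#' @return `path` / the restored `cmi_null` object.
#' @export
write_null_model <- function(model, path) {
  stopifnot(inherits(model, "cmi_null"))
  obj <- list(bin_edges = model$bin_edges,
              bins = model$bins,
              null_values = model$null_values,
              pairs = model$pairs,
              sorted_mi = model$sorted_mi,
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nv <- obj$null_values
  # equal-sized bins come back as a matrix (one row per bin)
  nv <- if (is.matrix(nv)) lapply(seq_len(nrow(nv)), function(i) nv[i, ])
        else lapply(nv, as.numeric)
  structure(list(bin_edges = as.numeric(obj$bin_edges),
                 bins = as_tibble(obj$bins),
                 null_values = nv,
                 pairs = as_tibble(obj$pairs),
                 sorted_mi = as.numeric(obj$sorted_mi),
                 meta = as.list(obj$meta)),
            class = "cmi_null")
}

#' @export
tidy.cmi_null <- function(x, ...) x$bins

#' @export
glance.cmi_null <- function(x, ...) {
  as_tibble(x$meta)
}

#' @export
print.cmi_null <- function(x, ...) {
  cat(sprintf("MI-stratified CMI null model: %d pairs x %d permutations, %d bins (n = %d samples)\n",
              x$meta$n_pairs, x$meta$n_perm, x$meta$n_bins, x$meta$n_samples))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_genes <- function(mat, ids) {
  miss <- setdiff(unique(ids), rownames(mat))
  if (length(miss))
    abort(paste0("gene ids missing from the expression matrix: ",
                 paste(head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10)))
  invisible(TRUE)
}
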