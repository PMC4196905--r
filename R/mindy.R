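#' Default parameters of the tail-based delta-I baseline
#'
#' The classic heuristic's published defaults: 35% expression tails, an
#' independence prefilter on the modulator-TF mutual information at p =
#' 1e-5, a corrected per-triplet threshold of 0.05, a TF-target dependence
#' requirement at p = 1e-6, and pair calling at FDR 0.05.
#'
#' @param tail_fraction proportion of samples in each modulator tail
#'   (0 < f <= 0.5).
#' @param p_indep_m_tf MI p-value above which a modulator-TF pair counts as
#'   independent (pairs below are discarded).
#' @param alpha_corrected corrected delta-I p-value threshold per triplet.
#' @param p_dep_tf_tg MI p-value below which a TF-target pair counts as
#'   dependent (targets above are discarded).
#' @param fdr FDR threshold for pair calling.
#' @param n_perm tail-label permutations for the delta-I null.
#' @param cor_ceiling rank-correlation magnitude at or above which a target
#'   is discarded as a near-duplicate of its TF.
#' @return validated list of class `mindy_params`.
#' @export
mindy_params <- function(tail_fraction = 0.35, p_indep_m_tf = 1e-5,
                         alpha_corrected = 0.05, p_dep_tf_tg = 1e-6,
                         fdr = 0.05, n_perm = 200L, cor_ceiling = 0.9) {
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    abort("tail_fraction must be in (0, 0.5]")
  for (p in c(p_indep_m_tf, alpha_corrected, p_dep_tf_tg, fdr))
    if (p <= 0 || p >= 1) abort("thresholds must lie in (0, 1)")
  structure(list(tail_fraction = tail_fraction, p_indep_m_tf = p_indep_m_tf,
                 alpha_corrected = alpha_corrected, p_dep_tf_tg = p_dep_tf_tg,
                 fdr = fdr, n_perm = as.integer(n_perm),
                 cor_ceiling = cor_ceiling),
            class = "mindy_params")
}

#' Select the high/low modulator expression tails
#'
#' Returns the sample indices of the `floor(f * n)` highest and lowest
#' modulator values; boundary ties are resolved by the seeded rank
#' transform, so membership is deterministic given the seed.
#'
#' @param m_profile numeric modulator profile.
#' @param tail_fraction proportion per tail; tails must not overlap.
#' @param seed tie-breaking seed.
#' @return list with integer index vectors `high` and `low` (disjoint).
#' @export
select_tails <- function(m_profile, tail_fraction = 0.35, seed = 1L) {
  if (2 * tail_fraction > 1) abort("tails overlap: 2 * tail_fraction > 1")
  n <- length(m_profile)
  t <- floor(tail_fraction * n)
  r <- rank_transform(m_profile, seed)
  list(high = which(r > n - t), low = which(r <= t))
}

#' Null distribution of mutual information between independent profiles
#'
#' After the rank transform every profile is a uniform random permutation,
#' so the MI null distribution depends only on the sample count.  The model
#' stores `n_null` MI values between independent random permutations plus
#' an extended-exponential tail fit for extrapolating small p-values (the
#' published prefilter thresholds, 1e-5 and 1e-6, lie far below any
#' affordable empirical resolution).
#'
#' @param n number of samples.
#' @param n_null number of simulated independent pairs.
#' @param alpha,min_cell,max_cell estimator settings.
#' @param seed RNG seed.
#' @return object of class `mi_null`.
#' @export
build_mi_null <- function(n, n_null = 3000L, alpha = 0.05, min_cell = 4L,
                          max_cell = 8L, seed = 1L) {
  crit <- ap_crit(alpha, 2)
  vals <- withr::with_seed(mix_seed(seed, "minull"), {
    vapply(seq_len(n_null), function(i) {
      p <- canonical_pair(sample.int(n), sample.int(n))
      .ap_mi_cpp(p[[1]], p[[2]], crit, as.integer(min_cell),
                 as.integer(max_cell))
    }, 0)
  })
  vals <- sort(vals)
  fit <- if (vals[length(vals)] > vals[1]) fit_tail(vals) else
    list(a = 0, b = -1e-8, c = 1)
  structure(list(values = vals, fit = fit, n = as.integer(n)),
            class = "mi_null")
}

#' Upper-tail p-value of an MI estimate under independence
#'
#' Empirical survival inside the stored null range; extended-exponential
#' extrapolation beyond it; floored at 1e-30.
#'
#' @param model a [build_mi_null()] object.
#' @param mi numeric vector of MI estimates (nats).
#' @return numeric vector of p-values in (0, 1].
#' @export
mi_pvalue <- function(model, mi) {
  stopifnot(inherits(model, "mi_null"))
  nv <- model$values
  nn <- length(nv)
  vapply(mi, function(x) {
    p <- (1 + nn - findInterval(x, nv, left.open = TRUE)) / (1 + nn)
    if (x > nv[nn])
      p <- min(p, exp(model$fit$a + model$fit$b * x^model$fit$c))
    min(1, max(p, 1e-30))
  }, 0)
}

#' Keep modulator-TF pairs whose expression is independent
#'
#' The delta-I heuristic is only valid when modulator and TF expression are
#' statistically independent, so every (M, TF) pair whose MI p-value is at
#' or below `p_indep_m_tf` is discarded.  This is the prefilter that blinds
#' the heuristic to modulators co-expressed with their TF.
#'
#' @param mat expression matrix.
#' @param modulators,tfs gene id vectors.
#' @param params a [mindy_params()].
#' @param mi_null optional prebuilt [build_mi_null()].
#' @param seed rank seed.
#' @return tibble `m_id, tf_id, mi, p, admissible` covering every candidate
#'   pair (M != TF).
#' @export
prefilter_pairs <- function(mat, modulators, tfs, params = mindy_params(),
                            mi_null = NULL, seed = 1L) {
  check_genes(mat, c(modulators, tfs))
  if (is.null(mi_null)) mi_null <- build_mi_null(ncol(mat), seed = seed)
  ranks <- rank_matrix(mat[unique(c(modulators, tfs)), , drop = FALSE], seed)
  crit <- ap_crit(0.05, 2)
  grid <- tidyr::expand_grid(m_id = modulators, tf_id = tfs) %>%
    filter(.data$m_id != .data$tf_id)
  grid$mi <- vapply(seq_len(nrow(grid)), function(i) {
    p <- canonical_pair(ranks[grid$m_id[i], ], ranks[grid$tf_id[i], ])
    .ap_mi_cpp(p[[1]], p[[2]], crit, 4L, 8L)
  }, 0)
  grid$p <- mi_pvalue(mi_null, grid$mi)
  grid$admissible <- grid$p > params$p_indep_m_tf
  grid
}

#' Keep candidate targets dependent on, but not duplicating, their TF
#'
#' A target is admissible when its MI with the TF is significant at
#' `p_dep_tf_tg` and its rank correlation with the TF stays below the
#' near-duplicate ceiling.
#'
#' @param mat expression matrix.
#' @param tf a single TF id.
#' @param targets candidate target ids.
#' @param params a [mindy_params()].
#' @param mi_null optional prebuilt [build_mi_null()].
#' @param seed rank seed.
#' @return tibble `tg_id, mi, p, rho, admissible`.
#' @export
prefilter_targets <- function(mat, tf, targets, params = mindy_params(),
                              mi_null = NULL, seed = 1L) {
  check_genes(mat, c(tf, targets))
  if (is.null(mi_null)) mi_null <- build_mi_null(ncol(mat), seed = seed)
  targets <- setdiff(targets, tf)
  ranks <- rank_matrix(mat[unique(c(tf, targets)), , drop = FALSE], seed)
  crit <- ap_crit(0.05, 2)
  rtf <- ranks[tf, ]
  mi <- vapply(targets, function(tg) {
    p <- canonical_pair(rtf, ranks[tg, ])
    .ap_mi_cpp(p[[1]], p[[2]], crit, 4L, 8L)
  }, 0)
  rho <- vapply(targets, function(tg) cor(rtf, ranks[tg, ]), 0)
  p <- mi_pvalue(mi_null, mi)
  tibble(tg_id = targets, mi = unname(mi), p = unname(p),
         rho = unname(rho),
         admissible = p <= params$p_dep_tf_tg & abs(rho) < params$cor_ceiling)
}

# delta-I for one triplet given precomputed global ranks and tail indices;
# returns i_high, i_low, delta_i, p (two-sided, permutation + normal tail)
delta_i_ranks <- function(rtf, rtg, high, low, n_perm, seed,
                          crit2 = ap_crit(0.05, 2), mc2 = 4L, xc2 = 8L) {
  t <- length(high)
  comb <- c(high, low)
  n2 <- 2L * t
  perms <- withr::with_seed(mix_seed(seed, "di"), {
    vapply(seq_len(n_perm), function(i) sample.int(n2), integer(n2))
  })
  perms <- cbind(seq_len(n2), perms)  # first column = observed assignment
  di <- .delta_i_perm_cpp(rtf[comb], rtg[comb], perms, t, crit2, mc2, xc2)
  obs <- di[1]
  nullv <- di[-1]
  p_emp <- (1 + sum(abs(nullv) >= abs(obs))) / (1 + n_perm)
  s <- sd(nullv)
  p <- if (abs(obs) > max(abs(nullv)) && s > 0)
    min(p_emp, max(2 * pnorm(-abs(obs) / s), 1e-30)) else p_emp
  list(obs = obs, p = min(p, 1))
}

#' Tail-conditioned mutual information difference for one triplet
#'
#' Computes the TF-target MI separately in the samples with highest and
#' lowest modulator expression (profiles re-ranked within each tail so both
#' estimates see uniform marginals) and assesses the difference against a
#' null in which tail labels are reassigned by permutation.  Two-sided:
#' modulation may strengthen or weaken the coupling.  Beyond empirical
#' permutation resolution the p-value is extrapolated from a normal fit to
#' the permutation null.
#'
#' @param tf_profile,tg_profile,m_profile numeric profiles.
#' @param tail_fraction per-tail sample proportion.
#' @param n_perm number of tail-label permutations.
#' @param seed RNG seed.
#' @return one-row tibble: `i_high, i_low, delta_i, p`.
#' @export
delta_i <- function(tf_profile, tg_profile, m_profile, tail_fraction = 0.35,
                    n_perm = 200L, seed = 1L) {
  tails <- select_tails(m_profile, tail_fraction, seed)
  if (length(tails$high) < 10 || length(tails$low) < 10)
    abort("each modulator tail needs at least 10 samples")
  rtf <- rank_transform(tf_profile, seed)
  rtg <- rank_transform(tg_profile, seed)
  crit2 <- ap_crit(0.05, 2)
  sub_mi <- function(ix) {
    p <- canonical_pair(rerank_int(rtf[ix]), rerank_int(rtg[ix]))
    .ap_mi_cpp(p[[1]], p[[2]], crit2, 4L, 8L)
  }
  ih <- sub_mi(tails$high)
  il <- sub_mi(tails$low)
  res <- delta_i_ranks(rtf, rtg, tails$high, tails$low, n_perm, seed)
  tibble(i_high = ih, i_low = il, delta_i = ih - il, p = res$p)
}

rerank_int <- function(x) {
  r <- integer(length(x))
  r[order(x)] <- seq_along(x)
  r
}

#' Run the tail-based delta-I baseline pipeline
#'
#' Applies the independence and target prefilters, computes per-triplet
#' delta-I significance, counts per-pair significant targets at the
#' corrected threshold, and calls (M, TF) pairs with the same
#' randomized-modulator N_sig machinery as the conditional-mutual-
#' information pipeline.  Prefiltered pairs remain in the output (with
#' `admissible = FALSE` and `n_sig = NA`): they can never be called, which
#' is exactly how the heuristic loses co-expressed modulators.
#'
#' @param mat expression matrix.
#' @param modulators,tfs gene id vectors.
#' @param targets optional candidate target ids (default: all genes).
#' @param params a [mindy_params()].
#' @param n_rounds randomized-modulator rounds for the N_sig null.
#' @param pool `"tf"` or `"all"` (see [build_nsig_null()]).
#' @param seed master seed.
#' @return object of class `mindy_fit` with elements `pairs` (schema of
#'   [call_modulations()] plus `admissible`), `triplets`, `prefilter`.
#' @export
run_mindy <- function(mat, modulators, tfs, targets = NULL,
                      params = mindy_params(), n_rounds = 5L,
                      pool = c("tf", "all"), seed = 1L) {
  pool <- match.arg(pool)
  targets <- targets %||% rownames(mat)
  check_genes(mat, c(modulators, tfs, targets))
  genes <- unique(c(modulators, tfs, targets))
  ranks <- rank_matrix(mat[genes, , drop = FALSE], seed)
  degen <- attr(ranks, "degenerate")
  modulators <- setdiff(modulators, degen)
  tfs <- setdiff(tfs, degen)
  targets <- setdiff(targets, degen)
  n <- ncol(ranks)
  mi_null <- build_mi_null(n, seed = seed)
  pf_pairs <- prefilter_pairs(mat, modulators, tfs, params, mi_null, seed)
  pf_targets <- lapply(setNames(tfs, tfs), function(tf)
    prefilter_targets(mat, tf, targets, params, mi_null, seed))

  score_round <- function(mod_ranks) {
    res <- list()
    for (i in seq_len(nrow(pf_pairs))) {
      if (!pf_pairs$admissible[i]) next
      m <- pf_pairs$m_id[i]; tf <- pf_pairs$tf_id[i]
      tgs <- pf_targets[[tf]]$tg_id[pf_targets[[tf]]$admissible]
      tgs <- setdiff(tgs, c(m, tf))
      if (!length(tgs)) {
        res[[length(res) + 1]] <- tibble(m_id = m, tf_id = tf,
                                         tg_id = character(0),
                                         delta_i = double(0), p = double(0))
        next
      }
      rm_ <- mod_ranks[m, ]
      t <- floor(params$tail_fraction * n)
      high <- which(rm_ > n - t); low <- which(rm_ <= t)
      rows <- purrr::map_dfr(tgs, function(tg) {
        r <- delta_i_ranks(ranks[tf, ], ranks[tg, ], high, low,
                           params$n_perm, mix_seed(seed, m, tf, tg))
        tibble(m_id = m, tf_id = tf, tg_id = tg, delta_i = r$obs, p = r$p)
      })
      res[[length(res) + 1]] <- rows
    }
    bind_rows(res)
  }

  triplets <- score_round(ranks)
  if (nrow(triplets)) {
    triplets <- triplets %>%
      group_by(.data$m_id, .data$tf_id) %>%
      mutate(significant =
               p.adjust(.data$p, method = "bonferroni") <= params$alpha_corrected) %>%
      ungroup()
  } else {
    triplets$significant <- logical(0)
  }
  nsig <- if (nrow(triplets)) count_significant(triplets) else
    tibble(m_id = character(), tf_id = character(), n_sig = integer(),
           n_targets = integer())

  # randomized-modulator N_sig null, pooled like the main pipeline
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    mod_ranks <- ranks[modulators, , drop = FALSE]
    for (m in modulators) {
      perm <- withr::with_seed(mix_seed(seed, "mnsig", r, m), sample.int(n))
      mod_ranks[m, ] <- mod_ranks[m, ][perm]
    }
    tr <- score_round(mod_ranks)
    if (!nrow(tr)) {
      rounds[[r]] <- tibble(round = r, m_id = character(),
                            tf_id = character(), n_sig = integer())
      next
    }
    tr <- tr %>%
      group_by(.data$m_id, .data$tf_id) %>%
      mutate(significant =
               p.adjust(.data$p, method = "bonferroni") <= params$alpha_corrected) %>%
      ungroup()
    rounds[[r]] <- count_significant(tr) %>%
      mutate(round = r) %>%
      select("round", "m_id", "tf_id", "n_sig")
  }
  nsig_null <- bind_rows(rounds)
  attr(nsig_null, "pool") <- pool

  called <- if (nrow(nsig) && nrow(nsig_null)) {
    call_modulations(nsig, nsig_null, fdr = params$fdr)
  } else {
    tibble(m_id = character(), tf_id = character(), n_sig = integer(),
           n_targets = integer(), p = double(), q = double(),
           called = logical())
  }
  pairs <- pf_pairs %>%
    select("m_id", "tf_id", "admissible") %>%
    left_join(called, by = c("m_id", "tf_id")) %>%
    mutate(called = ifelse(is.na(.data$called), FALSE, .data$called)) %>%
    arrange(desc(.data$admissible), .data$q)
  attr(pairs, "sweep") <- attr(called, "sweep")
  structure(list(pairs = pairs, triplets = triplets,
                 prefilter = list(pairs = pf_pairs, targets = pf_targets),
                 params = params,
                 config = list(n_rounds = n_rounds, pool = pool, seed = seed)),
            class = "mindy_fit")
}

#' @export
tidy.mindy_fit <- function(x, ...) x$pairs

#' @export
glance.mindy_fit <- function(x, ...) {
  tibble(n_pairs_candidate = nrow(x$pairs),
         n_admissible = sum(x$pairs$admissible),
         n_called = sum(x$pairs$called),
         fdr = x$params$fdr,
         tail_fraction = x$params$tail_fraction,
         seed = x$config$seed)
}

#' @export
print.mindy_fit <- function(x, ...) {
  cat(sprintf("delta-I baseline: %d candidate pairs, %d admissible, %d called at FDR %.2g\n",
              nrow(x$pairs), sum(x$pairs$admissible), sum(x$pairs$called),
              x$params$fdr))
  invisible(x)
}
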