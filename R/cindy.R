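# Internal scorer on a precomputed rank matrix; `mod_ranks` allows the
# randomized-modulator null rounds to swap in permuted modulator profiles
# without touching the TF/target ranks.
score_ranks <- function(ranks, modulators, tfs, targets, null,
                        alpha = 0.05, correction = "bonferroni",
                        crit3, mc3, xc3, crit2, mc2, xc2,
                        mod_ranks = NULL) {
  res <- vector("list", length(tfs))
  n <- ncol(ranks)
  for (ti in seq_along(tfs)) {
    tf <- tfs[ti]
    rtf <- ranks[tf, ]
    tgs <- setdiff(targets, tf)
    mi <- vapply(tgs, function(tg) {
      p <- canonical_pair(rtf, ranks[tg, ])
      .ap_mi_cpp(p[[1]], p[[2]], crit2, mc2, xc2)
    }, 0)
    tg_ranks <- t(ranks[tgs, , drop = FALSE])  # n x targets, batch layout
    per_m <- vector("list", length(modulators))
    for (mi_ix in seq_along(modulators)) {
      m <- modulators[mi_ix]
      if (m == tf) next
      rm_ <- if (is.null(mod_ranks)) ranks[m, ] else mod_ranks[m, ]
      keep <- tgs != m
      cmi <- .ap_cmi_batch_cpp(rtf, tg_ranks[, keep, drop = FALSE], rm_,
                               crit3, mc3, xc3)
      per_m[[mi_ix]] <- tibble(m_id = m, tf_id = tf, tg_id = tgs[keep],
                               mi = unname(mi[keep]), cmi = unname(cmi))
    }
    res[[ti]] <- bind_rows(per_m)
  }
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(m_id = character(), tf_id = character(), tg_id = character(),
                  mi = double(), cmi = double(), p = double(),
                  significant = logical()))
  }
  out$p <- cmi_pvalue(null, out$mi, out$cmi)
  out <- out %>%
    group_by(.data$m_id, .data$tf_id) %>%
    mutate(significant = p.adjust(.data$p, method = correction) <= alpha) %>%
    ungroup()
  out
}

#' Score all (modulator, TF, target) triplets
#'
#' For every admissible triplet of three distinct genes, estimates the
#' conditional mutual information I(TF;Tg|M) and its p-value under the
#' MI-stratified null, then applies a multiple-testing correction across
#' each (M, TF) pair's tested targets.  When `targets` is omitted every
#' matrix gene is a candidate target (minus the triplet's own members);
#' passing a target list (e.g. a per-TF regulon) restricts the search.
#' Constant-expression genes are excluded from all three roles.
#'
#' @param mat expression matrix (genes x samples).
#' @param modulators,tfs character vectors of gene ids.
#' @param targets optional candidate target ids (default: all genes).
#' @param null a [build_cmi_null()] model built on the same matrix.
#' @param alpha corrected p-value threshold for per-triplet significance.
#' @param correction `"bonferroni"` (conservative default) or any
#'   [stats::p.adjust()] method, applied within each (M, TF) target set.
#' @param seed tie-breaking seed for the rank transform.
#' @return tibble of class `cindy_triplets`: `m_id, tf_id, tg_id, mi, cmi,
#'   p, significant`.
#' @export
score_triplets <- function(mat, modulators, tfs, targets = NULL, null,
                           alpha = 0.05, correction = "bonferroni",
                           seed = 1L) {
  targets <- targets %||% rownames(mat)
  check_genes(mat, c(modulators, tfs, targets))
  genes <- unique(c(modulators, tfs, targets))
  ranks <- rank_matrix(mat[genes, , drop = FALSE], seed)
  degen <- attr(ranks, "degenerate")
  if (length(degen)) {
    message("excluding constant-expression genes: ",
            paste(degen, collapse = ", "))
    modulators <- setdiff(modulators, degen)
    tfs <- setdiff(tfs, degen)
    targets <- setdiff(targets, degen)
  }
  out <- score_ranks(ranks, modulators, tfs, targets, null,
                     alpha = alpha, correction = correction,
                     crit3 = ap_crit(0.05, 3), mc3 = 8L,
                     xc3 = default_max_cell(3L, ncol(ranks)),
                     crit2 = ap_crit(0.05, 2), mc2 = 4L, xc2 = 8L)
  class(out) <- c("cindy_triplets", class(out))
  out
}

#' Count significant conditional target interactions per (M, TF) pair
#'
#' @param triplets a [score_triplets()] result.
#' @return tibble: `m_id, tf_id, n_sig, n_targets`, one row per tested
#'   (M, TF) pair.
#' @export
count_significant <- function(triplets) {
  triplets %>%
    group_by(.data$m_id, .data$tf_id) %>%
    summarise(n_sig = sum(.data$significant), n_targets = n(),
              .groups = "drop")
}

#' Randomized-modulator null distribution of N_sig
#'
#' Re-runs triplet scoring `n_rounds` times with every modulator profile
#' replaced by a sample-order permutation of itself (seeded per round and
#' modulator), recording the per-pair count of significant targets.  The
#' pooled values form the null distribution against which observed N_sig
#' counts are judged.
#'
#' @inheritParams score_triplets
#' @param n_rounds number of randomization rounds (>= 2).
#' @param pool `"tf"` (pool null N_sig per TF) or `"all"` (one pooled
#'   null).  Per-TF pooling conditions on the TF's target spectrum; global
#'   pooling buys p-value resolution when rounds are few.
#' @return tibble of class `nsig_null`: `round, m_id, tf_id, n_sig`.
#' @export
build_nsig_null <- function(mat, modulators, tfs, targets = NULL, null,
                            alpha = 0.05, correction = "bonferroni",
                            n_rounds = 10L, pool = c("tf", "all"),
                            seed = 1L) {
  pool <- match.arg(pool)
  if (n_rounds < 2) abort("n_rounds must be at least 2")
  targets <- targets %||% rownames(mat)
  check_genes(mat, c(modulators, tfs, targets))
  genes <- unique(c(modulators, tfs, targets))
  ranks <- rank_matrix(mat[genes, , drop = FALSE], seed)
  degen <- attr(ranks, "degenerate")
  modulators <- setdiff(modulators, degen)
  tfs <- setdiff(tfs, degen)
  targets <- setdiff(targets, degen)
  n <- ncol(ranks)
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    mod_ranks <- ranks[modulators, , drop = FALSE]
    for (m in modulators) {
      perm <- withr::with_seed(mix_seed(seed, "nsig", r, m), sample.int(n))
      mod_ranks[m, ] <- mod_ranks[m, ][perm]
    }
    tr <- score_ranks(ranks, modulators, tfs, targets, null,
                      alpha = alpha, correction = correction,
                      crit3 = ap_crit(0.05, 3), mc3 = 8L,
                      xc3 = default_max_cell(3L, ncol(ranks)),
                      crit2 = ap_crit(0.05, 2), mc2 = 4L, xc2 = 8L,
                      mod_ranks = mod_ranks)
    out[[r]] <- count_significant(tr) %>%
      mutate(round = r) %>%
      select("round", "m_id", "tf_id", "n_sig")
  }
  out <- bind_rows(out)
  attr(out, "pool") <- pool
  class(out) <- c("nsig_null", class(out))
  out
}

#' Call modulator-TF interactions from N_sig counts
#'
#' Computes, per (M, TF) pair, the empirical probability of observing at
#' least its N_sig under the randomized-modulator null
#' (`p = (1 + #null >= N_sig) / (1 + #null)`), applies Benjamini-Hochberg
#' across all pairs and calls pairs with `q <= fdr`.  The result carries a
#' `sweep` attribute with the stringency sweep: the number of pairs whose
#' `N_sig >= k` for `k = 1..k_max`.
#'
#' @param nsig a [count_significant()] table.
#' @param nsig_null a [build_nsig_null()] table.
#' @param fdr false discovery rate threshold.
#' @param k_max largest N_sig stringency threshold in the sweep.
#' @return tibble of class `cindy_pairs`, sorted by `q` then decreasing
#'   `n_sig`: `m_id, tf_id, n_sig, n_targets, p, q, called`.
#' @export
call_modulations <- function(nsig, nsig_null, fdr = 0.05, k_max = 300L) {
  pool <- attr(nsig_null, "pool") %||% "tf"
  if (!nrow(nsig_null) || all(is.na(nsig_null$n_sig)))
    abort("degenerate N_sig null")
  pvals <- vapply(seq_len(nrow(nsig)), function(i) {
    nv <- if (pool == "all") nsig_null$n_sig else
      nsig_null$n_sig[nsig_null$tf_id == nsig$tf_id[i]]
    if (!length(nv)) return(NA_real_)
    (1 + sum(nv >= nsig$n_sig[i])) / (1 + length(nv))
  }, 0)
  out <- nsig %>%
    mutate(p = pvals, q = p.adjust(pvals, method = "BH"),
           called = .data$q <= fdr & .data$n_sig > 0) %>%
    arrange(.data$q, desc(.data$n_sig))
  sweep <- tibble(k = seq_len(k_max),
                  n_called = vapply(seq_len(k_max),
                                    function(k) sum(out$n_sig >= k), 0L))
  attr(out, "sweep") <- sweep
  attr(out, "fdr") <- fdr
  class(out) <- c("cindy_pairs", class(out))
  out
}

#' Run the full conditional-mutual-information modulator inference pipeline
#'
#' One-shot wrapper: builds (or reuses) the MI-stratified CMI null, scores
#' all triplets, counts significant targets per (M, TF), builds the
#' randomized-modulator N_sig null and calls pairs at the requested FDR.
#'
#' @inheritParams score_triplets
#' @inheritParams build_nsig_null
#' @param fdr FDR threshold for pair calling.
#' @param null optional prebuilt [build_cmi_null()] model.
#' @param null_args list of overrides for [build_cmi_null()]
#'   (`n_pairs`, `n_perm`, `n_bins`).
#' @return object of class `cindy_fit`: list with `pairs`, `triplets`,
#'   `nsig`, `nsig_null`, `null`, `config`.  `tidy()` returns the pair
#'   table; `glance()` a one-row run summary.
#' @export
cindy <- function(mat, modulators, tfs, targets = NULL, null = NULL,
                  alpha = 0.05, correction = "bonferroni", fdr = 0.05,
                  n_rounds = 10L, pool = c("tf", "all"),
                  null_args = list(), seed = 1L) {
  pool <- match.arg(pool)
  targets <- targets %||% rownames(mat)
  if (is.null(null)) {
    args <- modifyList(list(mat = mat, tfs = tfs, targets = targets,
                            modulators = modulators,
                            n_pairs = 1000L, n_perm = 200L, n_bins = 20L,
                            seed = seed),
                       null_args)
    null <- do.call(build_cmi_null, args)
  }
  triplets <- score_triplets(mat, modulators, tfs, targets, null,
                             alpha = alpha, correction = correction,
                             seed = seed)
  nsig <- count_significant(triplets)
  nsig_null <- build_nsig_null(mat, modulators, tfs, targets, null,
                               alpha = alpha, correction = correction,
                               n_rounds = n_rounds, pool = pool, seed = seed)
  pairs <- call_modulations(nsig, nsig_null, fdr = fdr)
  structure(list(pairs = pairs, triplets = triplets, nsig = nsig,
                 nsig_null = nsig_null, null = null,
                 config = list(alpha = alpha, correction = correction,
                               fdr = fdr, n_rounds = n_rounds, pool = pool,
                               seed = seed)),
            class = "cindy_fit")
}

#' @export
tidy.cindy_fit <- function(x, ...) x$pairs

#' @export
glance.cindy_fit <- function(x, ...) {
  tibble(n_pairs_tested = nrow(x$pairs),
         n_called = sum(x$pairs$called),
         n_triplets = nrow(x$triplets),
         fdr = x$config$fdr,
         alpha = x$config$alpha,
         seed = x$config$seed)
}

#' @export
print.cindy_fit <- function(x, ...) {
  cat(sprintf("cindy fit: %d (M, TF) pairs tested, %d called at FDR %.2g\n",
              nrow(x$pairs), sum(x$pairs$called), x$config$fdr))
  invisible(x)
}
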