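pair_key <- function(df) paste(df$m_id, df$tf_id, sep = "\r")

#' Precision and recall of called pairs against a gold standard
#'
#' The gold standard is first restricted to the tested universe (pairs the
#' algorithm could possibly have called): recall against unobservable pairs
#' measures dataset coverage, not algorithm quality.  Then
#' `precision = |called n gold| / |called|` and
#' `recall = |called n gold| / |gold n universe|`.  Gold-standard coverage
#' of true biology is sparse, so precision is a comparative metric only.
#'
#' @param called tibble with `m_id`, `tf_id` columns (the called pairs).
#' @param gold a [read_gold_standard()] tibble (or any `m_id`/`tf_id`
#'   tibble).
#' @param universe tibble of all tested pairs; `called` must be a subset.
#' @return one-row tibble: `n_called, n_gold, tp, precision, recall`
#'   (`precision` is `NA` when nothing was called).
#' @export
precision_recall <- function(called, gold, universe) {
  uk <- unique(pair_key(universe))
  ck <- unique(pair_key(called))
  if (length(setdiff(ck, uk)))
    abort("called pairs must be a subset of the tested universe")
  gk <- intersect(unique(pair_key(gold)), uk)
  if (!length(gk)) abort("gold standard does not intersect the tested universe")
  tp <- length(intersect(ck, gk))
  tibble(n_called = length(ck), n_gold = length(gk), tp = tp,
         precision = if (length(ck)) tp / length(ck) else NA_real_,
         recall = tp / length(gk))
}

#' Precision/recall sweep over N_sig stringency thresholds
#'
#' For every threshold `k = 1..k_max`, calls the pairs with `n_sig >= k`
#' and evaluates them against the gold standard.  Recall is non-increasing
#' in `k`; precision typically rises with stringency.
#'
#' @param pair_results tibble carrying `m_id`, `tf_id`, `n_sig` (pairs with
#'   `NA` n_sig -- e.g. prefiltered ones -- are treated as never called but
#'   stay in the universe).
#' @param gold gold-standard pair tibble.
#' @param universe tested-pair universe (default: `pair_results` itself).
#' @param k_max largest threshold.
#' @return tibble of class `benchmark_curve`: `k, n_called, tp, precision,
#'   recall`.
#' @export
threshold_sweep <- function(pair_results, gold, universe = pair_results,
                            k_max = 300L) {
  uk <- unique(pair_key(universe))
  gk <- intersect(unique(pair_key(gold)), uk)
  if (!length(gk)) abort("gold standard does not intersect the tested universe")
  ns <- pair_results$n_sig
  ns[is.na(ns)] <- -1L
  keys <- pair_key(pair_results)
  out <- purrr::map_dfr(seq_len(k_max), function(k) {
    ck <- unique(keys[ns >= k])
    tp <- length(intersect(ck, gk))
    tibble(k = k, n_called = length(ck), tp = tp,
           precision = if (length(ck)) tp / length(ck) else NA_real_,
           recall = tp / length(gk))
  })
  class(out) <- c("benchmark_curve", class(out))
  out
}

#' @export
autoplot.benchmark_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("precision", "recall"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "N_sig threshold (called when N_sig >= k)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cmi_null <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$null_values), function(b) {
    v <- object$null_values[[b]]
    tibble(bin = b, mi_mid = (object$bin_edges[b] + object$bin_edges[b + 1]) / 2,
           median = median(v), q95 = quantile(v, 0.95))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mi_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median, colour = "median")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q95, colour = "95th percentile")) +
    ggplot2::labs(x = "TF-target MI (nats)", y = "null CMI (nats)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cindy_pairs <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_sig, y = -log10(.data$q),
                               colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "significant conditional target interactions (N_sig)",
                  y = "-log10 FDR q-value", colour = "called") +
    ggplot2::theme_minimal()
}

#' Plot a precision/recall comparison of two result sets
#'
#' Convenience wrapper building [threshold_sweep()] curves for both methods
#' and overlaying them.
#'
#' @param cindy_pairs,mindy_pairs pair tables carrying `n_sig`.
#' @param gold gold-standard tibble.
#' @param k_max sweep limit.
#' @return a ggplot object.
#' @export
plot_method_comparison <- function(cindy_pairs, mindy_pairs, gold,
                                   k_max = 300L) {
  a <- threshold_sweep(cindy_pairs, gold, k_max = k_max)
  b <- threshold_sweep(mindy_pairs, gold, k_max = k_max)
  df <- bind_rows(mutate(as_tibble(a), method = "CMI (full)"),
                  mutate(as_tibble(b), method = "delta-I (tails)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$method)) +
    ggplot2::geom_path() +
    ggplot2::theme_minimal()
}
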