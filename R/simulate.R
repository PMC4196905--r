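#' Configure a planted regulatory triplet
#'
#' Describes one (modulator, TF, targets) system for the synthetic
#' generator.  Two topologies are supported, mirroring the two competing
#' three-way network hypotheses:
#'
#' * `"modulated"`: the modulator rescales the TF-target coupling,
#'   `Tg = alpha * TF + beta * g(M) * TF + sigma * eps` with
#'   `g(M) = plogis(3 M)` a switch-like logistic squash to `[0, 1]`; this is
#'   the genuine
#'   three-way interaction.
#' * `"independent"`: modulator and TF regulate the target additively and
#'   independently, `Tg = alpha * TF + gamma * M + sigma * eps`; there is no
#'   three-way term, so conditioning on M must reveal no modulation.
#'
#' The modulator and TF are standard normal with
#' `TF = rho_mt * M + sqrt(1 - rho_mt^2) * z`, so `rho_mt` controls the
#' modulator-TF expression correlation (the regime that defeats tail-based
#' heuristics relying on an independence prefilter).
#'
#' @param topology `"modulated"` or `"independent"`.
#' @param n_targets number of target genes in this system.
#' @param beta modulation strength (forced to 0 for `"independent"`).
#' @param alpha baseline TF-target coupling.
#' @param gamma additive modulator-target coupling (independent topology
#'   only; forced to 0 for `"modulated"`).
#' @param rho_mt modulator-TF correlation, in (-1, 1).
#' @param sigma target noise standard deviation (> 0).
#' @return one-row tibble of triplet settings.
#' @export
triplet_config <- function(topology = c("modulated", "independent"),
                           n_targets = 50L, beta = 2.5, alpha = 0.1,
                           gamma = 0.5, rho_mt = 0, sigma = 0.5) {
  topology <- match.arg(topology)
  if (topology == "independent") beta <- 0
  if (topology == "modulated") gamma <- 0
  tibble(topology = topology, n_targets = as.integer(n_targets),
         beta = beta, alpha = alpha, gamma = gamma,
         rho_mt = rho_mt, sigma = sigma)
}

#' Specify a synthetic expression dataset
#'
#' Bundles sample size, decoy count, planted triplet configurations and the
#' master seed.  Validation errors name the offending field.
#'
#' @param n_samples number of expression profiles (columns).
#' @param n_decoys number of i.i.d. standard-normal decoy genes.
#' @param triplets tibble of triplet configurations ([triplet_config()]
#'   rows).
#' @param seed master seed; every gene derives its own RNG stream from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 300L, n_decoys = 200L,
                           triplets = triplet_config(), seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 3)
    abort("invalid `n_samples`: need at least 3")
  if (!is.numeric(n_decoys) || n_decoys < 0)
    abort("invalid `n_decoys`: must be non-negative")
  triplets <- as_tibble(triplets)
  need <- c("topology", "n_targets", "beta", "alpha", "gamma", "rho_mt", "sigma")
  miss <- setdiff(need, names(triplets))
  if (length(miss))
    abort(paste0("invalid `triplets`: missing fields ", paste(miss, collapse = ", ")))
  if (any(triplets$sigma <= 0)) abort("invalid `sigma`: must be > 0")
  if (any(abs(triplets$rho_mt) >= 1)) abort("invalid `rho_mt`: need |rho_mt| < 1")
  if (any(triplets$beta < 0)) abort("invalid `beta`: must be >= 0")
  if (any(triplets$topology == "independent" & triplets$beta != 0))
    abort("invalid `beta`: independent topology forces beta = 0")
  if (any(triplets$n_targets < 1)) abort("invalid `n_targets`: need >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_decoys = as.integer(n_decoys),
                 triplets = triplets, seed = as.integer(seed)),
            class = "synthetic_spec")
}

gene_stream <- function(seed, gene_id, n) {
  withr::with_seed(mix_seed(seed, "gene", gene_id), rnorm(n))
}

#' Generate a synthetic expression matrix with planted modulation events
#'
#' Draws every gene from its own RNG stream keyed by `(seed, gene id)` (so
#' adding triplets or decoys does not perturb existing genes), assembles the
#' planted systems described by the spec, appends i.i.d. decoy genes, and
#' shuffles the row order deterministically.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `matrix` (genes x samples, dimnames set),
#'   `truth` (tibble: `m_id`, `tf_id`, `tg_id`, `topology`, `beta`) and
#'   `positives` (tibble of distinct true modulated `(m_id, tf_id)` pairs).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(spec$triplets))) {
    cfg <- spec$triplets[i, ]
    m_id <- sprintf("M%03d", i)
    tf_id <- sprintf("TF%03d", i)
    m <- gene_stream(spec$seed, m_id, n)
    z <- gene_stream(spec$seed, paste0(tf_id, ".z"), n)
    tf <- cfg$rho_mt * m + sqrt(1 - cfg$rho_mt^2) * z
    rows[[m_id]] <- m
    rows[[tf_id]] <- tf
    gm <- plogis(3 * m)
    for (j in seq_len(cfg$n_targets)) {
      tg_id <- sprintf("TG%03d_%03d", i, j)
      eps <- gene_stream(spec$seed, tg_id, n)
      rows[[tg_id]] <- if (cfg$topology == "modulated") {
        cfg$alpha * tf + cfg$beta * gm * tf + cfg$sigma * eps
      } else {
        cfg$alpha * tf + cfg$gamma * m + cfg$sigma * eps
      }
      truth[[tg_id]] <- tibble(m_id = m_id, tf_id = tf_id, tg_id = tg_id,
                               topology = cfg$topology, beta = cfg$beta)
    }
  }
  for (k in seq_len(spec$n_decoys)) {
    d_id <- sprintf("DEC%04d", k)
    rows[[d_id]] <- gene_stream(spec$seed, d_id, n)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- sprintf("S%04d", seq_len(n))
  ord <- withr::with_seed(mix_seed(spec$seed, "shuffle"),
                          sample.int(nrow(mat)))
  mat <- mat[ord, , drop = FALSE]
  truth <- if (length(truth)) bind_rows(truth) else
    tibble(m_id = character(), tf_id = character(), tg_id = character(),
           topology = character(), beta = double())
  positives <- truth %>%
    filter(.data$topology == "modulated") %>%
    distinct(.data$m_id, .data$tf_id)
  attr(mat, "zero_variance") <- character(0)
  list(matrix = mat, truth = truth, positives = positives)
}

#' Preset benchmark fixtures on disk
#'
#' Writes a complete, self-contained benchmark input set: expression TSV,
#' modulator/TF/target lists, gold-standard pairs (= the planted positives)
#' and a YAML run configuration.  The `small` preset supports a full
#' pipeline run in well under two minutes on one CPU; `medium` is the
#' planted-recovery benchmark (n = 300, 10 modulated systems of 50 targets,
#' 20 decoy candidate modulators giving 200 decoy modulator-TF
#' combinations).
#'
#' @param preset `"small"` or `"medium"`.
#' @param dir output directory (created if needed).
#' @param seed master generator seed.
#' @return invisible named list of the file paths plus the ground truth.
#' @export
make_benchmark_fixture <- function(preset = c("small", "medium"), dir,
                                   seed = 1L) {
  preset <- match.arg(preset)
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      abort(paste0("cannot create directory: ", dir))
  cfg <- switch(preset,
    small = list(n_samples = 150L, n_systems = 3L, n_targets = 10L,
                 n_decoy_mods = 7L, n_decoys = 20L,
                 null = list(n_pairs = 80L, n_perm = 60L, n_bins = 8L),
                 n_rounds = 8L, pool = "all"),
    medium = list(n_samples = 300L, n_systems = 10L, n_targets = 50L,
                  n_decoy_mods = 20L, n_decoys = 60L,
                  null = list(n_pairs = 1000L, n_perm = 200L, n_bins = 20L),
                  n_rounds = 8L, pool = "all"))
  spec <- synthetic_spec(
    n_samples = cfg$n_samples, n_decoys = cfg$n_decoys,
    triplets = bind_rows(lapply(seq_len(cfg$n_systems),
                                function(i) triplet_config(n_targets = cfg$n_targets))),
    seed = seed)
  gen <- generate_expression(spec)
  gene_ids <- rownames(gen$matrix)
  mods <- c(sort(unique(gen$truth$m_id)),
            head(sort(grep("^DEC", gene_ids, value = TRUE)), cfg$n_decoy_mods))
  tfs <- sort(unique(gen$truth$tf_id))
  targets <- sort(unique(gen$truth$tg_id))
  paths <- list(
    matrix = file.path(dir, "matrix.tsv"),
    modulators = file.path(dir, "modulators.txt"),
    tfs = file.path(dir, "tfs.txt"),
    targets = file.path(dir, "targets.txt"),
    gold = file.path(dir, "gold.tsv"),
    config = file.path(dir, "config.yaml"))
  write_expression(gen$matrix, paths$matrix)
  writeLines(mods, paths$modulators)
  writeLines(tfs, paths$tfs)
  writeLines(targets, paths$targets)
  writeLines(paste(gen$positives$m_id, gen$positives$tf_id, sep = "\t"),
             paths$gold)
  run_cfg <- list(seed = as.integer(seed), fdr = 0.05, alpha_triplet = 0.05,
                  null = cfg$null, n_rounds = cfg$n_rounds, pool = cfg$pool)
  yaml::write_yaml(run_cfg, paths$config)
  invisible(c(paths, list(truth = gen$truth, positives = gen$positives)))
}
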