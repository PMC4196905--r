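# Shared fixture builders (all data generated in code at test time).

# random strict rank vector
rand_ranks <- function(n, seed) withr::with_seed(seed, sample.int(n))

# bivariate Gaussian profiles with correlation rho
gauss_pair <- function(n, rho, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    list(x = x, y = y)
  })
}

# trivariate Gaussian with partial correlation pc between tf and tg given m
gauss_triplet <- function(n, pc, seed, rho_m = 0.5) {
  withr::with_seed(seed, {
    m <- rnorm(n)
    u <- rnorm(n)
    w <- rnorm(n)
    tf <- rho_m * m + sqrt(1 - rho_m^2) * u
    tg <- rho_m * m + sqrt(1 - rho_m^2) * (pc * u + sqrt(1 - pc^2) * w)
    list(m = m, tf = tf, tg = tg)
  })
}

# small expression TSV on disk; returns the path
write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# planted-system expression set used across pipeline tests
planted_fixture <- function(n_samples, n_systems, n_targets, n_decoy_mods,
                            seed, rho_mt = 0, n_decoys = 30L) {
  spec <- synthetic_spec(
    n_samples = n_samples, n_decoys = n_decoys,
    triplets = dplyr::bind_rows(lapply(seq_len(n_systems), function(i)
      triplet_config(n_targets = n_targets, rho_mt = rho_mt))),
    seed = seed)
  gen <- generate_expression(spec)
  decs <- head(sort(grep("^DEC", rownames(gen$matrix), value = TRUE)),
               n_decoy_mods)
  list(mat = gen$matrix,
       mods = c(sort(unique(gen$truth$m_id)), decs),
       tfs = sort(unique(gen$truth$tf_id)),
       targets = sort(unique(gen$truth$tg_id)),
       truth = gen$truth,
       positives = gen$positives)
}

pairs_key <- function(df) paste(df$m_id, df$tf_id)
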