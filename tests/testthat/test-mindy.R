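test_that("tail selection is deterministic, disjoint and correctly sized", {
  tl <- select_tails(withr::with_seed(1, rnorm(20)), 0.35, seed = 2)
  expect_identical(length(tl$high), 7L)
  expect_identical(length(tl$low), 7L)
  expect_length(intersect(tl$high, tl$low), 0)

  # monotone profile: tails are the index extremes
  tl2 <- select_tails(1:10, 0.3)
  expect_identical(sort(tl2$high), 8:10)
  expect_identical(sort(tl2$low), 1:3)

  # boundary ties resolved reproducibly by the seeded rank transform
  x <- c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8)
  expect_identical(select_tails(x, 0.3, seed = 5),
                   select_tails(x, 0.3, seed = 5))
  expect_error(select_tails(1:10, 0.6), "overlap")
})

test_that("baseline defaults match the published parameterization", {
  p <- mindy_params()
  expect_identical(p$tail_fraction, 0.35)
  expect_identical(p$p_indep_m_tf, 1e-5)
  expect_identical(p$alpha_corrected, 0.05)
  expect_identical(p$p_dep_tf_tg, 1e-6)
  expect_identical(p$fdr, 0.05)
  expect_error(mindy_params(tail_fraction = 0.7), "0.5")
  expect_error(mindy_params(fdr = 0), "thresholds")
})

test_that("MI null p-values are calibrated and reach extrapolated depths", {
  mn <- build_mi_null(200, n_null = 500, seed = 3)
  # independent profiles get roughly uniform p-values
  ps <- vapply(1:200, function(s) {
    mi <- estimate_mi(rand_ranks(200, s + 1000), rand_ranks(200, s + 3000))
    mi_pvalue(mn, mi)
  }, 0)
  expect_gt(mean(ps > 1e-5), 0.97)
  # strong dependence extrapolates far beyond the empirical range
  g <- gauss_pair(200, 0.8, 4)
  expect_lt(mi_pvalue(mn, estimate_mi(g$x, g$y)), 1e-6)
})

test_that("the independence prefilter drops coupled modulator-TF pairs", {
  withr::with_seed(6, {
    n <- 300
    m1 <- rnorm(n)
    mat <- rbind(M1 = m1, M2 = rnorm(n), TFa = m1 + 0.01 * rnorm(n),
                 TFb = rnorm(n))
    colnames(mat) <- paste0("s", 1:n)
  })
  mn <- build_mi_null(300, n_null = 500, seed = 1)
  pf <- prefilter_pairs(mat, c("M1", "M2"), c("TFa", "TFb"),
                        mi_null = mn, seed = 1)
  expect_identical(nrow(pf), 4L)  # <= |M| x |TF|
  expect_false(pf$admissible[pf$m_id == "M1" & pf$tf_id == "TFa"])
  expect_true(pf$admissible[pf$m_id == "M2" & pf$tf_id == "TFb"])
})

test_that("the target prefilter requires dependence but rejects duplicates", {
  withr::with_seed(8, {
    n <- 300
    tf <- rnorm(n)
    mat <- rbind(TF = tf,
                 dup = tf + 0.001 * rnorm(n),
                 coupled = 0.55 * tf + sqrt(1 - 0.55^2) * rnorm(n),
                 indep = rnorm(n))
    colnames(mat) <- paste0("s", 1:n)
  })
  mn <- build_mi_null(300, n_null = 500, seed = 2)
  pf <- prefilter_targets(mat, "TF", c("dup", "coupled", "indep"),
                          mi_null = mn, seed = 1)
  expect_false(pf$admissible[pf$tg_id == "indep"])   # no dependence
  expect_false(pf$admissible[pf$tg_id == "dup"])     # correlation ceiling
  expect_true(pf$admissible[pf$tg_id == "coupled"])
})

test_that("delta-I separates tail-specific coupling from uniform coupling", {
  n <- 300
  p_mod <- p_flat <- numeric(6)
  for (s in 1:6) {
    withr::with_seed(s + 40, {
      m <- rnorm(n)
      tf <- rnorm(n)
      on <- plogis(3 * m)             # coupling only at high modulator
      tg_mod <- 2 * on * tf + 0.5 * rnorm(n)
      tg_flat <- tf + 0.7 * rnorm(n)  # same coupling in both tails
    })
    p_mod[s] <- delta_i(tf, tg_mod, m, n_perm = 100, seed = s)$p
    p_flat[s] <- delta_i(tf, tg_flat, m, n_perm = 100, seed = s)$p
  }
  expect_gte(mean(p_mod <= 0.05), 0.8)
  expect_gte(mean(p_flat > 0.05), 0.8)
  expect_error(delta_i(rnorm(20), rnorm(20), rnorm(20), 0.35), "at least 10")
})

test_that("the tail-label permutation null is centred at zero", {
  withr::with_seed(9, {
    n <- 200
    m <- rnorm(n); tf <- rnorm(n); tg <- tf + rnorm(n)
  })
  tails <- select_tails(m, 0.35, 1)
  rtf <- rank_transform(tf, 1); rtg <- rank_transform(tg, 1)
  comb <- c(tails$high, tails$low)
  t <- length(tails$high)
  perms <- withr::with_seed(3, vapply(1:200, function(i)
    sample.int(2 * t), integer(2 * t)))
  di <- .delta_i_perm_cpp(rtf[comb], rtg[comb], perms, t,
                          qchisq(0.95, 3), 4L, 8L)
  expect_lt(abs(mean(di)), 0.03)
})

test_that("the baseline pipeline runs and prefiltered pairs stay uncallable", {
  fx <- planted_fixture(n_samples = 250, n_systems = 2, n_targets = 10,
                        n_decoy_mods = 3, seed = 31, rho_mt = 0.6)
  mfit <- run_mindy(fx$mat, fx$mods, fx$tfs, fx$targets,
                    params = mindy_params(n_perm = 60L),
                    n_rounds = 2, pool = "all", seed = 2)
  pr <- tidy(mfit)
  # candidate universe is the full grid
  expect_identical(nrow(pr), length(fx$mods) * length(fx$tfs))
  # strongly coupled planted modulators are blocked by the prefilter
  blocked <- pr[!pr$admissible, ]
  expect_true(all(pairs_key(fx$positives) %in% pairs_key(blocked)))
  expect_false(any(blocked$called))
  # an empty admissible set is handled without error
  m_empty <- run_mindy(fx$mat, fx$tfs[1], fx$tfs[2],
                       fx$targets[1:4],
                       params = mindy_params(p_indep_m_tf = 1 - 1e-9,
                                             n_perm = 30L),
                       n_rounds = 2, seed = 2)
  expect_false(any(tidy(m_empty)$called))
})
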