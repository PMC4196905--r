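# shared small planted dataset + null model for the pipeline tests
local_fixture <- NULL
get_fixture <- function() {
  if (is.null(local_fixture)) {
    fx <- planted_fixture(n_samples = 250, n_systems = 3, n_targets = 12,
                          n_decoy_mods = 5, seed = 21)
    fx$null <- build_cmi_null(fx$mat, tfs = fx$tfs, targets = fx$targets,
                              modulators = fx$mods,
                              n_pairs = 100, n_perm = 80, n_bins = 10,
                              seed = 8)
    local_fixture <<- fx
  }
  local_fixture
}

test_that("triplet scoring enumerates exactly the admissible triplets", {
  fx <- get_fixture()
  tr <- score_triplets(fx$mat, modulators = fx$mods[1], tfs = fx$tfs[1],
                       targets = fx$targets[1:3], null = fx$null)
  expect_identical(nrow(tr), 3L)
  expect_true(all(tr$m_id != tr$tf_id & tr$m_id != tr$tg_id &
                  tr$tf_id != tr$tg_id))
  expect_true(all(tr$p > 0 & tr$p <= 1))
  expect_error(
    score_triplets(fx$mat, "MISSING_GENE", fx$tfs[1], fx$targets[1:3],
                   null = fx$null),
    "MISSING_GENE")
})

test_that("planted three-way interactions score significant, decoys do not", {
  fx <- get_fixture()
  tr <- score_triplets(fx$mat, modulators = c("M001", "DEC0001"),
                       tfs = "TF001",
                       targets = grep("^TG001", fx$targets, value = TRUE),
                       null = fx$null)
  planted <- tr[tr$m_id == "M001", ]
  decoy <- tr[tr$m_id == "DEC0001", ]
  expect_gt(sum(planted$significant), nrow(planted) / 3)
  expect_identical(sum(decoy$significant), 0L)
})

test_that("N_sig counting is order-invariant and monotone in alpha", {
  fx <- get_fixture()
  tr <- score_triplets(fx$mat, modulators = fx$mods[1:4], tfs = fx$tfs,
                       targets = fx$targets, null = fx$null)
  ns <- count_significant(tr)
  shuffled <- tr[withr::with_seed(2, sample.int(nrow(tr))), ]
  expect_equal(dplyr::arrange(count_significant(shuffled), m_id, tf_id),
               dplyr::arrange(ns, m_id, tf_id))
  # relaxing the corrected threshold never lowers any N_sig
  tr_strict <- score_triplets(fx$mat, modulators = fx$mods[1:4], tfs = fx$tfs,
                              targets = fx$targets, null = fx$null,
                              alpha = 0.01)
  ns_strict <- count_significant(tr_strict)
  j <- dplyr::inner_join(ns, ns_strict, by = c("m_id", "tf_id"))
  expect_true(all(j$n_sig.x >= j$n_sig.y))
})

test_that("genes annotated as both modulator and TF run in both roles", {
  fx <- get_fixture()
  dual <- c("TF001", "TF002")  # use TFs as candidate modulators of each other
  tr <- score_triplets(fx$mat, modulators = dual, tfs = dual,
                       targets = fx$targets[1:5], null = fx$null)
  expect_true(all(c("TF001", "TF002") %in% tr$m_id))
  expect_true(all(c("TF001", "TF002") %in% tr$tf_id))
  # no self-modulation triplets
  expect_true(all(tr$m_id != tr$tf_id))
})

test_that("the randomized-modulator N_sig null is small, seeded and complete", {
  fx <- get_fixture()
  nn1 <- build_nsig_null(fx$mat, modulators = fx$mods[1:6], tfs = fx$tfs,
                         targets = fx$targets, null = fx$null,
                         n_rounds = 2, seed = 3)
  nn2 <- build_nsig_null(fx$mat, modulators = fx$mods[1:6], tfs = fx$tfs,
                         targets = fx$targets, null = fx$null,
                         n_rounds = 2, seed = 3)
  expect_identical(as.data.frame(nn1), as.data.frame(nn2))
  # one null N_sig per (modulator, TF, round)
  expect_identical(nrow(nn1), 2L * 6L * length(fx$tfs))
  # randomized modulators rarely modulate anything
  expect_lt(quantile(nn1$n_sig, 0.95), 3)
  expect_error(
    build_nsig_null(fx$mat, fx$mods[1:2], fx$tfs, fx$targets, fx$null,
                    n_rounds = 1),
    "at least 2")
})

test_that("pair calling separates planted modulators from the null", {
  nsig <- tibble::tibble(m_id = c("Mplanted", "Mdecoy"),
                         tf_id = "TF1",
                         n_sig = c(40L, 0L), n_targets = c(50L, 50L))
  nsig_null <- tibble::tibble(round = rep(1:20, each = 2),
                              m_id = rep(c("a", "b"), 20),
                              tf_id = "TF1",
                              n_sig = withr::with_seed(4, rpois(40, 0.5)))
  attr(nsig_null, "pool") <- "tf"
  calls <- call_modulations(nsig, nsig_null, fdr = 0.05)
  expect_true(calls$called[calls$m_id == "Mplanted"])
  expect_false(calls$called[calls$m_id == "Mdecoy"])
  # N_sig = 0 is never callable regardless of the null
  expect_false(any(calls$called[calls$n_sig == 0]))
  # the stringency sweep spans k = 1..300 and is monotone
  sw <- attr(calls, "sweep")
  expect_identical(sw$k, 1:300)
  expect_true(all(diff(sw$n_called) <= 0))
  expect_identical(sw$n_called[1], 1L)
})

test_that("the full pipeline recovers planted modulations end to end", {
  fx <- get_fixture()
  fit <- cindy(fx$mat, fx$mods, fx$tfs, fx$targets, null = fx$null,
               n_rounds = 8, pool = "all", seed = 7)
  pr <- tidy(fit)
  expect_s3_class(pr, "cindy_pairs")
  called <- pr[pr$called, ]
  expect_setequal(pairs_key(called), pairs_key(fx$positives))
  g <- glance(fit)
  expect_identical(g$n_called, nrow(fx$positives))
  expect_identical(g$n_pairs_tested, length(fx$mods) * length(fx$tfs) -
                     sum(fx$mods %in% fx$tfs))
})
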