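# small expression set with a spread of TF-target couplings, so the MI
# bins are meaningfully stratified
null_fixture <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in 1:6) {
      tf <- rnorm(n)
      rows[[paste0("TF", i)]] <- tf
      for (j in 1:6) {
        a <- (j - 1) / 3  # couplings 0 .. 1.67
        rows[[sprintf("TG%d_%d", i, j)]] <- a * tf + rnorm(n)
      }
    }
    for (k in 1:12) rows[[paste0("DEC", k)]] <- rnorm(n)
    do.call(rbind, rows)
  })
}

test_that("extended-exponential tail fits recover an exponential rate", {
  bs <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rexp(2000, rate = 5))
    fit <- fit_tail(x)
    expect_lt(fit$b, 0)
    fit$b
  }, 0)
  expect_lt(abs(mean(bs) + 5) / 5, 0.15)
  # c stays at 1 for genuinely exponential data in the large majority of
  # draws (the stretch is only accepted when it quarters the tail SSE)
  cs <- vapply(1:10, function(s)
    fit_tail(withr::with_seed(s, rexp(2000, 5)))$c, 0)
  expect_gte(mean(cs == 1), 0.8)
  # a genuinely stretched null adopts c well below 1
  cw <- vapply(1:10, function(s)
    fit_tail(withr::with_seed(s, rweibull(2000, 0.5, 0.1)))$c, 0)
  expect_gte(mean(cw < 0.85), 0.8)
})

test_that("translating the null shifts the intercept, not the slope", {
  x <- withr::with_seed(42, rexp(5000, rate = 3))
  f0 <- fit_tail(x)
  f1 <- fit_tail(x + 0.1)
  expect_equal(f1$b, f0$b, tolerance = 1e-8)
  expect_equal(f1$a, f0$a - 0.1 * f0$b, tolerance = 1e-6)
})

test_that("tail fitting rejects degenerate or tiny inputs", {
  expect_error(fit_tail(rep(0.5, 500)), "degenerate")
  expect_error(fit_tail(runif(50)), "at least 100")
})

test_that("null model construction is reproducible and correctly shaped", {
  mat <- null_fixture()
  nm1 <- build_cmi_null(mat, tfs = paste0("TF", 1:6),
                        targets = grep("^TG", rownames(mat), value = TRUE),
                        n_pairs = 100, n_perm = 50, n_bins = 10, seed = 5)
  nm2 <- build_cmi_null(mat, tfs = paste0("TF", 1:6),
                        targets = grep("^TG", rownames(mat), value = TRUE),
                        n_pairs = 100, n_perm = 50, n_bins = 10, seed = 5)
  expect_identical(nm1$bin_edges, nm2$bin_edges)
  expect_identical(nm1$bins, nm2$bins)
  expect_identical(nm1$meta, nm2$meta)
  # 10 bins x (100/10 pairs) x 50 perms = 500 null values per bin
  expect_identical(nm1$bins$n_pairs, rep(10L, 10))
  expect_identical(nm1$bins$n_null, rep(500L, 10))
  # p-values reproduce an independently computed empirical survival when
  # probed at the MI of pairs with unique (untied) MI values
  uniq <- nm1$pairs[!(duplicated(nm1$pairs$mi) |
                      duplicated(nm1$pairs$mi, fromLast = TRUE)), ]
  probe <- uniq[withr::with_seed(1, sample.int(nrow(uniq), 5)), ]
  for (i in seq_len(nrow(probe))) {
    nv <- nm1$null_values[[probe$bin[i]]]
    for (x in unname(quantile(nv, c(0.3, 0.5, 0.9)))) {
      expect_equal(cmi_pvalue(nm1, probe$mi[i], x),
                   (1 + sum(nv >= x)) / (1 + length(nv)))
    }
  }
  # survival at the per-bin median is about one half wherever the median
  # is not part of a tie mass (probing via a unique member pair's MI)
  for (i in seq_len(nrow(uniq))) {
    nv <- nm1$null_values[[uniq$bin[i]]]
    med <- median(nv)
    if (mean(nv == med) > 0) next
    expect_lt(abs(cmi_pvalue(nm1, uniq$mi[i], med) - 0.5), 0.05)
  }
})

test_that("high-MI bins hold stochastically larger null CMI", {
  mat <- null_fixture(n = 150, seed = 3)
  nm <- build_cmi_null(mat, tfs = paste0("TF", 1:6),
                       targets = grep("^TG", rownames(mat), value = TRUE),
                       n_pairs = 150, n_perm = 60, n_bins = 6, seed = 2)
  meds <- vapply(nm$null_values, median, 0)
  # stochastic ordering of bin medians: top bin far above bottom bin and
  # rank correlation with bin index strongly positive
  expect_gt(meds[6], meds[1])
  expect_gt(cor(seq_along(meds), meds, method = "spearman"), 0.7)
})

test_that("p-values behave like a calibrated upper-tail survival", {
  mat <- null_fixture(n = 100, seed = 7)
  # continuous stub statistic: exercises the p-value machinery with an
  # atom-free null, so quantile probes are exact
  nm <- build_cmi_null(mat, tfs = paste0("TF", 1:6),
                       targets = grep("^TG", rownames(mat), value = TRUE),
                       n_pairs = 120, n_perm = 60, n_bins = 6, seed = 11,
                       cmi_fun = function(rtf, rtg, rm)
                         sum(rm * rtf) / (length(rm)^2 * 10))
  b3 <- nm$pairs$mi[nm$pairs$bin == 3][1]
  expect_identical(cmi_pvalue(nm, b3, 0), 1)
  # empirical 95th percentile maps to p ~ 0.05
  q95 <- quantile(nm$null_values[[3]], 0.95)
  expect_lt(abs(cmi_pvalue(nm, b3, q95) - 0.05), 0.01)
  # monotone in CMI within a bin, including the extrapolated region
  grid <- seq(0, max(nm$null_values[[3]]) * 3, length.out = 60)
  ps <- cmi_pvalue(nm, rep(b3, 60), grid)
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("the null model survives a serialization round trip", {
  mat <- null_fixture(n = 80, seed = 5)
  nm <- build_cmi_null(mat, tfs = paste0("TF", 1:3),
                       targets = grep("^TG[123]_", rownames(mat), value = TRUE),
                       n_pairs = 40, n_perm = 40, n_bins = 4, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_null_model(nm, path)
  back <- read_null_model(path)
  expect_equal(back$bin_edges, nm$bin_edges)
  expect_equal(back$bins, nm$bins, ignore_attr = TRUE)
  expect_equal(back$null_values, nm$null_values)
  # identical p-values from the restored model
  probe <- nm$pairs$mi[7]
  expect_equal(cmi_pvalue(back, probe, 0.1), cmi_pvalue(nm, probe, 0.1))
})

test_that("null construction validates its inputs", {
  mat <- null_fixture(n = 60, seed = 2)
  expect_error(build_cmi_null(mat, tfs = "NOPE", n_pairs = 10),
               "missing from the expression matrix")
  expect_warning(
    build_cmi_null(mat, tfs = "TF1",
                   targets = grep("^TG", rownames(mat), value = TRUE),
                   n_pairs = 100, n_perm = 30, n_bins = 2, seed = 1),
    "using all")
})
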