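---
title: "Inferring post-translational modulators of TF activity from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring post-translational modulators of TF activity from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cindy)
library(dplyr)
```

## The problem

A transcription factor's (TF) effect on its target genes is rarely static:
kinases, phosphatases, acetyltransferases and other signaling proteins
rewire it post-translationally.  Such modulators are invisible to pairwise
co-expression analysis because the modulator changes the *coupling* between
TF and target rather than either gene's own expression level.

`cindy` infers candidate modulators from a gene expression matrix alone.
For every candidate triplet of a modulator M, a TF and a target Tg it asks
whether the TF-target statistical dependence changes along the modulator's
expression range.  The statistic is the full conditional mutual information

$$ I(\mathrm{TF};\mathrm{Tg} \mid M) \;=\;
   \sum p(\mathrm{tf},\mathrm{tg},m)\,
   \log\frac{p(m)\,p(\mathrm{tf},\mathrm{tg},m)}
            {p(\mathrm{tf},m)\,p(\mathrm{tg},m)} , $$

estimated non-parametrically.  A genuine three-way interaction (the
modulator rescales the TF-target coupling) keeps CMI elevated above what
the pair's own mutual information predicts; an independent-regulation
topology does not.  The package also re-implements the classic tail-based
$\Delta I$ heuristic -- MI computed separately in the samples with highest
and lowest modulator expression -- as the comparison arm, including its
published prefilters, most importantly the requirement that the modulator
be expression-independent of its TF.  That prefilter is exactly what the
full-CMI analysis removes: co-expressed modulators become testable.

## The adaptive-partitioning estimator

All estimators run on the copula (rank) transform of each profile: ranks
`1..n` with ties broken by a seeded shuffle (`rank_transform()`).  This
makes every marginal exactly uniform, renders the estimates invariant to
any monotone normalization (microarray intensities and RPKM behave
identically), and makes median splits well defined.

The joint rank distribution is partitioned recursively
(`build_partition()`): each cell splits at the per-dimension lower median
of the points it contains into $2^d$ half-open subcells.  Two rules control
the recursion:

* **Resolution floor** (`max_cell`): a cell holding at least `max_cell`
  points is always subdivided.  This is the "initial partitioning" of the
  estimator; without it the plug-in estimate stalls far below the true
  information, because the unresolved dependence is spread across many
  cells whose individual deviations from uniformity are statistically
  invisible (we verified that single- and two-level chi-square tests,
  within-cell rank-correlation tests and global summed-chi-square stopping
  all leave a large fraction of Gaussian MI unrecovered).  Defaults:
  8 points in 2-D; in 3-D half the sample count, capped at 128 (the scaling
  matters below ~250 samples, where a fixed floor would never trigger).
* **Chi-square test** (`alpha = 0.05`, `uniformity_test()`): below the
  floor, a cell is subdivided only when its $2^d$ subcell counts reject
  local uniformity at `alpha` with $2^d - 1$ degrees of freedom.
  A minimum occupancy of $2^d$ points ends the recursion.

In 2-D the marginal cell probabilities are interval widths divided by *n*
-- exact under rank marginals -- so the joint plug-in term is the only
biased one and receives a Miller-Madow correction $(C_{occ}-1)/(2n)$.  In
3-D the (TF,M) and (Tg,M) marginals are obtained by counting all *n* points
inside each leaf's projected rectangle; their finite-count biases partially
cancel against the joint term's, so the 3-D estimate is used uncorrected.
Totals are clamped at zero, preserving non-negativity; the clamp creates an
atom of exact-zero estimates for weakly dependent pairs, which the null
model's bin lookup handles explicitly (below).

These defaults were fixed once by calibrating against analytic Gaussian
values (bivariate MI $-\tfrac12\log(1-\rho^2)$ across $\rho$, trivariate
CMI at fixed partial correlation, and conditional-independence topologies);
the acceptance tests re-verify the same properties.  Estimates are
bit-for-bit symmetric in (x, y) and in (TF, Tg): inputs are canonically
ordered (lexicographically smaller rank vector first) before the recursion,
so both argument orders run the identical computation.

## The MI-stratified permutation null

A CMI value is meaningless in isolation: conditioning a strongly coupled
pair on *any* irrelevant variable yields a large CMI.  The null model
(`build_cmi_null()`) therefore conditions on the pair's MI.  It samples
`n_pairs` (TF, Tg) pairs, estimates their MI, and for each pair computes
`n_perm` CMI values against randomized modulators -- a modulator profile
drawn from the modulator set with its sample order permuted, which destroys
any three-way coupling while preserving the modulator's marginal exactly
(after ranking, a permuted profile is just another uniform permutation).
The MI range is cut into `n_bins` equi-probable bins; at the full defaults
($10^4$ pairs, $10^3$ permutations, 100 bins) each bin holds 100 pairs and
$10^5$ null CMI values.

Within each bin the survival function's upper tail is modelled as an
extended exponential, $\log S(x) = a + b\,x^{c}$ with $b < 0$, fitted to
the top 25% of values (`fit_tail()`).  The stretch exponent stays at
$c = 1$ unless freeing it at least *quarters* the tail SSE; a plain halving
criterion triggered spuriously on genuinely exponential nulls in about a
third of draws, while quartering still accepts truly stretched (Weibull
$c = 0.5$) tails almost always.

`cmi_pvalue()` is the hybrid: the empirical survival
$(1 + \#\{ \mathrm{null} \ge x\})/(1 + N)$ inside the observed range, the
fitted tail only beyond it (its purpose is reaching p-values below the
$1/N$ permutation resolution), floored at $10^{-30}$.  The MI bin is found
by the query's mid-rank among the model's stored pair MI values: identical
to quantile-edge lookup wherever MI is continuous, and well defined on the
exact-zero atom, where many quantile edges coincide (a tied query maps to
the middle of its block of exchangeable strata).  Significance is
upper-tail (one-sided): modulation is reported as presence of extra
conditional dependence.

One caveat is intrinsic to stratification: within a bin, pairs near the
bin's upper MI edge face a pooled null that is slightly too small, so
p-values are mildly liberal at coarse bin counts.  The calibration test
(fraction of non-modulated triplets with $p < 0.05$) sits near 0.065 at the
scaled 20-bin setting used in testing; the effect shrinks as `n_bins`
grows toward the full 100.

## From triplets to modulator calls

`score_triplets()` evaluates every admissible (M, TF, Tg) triplet (three
distinct genes; constant-expression genes are excluded and listed), and
applies a Bonferroni correction across each (M, TF) pair's tested targets
(the conservative reading of a "corrected p-value threshold" of 0.05;
`correction` accepts any `p.adjust` method).  `N_sig`, the number of
significant conditional target interactions per pair
(`count_significant()`), is the pair-level evidence.

Pair significance uses a randomized-modulator null
(`build_nsig_null()`): every modulator profile is replaced by a permuted
copy and the whole scoring repeated for `n_rounds` rounds, yielding one
null `N_sig` per (modulator, TF, round).  `call_modulations()` computes the
empirical $p = (1 + \#\{\mathrm{null} \ge N_{sig}\})/(1 + \#\mathrm{null})$,
applies Benjamini-Hochberg across pairs, and calls pairs at `fdr` (default
0.05).  The null can be pooled per TF (conditions on the TF's target
spectrum) or globally (`pool = "all"`).  The choice is a resolution
trade-off: the smallest attainable p-value is 1/(1 + pool size), so with
*R* rounds, *m* modulators and *t* TFs, per-TF pooling bounds p at
$1/(1+Rm)$ while global pooling reaches $1/(1+Rmt)$.  The shipped
benchmark presets use global pooling because at affordable round counts the
per-TF bound cannot clear BH at FDR 0.05 for a handful of true pairs among
hundreds of candidates.  A stringency sweep (`N_sig >= k`, `k = 1..300`) is
attached to every call set for threshold-based benchmarking.

## The tail-based baseline

`run_mindy()` reproduces the $\Delta I$ heuristic with its published
defaults (`mindy_params()`): 35% expression tails (the parameter is
exposed because the original description is ambiguous between 35% and
25%), an (M, TF) independence prefilter at MI p-value $10^{-5}$, a
TF-target dependence requirement at $10^{-6}$ plus a rank-correlation
ceiling of 0.9 against near-duplicate targets, a corrected per-triplet
threshold of 0.05, and FDR 0.05 with the same randomized-modulator
machinery as the main pipeline.  Prefiltered pairs remain in the output as
uncallable rows so that benchmarking charges the heuristic for the
modulators it cannot test.

Two implementation notes.  MI p-values for the prefilters come from a
shared null of MI between independent random rank permutations
(`build_mi_null()`), which after the copula transform depends only on the
sample count; per-pair permutation tests at $10^{-6}$ resolution would need
millions of permutations each, while the shared null needs one
extended-exponential tail fit.  $\Delta I$ significance uses tail-label
permutations (`delta_i()`); beyond the empirical resolution the two-sided
p-value is extrapolated from a normal fit to the permutation null, since
Bonferroni-corrected calling at many targets needs p-values below
$1/(n_{perm}+1)$.

## The synthetic benchmark generator

`generate_expression()` plants known ground truth among decoys:

* **Modulated topology**: $M \sim N(0,1)$,
  $TF = \rho_{MT} M + \sqrt{1-\rho_{MT}^2}\,z$, and each target
  $Tg = \alpha\,TF + \beta\,g(M)\,TF + \sigma\,\varepsilon$ with
  $g(M) = \mathrm{plogis}(3M)$.  The modulator acts as a switch: coupling
  ramps from $\alpha$ to $\alpha + \beta$ along M.  Defaults
  ($\alpha = 0.1$, $\beta = 2.5$, $\sigma = 0.5$) describe strong,
  switch-like modulation -- TF-target correlation moves from about 0.2 to
  about 0.95 across the modulator range.  These are benchmark conditions
  for verifying the machinery, chosen once; weaker contrasts at a few
  hundred samples sink below the 3-D estimator's resolution for any
  method.
* **Independent topology**: $Tg = \alpha\,TF + \gamma\,M + \sigma\,
  \varepsilon$ ($\gamma = 0.5$): modulator and TF act additively, no
  three-way term.
* **Decoys**: i.i.d. standard normal genes.

Every gene draws from its own RNG stream keyed by `(seed, gene id)`, so
specs are extensible without perturbing existing genes, and generation is
bit-reproducible.  Gaussian marginals are sufficient because the rank
transform discards marginal shape anyway.

Two calibration subtleties are worth knowing.  Conditioning on a variable
that *feeds into the target additively* ($\gamma > 0$) genuinely increases
the TF-target conditional dependence -- such modulators are not
exchangeable with permuted ones, and their CMI p-values are legitimately
small even without a three-way term.  Calibration checks therefore use
decoy modulators (exchangeable with the permutation null by construction).
Conversely, a modulator that drives *both* TF and target (a common
upstream driver) has its spurious pairwise dependence removed by
conditioning; the acceptance tests verify both directions.

What the generator does not emulate: realistic transcriptome covariance,
count noise, batch effects, or modulators acting through unmeasured
proteins.  Passing these benchmarks shows the inferential machinery is
sound, not that any particular biological dataset will yield comparable
recall.

## Practical guidance and limitations

* **Sample count**: at least ~150 profiles; below that the 3-D estimator
  has little resolution (`read_expression()` warns).  The sample-size
  acceptance test tracks recall over n = 50..200 on fixed generative
  conditions.
* **Problem sizes in the shipped tests**: the test suite scales the
  full-size analyses down so the whole suite completes on one CPU in
  under ~20 minutes: null models of $10^3$ pairs x 200 permutations x 20
  bins, benchmarks of 10 planted systems x 50 targets among ~300 candidate
  pairs at n = 300, and a comparative run of 5 coupled systems at n = 600.
  The structural test of the full $10^4 \times 10^3 \times 100$ null runs
  with stub statistics.
* **Determinism**: every stage derives its RNG stream from the master seed
  via a string-keyed hash (`seed`, gene, pair, round), so results are
  byte-identical across runs and independent of scheduling; scoring is
  sequential.
* **Degenerate inputs**: constant profiles rank as a seeded shuffle and are
  flagged; the pipeline excludes them from all three roles and logs them.
  Duplicate gene rows keep the highest-variance profile on load.
* **Direction and sign**: the method reports presence of modulation, not
  its sign or mechanism; gold-standard matching is undirected by default
  because PPI databases are.
* **Precision against sparse gold standards** is comparative only: most
  true interactions are absent from any database, so absolute precision is
  badly underestimated by construction.

## A worked miniature

```{r mini, eval = FALSE}
dir <- tempfile()
make_benchmark_fixture("small", dir, seed = 1)
mat  <- read_expression(file.path(dir, "matrix.tsv"))
mods <- read_gene_list(file.path(dir, "modulators.txt"), "modulator")
tfs  <- read_gene_list(file.path(dir, "tfs.txt"), "transcription_factor")
tgts <- read_gene_list(file.path(dir, "targets.txt"), "target")
cfg  <- yaml::read_yaml(file.path(dir, "config.yaml"))

fit <- cindy(mat, mods, tfs, tgts,
             n_rounds = cfg$n_rounds, pool = cfg$pool,
             null_args = cfg$null, seed = cfg$seed)
tidy(fit)      # pair table: m_id, tf_id, n_sig, p, q, called
glance(fit)    # one-row run summary

gold <- read_gold_standard(file.path(dir, "gold.tsv"), symmetric = FALSE)
pr <- tidy(fit)
precision_recall(pr[pr$called, ], gold, pr)
autoplot(threshold_sweep(pr, gold))
```
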