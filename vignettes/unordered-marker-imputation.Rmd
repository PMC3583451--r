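---
title: "Imputing unordered markers and measuring the impact on genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing unordered markers and measuring the impact on genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genotyping-by-sequencing (GBS) produces thousands of *de novo* biallelic
markers, but in species without a reference genome those markers are
unordered, and low sequencing depth leaves a large share of calls missing
— often 50% or more at individual markers. Haplotype-based imputation
(Beagle, IMPUTE and kin) requires marker order and cannot be used. This
package implements, tests and characterises the family of map-independent
imputation algorithms that work directly on the `m x n` genotype matrix
`M` (individuals by markers, codes treated as continuous dosages), and
measures what the choice of algorithm does to downstream genomic selection
(GS) accuracy.

## The five imputation algorithms

* **MNI** (marker mean): every missing call at marker `j` becomes the mean
  of the observed calls at `j`. The baseline; its per-marker imputation
  R-squared is ~0 by construction.
* **kNNI** (k-nearest neighbours): markers are points in individual-space;
  after an MNI pre-fill, each missing call is the `1/d^2`-weighted average
  of the `k` nearest markers' observed calls in that row, with every
  marker also entered in sign-flipped form so strong negative LD counts as
  proximity. Zero-distance neighbours take the limit of the weighting
  scheme: an unweighted average of the zero-distance candidates. Distances
  are computed once on the pre-filled matrix; ties at the k-th distance
  break by marker index so the method is deterministic.
* **SVDI** (iterative singular value decomposition): regress each marker's
  observed calls on the top-`k` left singular vectors of the current
  completed matrix, replace missing calls by the regression predictions,
  and iterate until the relative change in the residual sum of squares
  over observed cells falls below 0.02 (at most 10 iterations). Rank
  deficiency in the regression is resolved by the minimum-norm solution.
* **EMI** (expectation-maximisation): the vector of individuals is modelled
  as multivariate normal with markers as repeated observations. The E-step
  fills each column's missing entries with their conditional expectation
  (Schur complement) given the observed entries; the M-step re-estimates
  the mean vector and individual-by-individual covariance from the
  expected sufficient statistics, *including* the conditional covariance
  of the imputed entries. Without that correction term the covariance
  collapses onto the regression surface and the fills degrade steadily
  with every iteration, eventually scoring worse than the marker mean;
  with the correction the accuracy is stable. Convergence is declared when the largest absolute
  change in the concatenation of the mean vector and the covariance Gram
  matrix `S S'` is at most 0.02 — the Gram form is our resolution of a
  convergence statistic whose printed definition is dimensionally
  inconsistent in the method's original description.
* **RFI** (iterative random-forest regression): markers sorted from least
  to most missing; for each marker with holes, 100 regression trees are
  grown on bootstrap samples of the originally observed rows with all
  other markers as predictors (bagging without feature subsampling,
  minimum node size 5), the ensemble mean fills the holes, and the matrix
  updates in place. Full sweeps repeat until the relative change
  `sum((M1 - M0)^2) / sum(M1^2)` increases for the first time (the
  previous matrix is returned) or 10 sweeps elapse. The tree ensembles are
  grown by `ranger`; everything around them is this package's code.

`k` for kNNI and SVDI is chosen by cross-validation (`select_k_cv()`):
each fold hides 5% of the observed cells, every candidate `k` imputes
them, and the mean squared error against the hidden truth is averaged over
folds; ties go to the smallest `k`. The 5% holdout and the MSE criterion
are this package's choices.

## Accuracy statistics

For the cells hidden by simulation, per marker (`Rm2`) and per individual
(`Ri2`):

    R2 = 1 - sum((true - imputed)^2) / sum((true - mean(true))^2)

with `mean(true)` taken over the same hidden-cell subset — so the mean
predictor scores 0 and values can be negative. Markers whose hidden truth
is constant have an undefined denominator; they are excluded from medians
and counted in a diagnostics field. Replicate averages (`Rm2-bar`),
medians over markers, and across-level averages (`Rm2-double-bar`) build
the summary tables.

Because continuous dosage fills cannot be scored as percent-correct
directly, `equivalent_percent_correct()` translates an (MAF, R2) pair by
simulation: biallelic truth at the MAF, imputed values from the
mean-reverting model `imputed = mu + r2 * (truth - mu) + noise` with noise
variance `r2 * (1 - r2) * var(truth)`, rounded to the nearest legal code.
This construction has expected imputation R-squared `r2`, collapses to the
marker mean at `r2 = 0` (percent correct `100 * (1 - MAF)` — the analytic
anchor that any reasonable construction must satisfy) and to the truth at
`r2 = 1`. A truth-plus-noise model without mean reversion would violate
the anchor, which is why we do not use it.

## Factors affecting accuracy

* **LD**: pairwise `r2 = D^2 / (p1 q1 p2 q2)`, `D = x11 - p1 p2`, with the
  (1,1)-haplotype frequency `x11` estimated by maximum likelihood over
  pairwise-complete individuals. For inbred two-state data haplotypes are
  observed and the estimate reduces to counting; heterozygous calls make
  phase ambiguous only in double heterozygotes, which an EM iteration
  resolves. Markers whose strongest `r2` is below 0.5 are "low LD";
  `ld_ratio()` compares class medians of accuracy.
* **MAF, nonmissing counts**: accuracies are binned by MAF rounded to the
  nearest tenth and by nonmissing counts rounded to the nearest multiple
  of 5 (`bin_accuracy_by()`), medians per bin.
* **Relatedness**: Euclidean distance to the closest relative, and overall
  prediction error variance (PEV). PEV treats each marker column as the
  response of the mixed model `y = 1 mu + g + e`, `cov(g) = sigma2_g *
  K(-j)` with `K(-j)` the genomic relationship matrix excluding that
  marker, takes the diagonal of the genetic block of the inverted
  mixed-model coefficient matrix, and sums over markers. Variance
  components come from spectral REML per marker; above 500 markers a
  shared-spectrum mode profiles the variance ratio per marker on the
  all-marker spectrum once and reuses the median ratio (cost: one
  eigendecomposition instead of `n`). Markers whose REML ratio hits the
  search boundary carry no usable signal and are skipped, with the sum
  rescaled to the full marker count.
* **Population structure**: Weir-Cockerham per-marker Fst screens out the
  most subdivided markers when accuracy should not be credited to
  structure. The estimator choice is ours.

## Genomic selection

`fit_rrblup()` fits `y = 1 mu + X u + e` with i.i.d. normal marker
effects; the variance ratio comes from spectral REML (one-dimensional
optimisation on the eigenvalues of the marker cross-product), and effects
from the equivalent-kernel ridge solution, verified against dense ridge
algebra in the tests. `fit_bayesian_lasso()` is a Park-Casella Gibbs
sampler (scale-mixture double-exponential priors, Gamma(0.1, 0.1) rate
hyperprior on `lambda^2`, scaled-inverse-chi-squared with `nu0 = 3`,
`S0 = var(y)/2` on the residual variance — conventional defaults, all
exposed). `cross_validate()` assigns individuals to 10 folds at random
(no stratification), trains on the remainder, and reports the Pearson
correlation between predicted and supplied breeding values per fold and
its mean.

## The synthetic study population

No public dataset ships with the package, so `simulate_population()`
generates panels with the two properties map-independent imputation
feeds on — high marker-marker LD and related individuals:

* markers sit on a finite set of sequencing-tag loci per chromosome
  (default 30 per chromosome, 5 chromosomes, 500 markers), so several
  markers can share a locus exactly as multiple SNPs on one GBS
  restriction-site tag do; such co-located markers are near-perfect
  mutual predictors, which is the raw material for kNNI and RFI;
* founder haplotypes follow a latent Ornstein-Uhlenbeck Gaussian copula
  along each chromosome (correlation `founder_ld = 0.9` at one mean
  inter-locus gap, 1 at distance zero), thresholded at per-marker Beta(0.8,
  0.8) allele frequencies floored at MAF 0.05 — block LD that decays with
  distance while marginals keep the Beta spectrum;
* 40 biparental families of 5 lines from 80 inbred founders (200 lines),
  each advanced by 8 generations of single-seed descent with
  Poisson(1) crossovers per chromosome per meiosis — residual
  heterozygosity `0.5^8 < 0.4%`, strong within-family relatedness, and a
  panel whose global rank is high enough that local neighbours (kNNI) beat
  global factors (SVDI), as in real breeding panels.

With these defaults the panel shows ~60-80% of markers in at least
moderate LD (`r2 >= 0.5`), in the range of published elite wheat and
barley panels. Phenotypes are additive: standard-normal effects at 50
random QTL markers, Gaussian noise scaled to heritability `h2 = 0.5`.

What the generator does *not* emulate: genotyping error, non-random
(coverage-driven) missingness, multi-allelic markers, dominance and
epistasis, and selection-induced pedigree structure. Passing the study
tests therefore shows the algorithms behave as published under the stated
population model, not that accuracies on any particular real panel will
match numerically.

### Simulated missingness

`mask_missing()` draws a target fraction per marker and hides
`round(fraction * n_observed)` observed cells uniformly without
replacement, never touching pre-existing missing cells and always leaving
at least one observed call. The built-in per-level fraction distributions
are Beta distributions rescaled to the caps 0.20 / 0.50 / 0.70 with
shapes (1.9, 1.24), (2.33, 1.0), (3.0, 0.5): right-skewed with the mode
near the cap and a long left tail, calibrated so the mean total missing
fraction lands at ~12%, ~35% and ~60% of cells — the regimes GBS filtering
at those caps produces in practice. An empirical list of fractions can be
supplied instead.

## The study pipeline and problem sizes

`run_experiment()` crosses levels x replicates x methods x GS models from
one seeded configuration; every cell's seed derives deterministically from
the base seed, so reruns are bit-identical and any cell can be recomputed
alone. Cell failures are recorded, not fatal. The default study design
used by the acceptance checks and `scripts/acceptance.R` is the 200 x 500
panel with 2 missing-data replicates per level — large enough that the
method ordering and level trends are stable, small enough to run on one
CPU in well under half an hour. Within the pipeline RFI is capped at 2
sweeps: on panels of this design the change statistic drops by an order
of magnitude between the first and second sweep and then flattens, the
median per-marker accuracy after two sweeps is within a hundredth of the
fully converged value, and later sweeps only add runtime; calling
`impute_rfi()` directly uses
the full 10-sweep cap with the first-increase stopping rule. Because the
method effect on GS accuracy at high missingness is small relative to
mask-to-mask variation, the genomic-selection comparison between mean and
random-forest imputation at NA70 uses 10 missing-data replicates with the
fold partitions shared between methods (a paired design) and the accuracy
averaged over repeated cross-validation partitions.

## Numerical choices and degenerate inputs

* All-missing markers are an error everywhere; `mask_missing()` cannot
  create them.
* EMI stabilises singular observed-block covariances with a relative ridge
  (`1e-8`, escalating to `1e-4` only if the solve still fails).
* SVDI regressions use only rows originally observed for that marker, in
  every iteration; rank deficiency falls back to the minimum-norm
  solution.
* kNNI with fewer than `k` usable candidates uses all available ones; with
  none, the marker-mean pre-fill stands and the event is counted in the
  result's notes.
* `Rm2` of a constant hidden-truth vector is undefined (`NA`), excluded
  from aggregates, counted in `n_undefined`.
* The LD `r2` is clamped to `[0, 1]`; pairs monomorphic in the
  pairwise-complete subset are undefined.
* Mean imputation pins its own `Rm2` near zero at every missingness level,
  so the strictly-decreasing-accuracy property across levels is asserted
  for the four informative methods; MNI is checked to stay at ~0.

## Known limitations

* RFI is by far the most expensive method (hundreds of forests per
  sweep); its accuracy advantage must be weighed against ~100x the
  runtime of kNNI, and tree growth makes it the only stochastic imputer.
* The Bayesian LASSO uses single-site Gibbs updates; at tens of thousands
  of iterations on large panels it is slow in pure R, and the study
  defaults (2000 iterations, 500 burn-in) are chosen for ranking, not for
  publication-grade posterior summaries.
* Exact-mode PEV fits one REML per marker and scales cubically in
  individuals; the shared-spectrum mode is an approximation whose ranks,
  not values, should be interpreted.
* Accuracy statements transfer to real data only insofar as the panel
  resembles the generator's assumptions (see above).
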