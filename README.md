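# gbsimpute

Map-independent imputation of missing genotype calls at **unordered**
genome-wide markers, and measurement of what the imputation method does to
genomic selection accuracy.

Genotyping-by-sequencing (GBS) and array platforms like DArT deliver
thousands of biallelic markers for species without a reference genome.
Those markers come with no known order and — at low sequencing depth —
with large fractions of missing calls (50% and more per marker).
Haplotype-based imputation tools need marker order and cannot help.
This package is for breeders and quantitative geneticists who need to
complete such matrices before genomic selection (GS), and who want to
know which completion method to trust and when.

## What it implements

For an `m x n` genotype matrix `M` (individuals x markers, codes −1/1,
0/1 or −1/0/1 treated as continuous dosages):

* **Five imputation algorithms** — marker-mean (MNI), k-nearest-neighbour
  markers with `1/d²` weights and sign-flipped duplicates (kNNI),
  iterative truncated-SVD regression with an `|RSS₀−RSS₁|/RSS₁ < 0.02`
  stopping rule (SVDI), EM under a multivariate-normal model of
  individuals (EMI), and iterative random-forest regression with the
  `ΔN = Σ(M₁−M₀)²/ΣM₁²` first-increase stopping rule (RFI, trees via
  `ranger`). Cross-validated choice of `k` for kNNI/SVDI.
* **Accuracy statistics** — per-marker `Rm² = 1 − SSE/SST` and
  per-individual `Ri²` over the simulated-missing cells, replicate and
  across-level aggregates, and a simulation-based translation of `(MAF,
  R²)` into an equivalent percent-correct.
* **Factor analyses** — EM-estimated LD `r² = D²/(p₁q₁p₂q₂)` for all
  marker pairs and the low-vs-moderate-LD accuracy ratio; accuracy binned
  by MAF, nonmissing count, closest-relative Euclidean distance, and
  prediction error variance (PEV) from the mixed-model equations;
  Weir–Cockerham Fst screening.
* **Genomic selection** — RR-BLUP with spectral REML and a Park–Casella
  Bayesian LASSO Gibbs sampler, scored by 10-fold cross-validated Pearson
  accuracy.
* **A synthetic study population** — inbred-line panels with block LD
  (sequencing-tag loci, Ornstein–Uhlenbeck founder haplotypes), biparental
  families under single-seed descent, additive phenotypes at a chosen
  heritability, and per-marker missingness distributions capped at
  20/50/70% with a long left tail — so the entire study design runs from
  one seed with no downloads.
* **A pipeline** — `run_experiment()` crosses levels × replicates ×
  methods × GS models from one config, with per-cell seed derivation,
  failure isolation and TSV report output.

## Worked example

```r
library(gbsimpute)

pop <- simulate_population(n_founders = 24, n_families = 12,
                           lines_per_family = 6, n_markers = 150,
                           n_chromosomes = 3, seed = 42)
pop <- simulate_phenotypes(pop, n_qtl = 30, h2 = 0.5, seed = 42)

md <- mask_missing(pop$genotypes, default_missingness_distribution("NA50"),
                   seed = 1)
md
#> masked_dataset: 72 x 150, cap 0.50, 34.80% of cells hidden by simulation

res <- impute_knni(md$observed, k = 2)
per_marker_accuracy(md, res, level = "NA50", replicate_id = 1)
#> accuracy_report: kNNI NA50 replicate 1
#>   median Rm2 = 0.387 over 143 marker(s)

cross_validate(res$completed, pop$phenotypes, model = "RR", seed = 7)
#> cv_result (RR, 10 folds): mean accuracy 0.407 (sd 0.403)
```

Reading: with up to 50% of the calls at a marker hidden, the
nearest-neighbour fill recovers a median 39% of the hidden variance per
marker (`Rm²`; the marker-mean fill would score ~0), and genomic
prediction on the completed matrix reaches a mean 10-fold accuracy of
0.41 on a trait with heritability 0.5. On the full-size default panel
(200 × 500) the methods separate clearly: RFI ≥ kNNI > EMI/SVDI ≫ MNI,
and the gap between RFI and MNI in GS accuracy opens as missingness grows.

A full factorial study is one call:

```r
cfg <- experiment_config(levels = c("NA20", "NA50", "NA70"),
                         n_replicates = 2, gs_models = "RR", base_seed = 1)
res <- run_experiment(cfg)     # ~20 min on one CPU; RFI dominates
res$accuracy_table             # median Rm2-bar and percent correct per cell
res$gs_table                   # mean CV accuracy ± SE per cell
```

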