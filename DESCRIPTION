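Package: gbsimpute
Title: Map-Independent Imputation of Unordered Markers and Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Imputation of missing genotype calls at unordered, genome-wide
    biallelic markers, as produced by genotyping-by-sequencing in species
    without a reference genome. Implements five map-independent imputation
    algorithms (marker-mean, k-nearest-neighbour, iterative singular value
    decomposition, expectation-maximisation under a multivariate normal
    model, and iterative random forest regression), per-marker and
    per-individual imputation accuracy statistics, EM-based linkage
    disequilibrium r2, factor analyses of imputation accuracy (minor allele
    frequency, nonmissing counts, LD class, closest-relative distance,
    prediction error variance, Fst screening), and cross-validated genomic
    selection with ridge-regression BLUP and the Bayesian LASSO. A synthetic
    inbred-line population simulator with block linkage disequilibrium,
    family relatedness, additive phenotypes and realistic per-marker
    missingness makes the full study design reproducible without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
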