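test_that("simulated panels are complete, polymorphic, seeded and near-inbred", {
  pop <- simulate_population(n_founders = 12, n_families = 6,
                             lines_per_family = 8, n_markers = 120,
                             n_chromosomes = 3, seed = 21)
  G <- pop$genotypes$values
  expect_false(anyNA(G))
  expect_identical(dim(G), c(48L, 120L))
  expect_true(all(apply(G, 2, function(x) length(unique(x)) > 1)))
  # >= 8 selfing generations: heterozygosity below 1% of cells
  expect_lt(mean(G == 0), 0.01)
  pop2 <- simulate_population(n_founders = 12, n_families = 6,
                              lines_per_family = 8, n_markers = 120,
                              n_chromosomes = 3, seed = 21)
  expect_identical(G, pop2$genotypes$values)
  expect_false(identical(G, simulate_population(n_founders = 12,
    n_families = 6, lines_per_family = 8, n_markers = 120,
    n_chromosomes = 3, seed = 22)$genotypes$values))
})

test_that("zero recombination on one chromosome forces complete within-family LD", {
  pop <- simulate_population(n_founders = 6, n_families = 2,
                             lines_per_family = 12, n_markers = 30,
                             n_chromosomes = 1, recomb_rate = 0,
                             founder_ld = 0, seed = 4)
  fam <- pop$pedigree$family == 1
  G <- pop$genotypes$values[fam, ]
  poly <- apply(G, 2, function(x) length(unique(x)) > 1)
  r2 <- suppressWarnings(stats::cor(G[, poly])^2)
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("relatedness is higher within families than across", {
  pop <- simulate_population(n_founders = 20, n_families = 8,
                             lines_per_family = 6, n_markers = 200, seed = 8)
  K <- grm(pop$genotypes)
  fam <- pop$pedigree$family
  same <- outer(fam, fam, "==") & upper.tri(K)
  diff <- !outer(fam, fam, "==") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
})

test_that("LD between markers decays as the recombination rate grows", {
  mean_adjacent_r2 <- function(rate) {
    pop <- simulate_population(n_founders = 8, n_families = 4,
                               lines_per_family = 10, n_markers = 60,
                               n_chromosomes = 1, recomb_rate = rate,
                               founder_ld = 0, n_loci_per_chromosome = 60,
                               seed = 31)
    G <- pop$genotypes$values
    r2 <- suppressWarnings(stats::cor(G)^2)
    mean(r2[upper.tri(r2)], na.rm = TRUE)
  }
  rates <- c(0, 1, 3, 10, 30)
  lds <- vapply(rates, mean_adjacent_r2, numeric(1))
  expect_lt(stats::cor(rates, lds, method = "spearman"), 0)
  expect_gt(lds[1], lds[5])
})

test_that("phenotypes hit the requested heritability and regress on true BVs", {
  pop <- simulate_population(n_founders = 20, n_families = 10,
                             lines_per_family = 10, n_markers = 300, seed = 3)
  expect_error(simulate_phenotypes(pop, n_qtl = 0), "n_qtl")
  expect_error(simulate_phenotypes(pop, n_qtl = 10, h2 = 1.2), "h2")
  hi <- simulate_phenotypes(pop, n_qtl = 40, h2 = 0.999, seed = 5)
  expect_gt(stats::cor(hi$phenotypes, hi$true_breeding_values), 0.99)
  # empirical h2 at 0.5: squared correlation between phenotype and BV
  r2s <- vapply(1:6, function(s) {
    p <- simulate_phenotypes(pop, n_qtl = 40, h2 = 0.5, seed = s)
    stats::cor(p$phenotypes, p$true_breeding_values)^2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.5), 0.08)
  # regression of phenotype on BV is ~1 (noise is independent additive)
  p <- simulate_phenotypes(pop, n_qtl = 40, h2 = 0.5, seed = 7)
  b <- unname(stats::coef(stats::lm(p$phenotypes ~ p$true_breeding_values))[2])
  expect_lt(abs(b - 1), 0.15)
})

test_that("masking hides the requested number of observed cells and nothing else", {
  gm <- gm_from(matrix(sample(c(-1, 1), 100, replace = TRUE), 10, 10))
  spec <- missingness_spec(cap = 0.5, fractions = 0.5)
  md <- mask_missing(gm, spec, seed = 2)
  expect_true(all(colSums(md$simulated_mask) == 5))  # round(0.5 * 10)
  expect_identical(md$observed$values[!md$simulated_mask],
                   gm$values[!md$simulated_mask])
  expect_true(all(is.na(md$observed$values[md$simulated_mask])))
  # reconstruction: observed + mask + truth restores the truth exactly
  rec <- md$observed$values
  rec[md$simulated_mask] <- md$truth$values[md$simulated_mask]
  expect_identical(rec, gm$values)
  # determinism
  md2 <- mask_missing(gm, spec, seed = 2)
  expect_identical(md$simulated_mask, md2$simulated_mask)
})

test_that("masking never hides a pre-existing missing cell", {
  gm <- holey_gm(12, 8, 0.2, seed = 9)
  pre <- is.na(gm$values)
  md <- mask_missing(gm, missingness_spec(cap = 0.7, fractions = 0.6), seed = 3)
  expect_false(any(md$simulated_mask & pre))
  # zero fractions leave everything observed
  md0 <- mask_missing(gm, missingness_spec(cap = 0.2, fractions = 0), seed = 1)
  expect_false(any(md0$simulated_mask))
  expect_identical(md0$observed$values, gm$values)
})

test_that("empirical missingness fractions resample to their mean", {
  gm <- gm_from(matrix(sample(c(-1, 1), 4000, replace = TRUE), 20, 200))
  spec <- missingness_spec(cap = 0.2, fractions = c(0.1, 0.2))
  md <- mask_missing(gm, spec, seed = 6)
  expect_lt(abs(mean(md$simulated_mask) - 0.15), 0.02)
  expect_error(missingness_spec(cap = 0.2, fractions = c(0.1, 0.3)),
               "exceed the cap")
})

test_that("built-in missingness distributions match their regimes", {
  for (lv in c("NA20", "NA50", "NA70")) {
    spec <- default_missingness_distribution(lv)
    set.seed(1)
    x <- gbsimpute:::draw_fractions(spec, 1e5)
    expect_true(all(x <= spec$cap & x >= 0))
  }
  # NA70: histogram mode near the cap (long left tail, mass near threshold)
  set.seed(2)
  x70 <- gbsimpute:::draw_fractions(default_missingness_distribution("NA70"), 1e5)
  h <- hist(x70, breaks = seq(0, 0.7, by = 0.05), plot = FALSE)
  expect_gte(h$mids[which.max(h$counts)], 0.55)
  # NA20: mean per-marker fraction ~0.12, the regime its cap targets
  set.seed(3)
  x20 <- gbsimpute:::draw_fractions(default_missingness_distribution("NA20"), 1e5)
  expect_lt(abs(mean(x20) - 0.12), 0.03)
})
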