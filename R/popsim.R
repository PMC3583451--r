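#' Simulate an inbred-line panel with block LD and family relatedness
#'
#' Emulates the population structure that map-independent imputation relies
#' on: panels of related inbred lines with block linkage disequilibrium.
#' Markers sit on a finite set of sequencing-tag loci per chromosome
#' (several markers can share a locus, as single-nucleotide polymorphisms on
#' one restriction-site tag do, giving near-duplicate marker pairs).
#' Founder lines are fully inbred; their haplotypes follow a latent
#' Ornstein-Uhlenbeck Gaussian copula along each chromosome, thresholded at
#' per-marker allele frequencies drawn from a Beta-shaped spectrum, so
#' founder alleles at nearby loci are correlated (block LD that decays with
#' distance) while every marker keeps its Beta-spectrum frequency. Each
#' family is a biparental cross between two founders advanced by
#' single-seed descent for `selfing_generations` generations, with
#' recombination simulated as a Poisson number of crossovers per chromosome
#' per meiosis. The chromosome assignment and hidden order are used only
#' for recombination and founder LD — the output markers are unordered, as
#' in genotyping-by-sequencing without a reference genome.
#'
#' Markers that come out monomorphic across the panel have their founder
#' alleles redrawn (descent fixed) until polymorphic.
#'
#' @param n_founders number of founder inbred lines.
#' @param n_families number of biparental families.
#' @param lines_per_family inbred lines derived per family.
#' @param n_markers number of biallelic markers.
#' @param n_chromosomes number of chromosomes.
#' @param recomb_rate expected crossovers per chromosome per meiosis.
#' @param selfing_generations generations of self-pollination after the F1.
#' @param maf_floor minimum founder minor-allele frequency, in `[0, 0.5)`.
#' @param n_loci_per_chromosome sequencing-tag loci per chromosome; markers
#'   are placed on these loci, so on average
#'   `n_markers / (n_chromosomes * n_loci_per_chromosome)` markers share a
#'   locus.
#' @param founder_ld latent copula correlation between founder alleles at
#'   loci one mean inter-locus distance apart, in `[0, 1)`; 0 gives
#'   independent founder loci (LD then arises from family structure only).
#'   Markers on the same locus share the latent value (correlation 1).
#' @param seed integer seed; output is bit-identical for identical arguments.
#' @return object of class `sim_population`: list with `genotypes`
#'   (a complete `geno_matrix`, coding `MINUS1_0_1` — residual heterozygotes
#'   are coded 0), `pedigree` (data.frame: individual, family, founder pair),
#'   `sim_params`; phenotype fields are filled by [simulate_phenotypes()].
#' @seealso [simulate_phenotypes()], [mask_missing()]
#' @export
simulate_population <- function(n_founders = 80, n_families = 40,
                                lines_per_family = 5, n_markers = 500,
                                n_chromosomes = 5, recomb_rate = 1,
                                selfing_generations = 8, maf_floor = 0.05,
                                n_loci_per_chromosome = 30,
                                founder_ld = 0.9, seed = 1) {
  stopifnot(n_founders >= 2, n_families >= 1, lines_per_family >= 1,
            n_markers >= 1, n_chromosomes >= 1, recomb_rate >= 0,
            selfing_generations >= 1)
  if (maf_floor < 0 || maf_floor >= 0.5) stop("maf_floor must be in [0, 0.5)")
  if (founder_ld < 0 || founder_ld >= 1) stop("founder_ld must be in [0, 1)")
  stopifnot(n_loci_per_chromosome >= 1)
  with_seed(seed, {
    m <- n_families * lines_per_family
    chrom <- sample.int(n_chromosomes, n_markers, replace = TRUE)

    draw_allele_freqs <- function(k) {
      p <- numeric(k)
      for (i in seq_len(k)) {
        repeat {
          pp <- stats::rbeta(1, 0.8, 0.8)
          if (min(pp, 1 - pp) >= maf_floor) { p[i] <- pp; break }
        }
      }
      p
    }
    # Founder haplotypes: markers sit on tag loci; a latent
    # Ornstein-Uhlenbeck Gaussian process over the loci of each chromosome
    # (corr = founder_ld at one mean inter-locus gap, 1 at distance 0) is
    # thresholded at the per-marker frequency, so marginals stay
    # Beta-spectrum Bernoulli while nearby loci correlate.
    freqs <- draw_allele_freqs(n_markers)
    pos <- numeric(n_markers)
    founder_alleles <- matrix(0, n_founders, n_markers)
    mean_gap <- 1 / n_loci_per_chromosome
    for (cc in seq_len(n_chromosomes)) {
      on_cc <- which(chrom == cc)
      if (length(on_cc) == 0) next
      locus_pos <- sort(stats::runif(n_loci_per_chromosome))
      locus_of <- sample.int(n_loci_per_chromosome, length(on_cc),
                             replace = TRUE)
      pos[on_cc] <- locus_pos[locus_of]
      Zl <- matrix(stats::rnorm(n_founders * n_loci_per_chromosome),
                   n_founders)
      if (founder_ld > 0 && n_loci_per_chromosome > 1) {
        for (t in 2:n_loci_per_chromosome) {
          a <- founder_ld^((locus_pos[t] - locus_pos[t - 1]) / mean_gap)
          Zl[, t] <- a * Zl[, t - 1] + sqrt(1 - a^2) * Zl[, t]
        }
      }
      Zm <- Zl[, locus_of, drop = FALSE]
      founder_alleles[, on_cc] <-
        2 * (t(t(stats::pnorm(Zm)) < freqs[on_cc]) * 1) - 1
    }

    # One meiosis: recombine two origin haplotypes (logical: TRUE = parent B)
    meiosis <- function(h1, h2) {
      out <- h1
      for (cc in seq_len(n_chromosomes)) {
        on_cc <- which(chrom == cc)
        if (length(on_cc) == 0) next
        nx <- stats::rpois(1, recomb_rate)
        start_h2 <- stats::runif(1) < 0.5
        if (nx == 0) {
          if (start_h2) out[on_cc] <- h2[on_cc]
          next
        }
        breaks <- sort(stats::runif(nx))
        # segment index of each marker along the hidden order
        seg <- findInterval(pos[on_cc], breaks)
        use_h2 <- xor(start_h2, seg %% 2 == 1)
        out[on_cc] <- ifelse(use_h2, h2[on_cc], h1[on_cc])
      }
      out
    }

    fam_parents <- t(replicate(n_families, sample.int(n_founders, 2)))
    hapA <- vector("list", m); hapB <- vector("list", m)
    ped_family <- integer(m); ped_p1 <- integer(m); ped_p2 <- integer(m)
    idx <- 0
    for (f in seq_len(n_families)) {
      for (l in seq_len(lines_per_family)) {
        idx <- idx + 1
        # F1: one haplotype from each founder; origins FALSE = parent 1
        h1 <- rep(FALSE, n_markers); h2 <- rep(TRUE, n_markers)
        for (g in seq_len(selfing_generations)) {
          g1 <- meiosis(h1, h2); g2 <- meiosis(h1, h2)
          h1 <- g1; h2 <- g2
        }
        hapA[[idx]] <- h1; hapB[[idx]] <- h2
        ped_family[idx] <- f
        ped_p1[idx] <- fam_parents[f, 1]; ped_p2[idx] <- fam_parents[f, 2]
      }
    }

    build_geno <- function(alleles) {
      G <- matrix(0, m, n_markers)
      for (i in seq_len(m)) {
        a1 <- ifelse(hapA[[i]], alleles[ped_p2[i], ], alleles[ped_p1[i], ])
        a2 <- ifelse(hapB[[i]], alleles[ped_p2[i], ], alleles[ped_p1[i], ])
        G[i, ] <- (a1 + a2) / 2
      }
      G
    }
    G <- build_geno(founder_alleles)
    for (rep_try in 1:100) {
      mono <- which(apply(G, 2, function(x) length(unique(x)) == 1))
      if (length(mono) == 0) break
      # redraw founder alleles of monomorphic markers (iid; descent fixed)
      pm <- draw_allele_freqs(length(mono))
      founder_alleles[, mono] <-
        2 * stats::rbinom(n_founders * length(mono), 1,
                          rep(pm, each = n_founders)) - 1
      G[, mono] <- build_geno(founder_alleles)[, mono]
    }

    ids <- sprintf("F%02d_L%03d", ped_family, seq_len(m))
    gm <- geno_matrix(`dimnames<-`(G, list(ids, sprintf("M%04d", seq_len(n_markers)))),
                      coding = "MINUS1_0_1")
    structure(list(
      genotypes = gm,
      true_breeding_values = NULL,
      phenotypes = NULL,
      qtl_indices = NULL,
      pedigree = data.frame(individual = ids, family = ped_family,
                            founder1 = ped_p1, founder2 = ped_p2,
                            stringsAsFactors = FALSE),
      sim_params = list(n_founders = n_founders, n_families = n_families,
                        lines_per_family = lines_per_family,
                        n_markers = n_markers, n_chromosomes = n_chromosomes,
                        recomb_rate = recomb_rate,
                        selfing_generations = selfing_generations,
                        maf_floor = maf_floor,
                        n_loci_per_chromosome = n_loci_per_chromosome,
                        founder_ld = founder_ld, seed = seed)),
      class = "sim_population")
  })
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d lines in %d families, %d markers%s\n",
              n_individuals(x$genotypes), x$sim_params$n_families,
              n_markers(x$genotypes),
              if (is.null(x$phenotypes)) "" else
                sprintf(", phenotypes at h2=%s", format(x$sim_params$h2))))
  invisible(x)
}

#' Add additive polygenic phenotypes to a simulated population
#'
#' Samples `n_qtl` markers as QTL with standard-normal additive effects;
#' true breeding values are the genotype-effect products and phenotypes add
#' Gaussian noise scaled so that `var(noise) = var(BV) * (1 - h2) / h2`,
#' i.e. the expected narrow-sense heritability of the phenotype equals `h2`.
#'
#' @param pop a `sim_population` from [simulate_population()].
#' @param n_qtl number of QTL markers (must be >= 1 and <= marker count).
#' @param h2 target heritability, strictly inside `(0, 1)`.
#' @param seed integer seed.
#' @return the population with `true_breeding_values`, `phenotypes` (named
#'   numeric vector) and `qtl_indices` filled.
#' @export
simulate_phenotypes <- function(pop, n_qtl = 50, h2 = 0.5, seed = 1) {
  stopifnot(inherits(pop, "sim_population"))
  if (n_qtl < 1) stop("n_qtl must be >= 1")
  if (n_qtl > n_markers(pop$genotypes)) stop("n_qtl exceeds marker count")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  with_seed(seed, {
    G <- pop$genotypes$values
    qtl <- sort(sample.int(ncol(G), n_qtl))
    eff <- stats::rnorm(n_qtl)
    bv <- drop(G[, qtl, drop = FALSE] %*% eff)
    noise_sd <- stats::sd(bv) * sqrt((1 - h2) / h2)
    y <- bv + stats::rnorm(length(bv), 0, noise_sd)
    pop$true_breeding_values <- stats::setNames(bv, rownames(G))
    pop$phenotypes <- stats::setNames(y, rownames(G))
    pop$qtl_indices <- qtl
    pop$sim_params$n_qtl <- n_qtl
    pop$sim_params$h2 <- h2
    pop$sim_params$phenotype_seed <- seed
    pop
  })
}

#' Specify a per-marker missingness distribution
#'
#' Either an empirical list of fractions (resampled with replacement) or a
#' Beta distribution rescaled to `[0, cap]`.
#'
#' @param cap maximum per-marker missing fraction, in `(0, 1]`.
#' @param fractions optional numeric vector of empirical per-marker
#'   fractions; all must be `<= cap`.
#' @param shape1,shape2 Beta shapes for the parametric form (used when
#'   `fractions` is `NULL`).
#' @return object of class `missingness_spec`.
#' @seealso [default_missingness_distribution()], [mask_missing()]
#' @export
missingness_spec <- function(cap, fractions = NULL, shape1 = 2, shape2 = 1) {
  stopifnot(cap > 0, cap <= 1)
  if (!is.null(fractions)) {
    if (any(fractions < 0)) stop("negative missingness fractions")
    if (any(fractions > cap))
      stop("empirical fractions exceed the cap (", cap, ")")
  }
  structure(list(cap = cap, fractions = fractions,
                 shape1 = shape1, shape2 = shape2),
            class = "missingness_spec")
}

#' Built-in per-marker missingness distributions for the NA20/NA50/NA70 regimes
#'
#' Parametric stand-ins for the empirical genotyping-by-sequencing
#' per-marker missingness distributions: right-skewed Beta distributions
#' rescaled to `[0, cap]` with caps 0.20, 0.50 and 0.70, shaped so that the
#' mode sits near the cap with a long left tail, and calibrated so the mean
#' total missing fraction lands in the regime each cap is associated with
#' (about 12%, 35% and 60% of all cells).
#'
#' @param level `"NA20"`, `"NA50"` or `"NA70"`.
#' @return a [missingness_spec()].
#' @export
default_missingness_distribution <- function(level = c("NA20", "NA50", "NA70")) {
  level <- match.arg(level)
  switch(level,
         NA20 = missingness_spec(0.20, shape1 = 1.90, shape2 = 1.24),
         NA50 = missingness_spec(0.50, shape1 = 2.33, shape2 = 1.00),
         NA70 = missingness_spec(0.70, shape1 = 3.00, shape2 = 0.50))
}

draw_fractions <- function(spec, n) {
  if (!is.null(spec$fractions))
    sample(spec$fractions, n, replace = TRUE)
  else
    spec$cap * stats::rbeta(n, spec$shape1, spec$shape2)
}

#' Hide observed genotype calls at random
#'
#' For each marker a target missing fraction is drawn from `spec`, then
#' `round(fraction * n_observed)` currently-observed cells are hidden
#' uniformly at random without replacement. Cells already missing in the
#' truth matrix are never "hidden" again, and at least one observed call is
#' always left per marker.
#'
#' @param truth a `geno_matrix` (each marker needs >= 1 non-missing call).
#' @param spec a [missingness_spec()].
#' @param seed integer seed.
#' @return object of class `masked_dataset`: list with `truth`, `observed`
#'   (same values with simulated-missing cells set `NA`), `simulated_mask`
#'   (logical matrix; `TRUE` = hidden by simulation), `spec`, `seed`.
#' @export
mask_missing <- function(truth, spec, seed = 1) {
  stopifnot(inherits(truth, "geno_matrix"), inherits(spec, "missingness_spec"))
  v <- truth$values
  if (any(colSums(!is.na(v)) == 0))
    stop("truth matrix has all-missing marker(s)")
  with_seed(seed, {
    n <- ncol(v); m <- nrow(v)
    frac <- draw_fractions(spec, n)
    mask <- matrix(FALSE, m, n, dimnames = dimnames(v))
    for (j in seq_len(n)) {
      obs <- which(!is.na(v[, j]))
      n_hide <- min(round(frac[j] * length(obs)), length(obs) - 1)
      if (n_hide > 0)
        mask[obs[sample.int(length(obs), n_hide)], j] <- TRUE
    }
    observed <- truth
    observed$values[mask] <- NA_real_
    structure(list(truth = truth, observed = observed,
                   simulated_mask = mask, spec = spec, seed = seed,
                   target_fractions = frac),
              class = "masked_dataset")
  })
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf(
    "masked_dataset: %d x %d, cap %.2f, %.2f%% of cells hidden by simulation\n",
    nrow(x$truth$values), ncol(x$truth$values), x$spec$cap,
    100 * mean(x$simulated_mask)))
  invisible(x)
}

#' Genomic relationship matrix
#'
#' VanRaden-style construction: marker columns are centred by their mean
#' dosage and the cross-product is rescaled so the mean diagonal equals 1.
#'
#' @param gm a complete `geno_matrix`.
#' @return m x m relationship matrix.
#' @export
grm <- function(gm) {
  v <- gm$values
  if (anyNA(v)) stop("grm requires a complete matrix; impute first")
  Z <- scale(v, center = TRUE, scale = FALSE)
  K <- tcrossprod(Z)
  K / mean(diag(K))
}
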