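# Two-locus LD machinery. Genotypes are converted to allele-1 dosage counts
# in {0, 1, 2} (two-state codings count each inbred individual as two copies
# of the same allele, so haplotypes are directly observed; the heterozygote
# code contributes one copy of each allele and makes phase ambiguous only in
# double heterozygotes, where an EM iteration resolves the cis/trans split).

#' Pairwise LD r-squared matrix via EM haplotype-frequency estimation
#'
#' For every marker pair, allele frequencies are computed from
#' pairwise-complete individuals and the frequency of the (allele 1, allele
#' 1) haplotype `x11` is estimated by maximum likelihood: haplotype counts
#' are observed directly except for double heterozygotes, whose cis/trans
#' ambiguity is resolved by EM. Returns
#' `r2 = D^2 / (p1 q1 p2 q2)` with `D = x11 - p1 p2`, clamped to `[0, 1]`.
#' Pairs where either marker is monomorphic in the pairwise-complete subset
#' are `NA` (undefined).
#'
#' @param gm a `geno_matrix` (missing calls allowed; pairwise-complete
#'   deletion).
#' @param max_em_iter EM iterations for double-heterozygote resolution.
#' @return n x n symmetric matrix of r2 values with `NA` diagonal.
#' @export
ld_r2_matrix <- function(gm, max_em_iter = 100) {
  D <- 2 * allele1_dosage(gm)             # dosage of allele 1 in {0,1,2}
  O <- (!is.na(D)) * 1
  D0 <- D; D0[is.na(D)] <- 0
  H <- (D == 1) & !is.na(D)               # heterozygote indicator
  H0 <- H * 1
  N <- crossprod(O)                       # pairwise-complete counts
  sumA <- crossprod(D0, O)                # sum of dosages at j over complete(j,l)
  sumB <- t(sumA)
  sumAB <- crossprod(D0)                  # sum of a*b over complete pairs
  ndh <- crossprod(H0)                    # double-heterozygote counts
  # phase-known haplotype counts (each individual contributes 2 haplotypes);
  # a double het contributes a*b/2 = 1/2 to each "known" product term, which
  # is removed and re-assigned by EM below.
  C11 <- sumAB / 2 - 0.5 * ndh
  C12 <- (2 * sumA - sumAB) / 2 - 0.5 * ndh
  C21 <- (2 * sumB - sumAB) / 2 - 0.5 * ndh
  C22 <- (4 * N - 2 * sumA - 2 * sumB + sumAB) / 2 - 0.5 * ndh
  twoN <- 2 * N
  p <- matrix(0.5, nrow(N), ncol(N))      # cis probability of a double het
  if (any(ndh > 0)) {
    for (it in seq_len(max_em_iter)) {
      h11 <- (C11 + ndh * p) / twoN
      h12 <- (C12 + ndh * (1 - p)) / twoN
      h21 <- (C21 + ndh * (1 - p)) / twoN
      h22 <- (C22 + ndh * p) / twoN
      cis <- h11 * h22
      tra <- h12 * h21
      pnew <- ifelse(cis + tra > 0, cis / (cis + tra), 0.5)
      delta <- max(abs(pnew - p)[ndh > 0])
      p <- pnew
      if (delta < 1e-12) break
    }
  }
  x11 <- (C11 + ndh * p) / twoN
  p1 <- sumA / twoN
  p2 <- sumB / twoN
  denom <- p1 * (1 - p1) * p2 * (1 - p2)
  Dld <- x11 - p1 * p2
  r2 <- ifelse(denom > 0, Dld^2 / denom, NA_real_)
  r2 <- pmin(pmax(r2, 0), 1)
  r2[N == 0] <- NA_real_
  diag(r2) <- NA_real_
  dimnames(r2) <- list(colnames(gm$values), colnames(gm$values))
  r2
}

#' LD r-squared between two marker vectors
#'
#' Scalar convenience wrapper around [ld_r2_matrix()].
#'
#' @param marker_j,marker_l numeric vectors of genotype codes (`NA` =
#'   missing) in the given coding.
#' @param coding coding of the two vectors.
#' @return r2 in `[0, 1]`, or `NA` if undefined.
#' @export
ld_r2_em <- function(marker_j, marker_l, coding = "MINUS1_0_1") {
  gm <- geno_matrix(cbind(a = marker_j, b = marker_l), coding = coding)
  ld_r2_matrix(gm)[1, 2]
}

#' Classify markers by their strongest pairwise LD
#'
#' A marker whose highest r2 with any other marker is below `threshold` is
#' in low LD with all other markers; otherwise it is in at least moderate LD
#' with at least one other marker.
#'
#' @param gm a `geno_matrix` with `n >= 2` markers.
#' @param threshold r2 threshold (default 0.5).
#' @return object of class `ld_summary`: list with `max_r2_per_marker`,
#'   `class_per_marker` (`"LOW_LD"`/`"MODERATE_LD"`), `threshold`,
#'   `moderate_fraction`.
#' @export
ld_classify <- function(gm, threshold = 0.5) {
  if (n_markers(gm) < 2) stop("need at least 2 markers")
  r2 <- ld_r2_matrix(gm)
  mx <- apply(r2, 2, function(x) if (all(is.na(x))) NA_real_ else
    max(x, na.rm = TRUE))
  cls <- ifelse(!is.na(mx) & mx >= threshold, "MODERATE_LD", "LOW_LD")
  structure(list(max_r2_per_marker = mx, class_per_marker = cls,
                 threshold = threshold,
                 moderate_fraction = mean(cls == "MODERATE_LD")),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("ld_summary: %.1f%% of %d markers in at least moderate LD (r2 >= %g)\n",
              100 * x$moderate_fraction, length(x$class_per_marker),
              x$threshold))
  invisible(x)
}

#' Ratio of median accuracy between LD classes
#'
#' Median replicate-averaged accuracy of markers in low LD with all other
#' markers, divided by that of markers in at least moderate LD with at
#' least one other marker. Values below 1 indicate that markers without a
#' strong LD partner impute worse.
#'
#' @param ldsum an `ld_summary` from [ld_classify()].
#' @param rm2bar accuracy vector aligned with the markers of `ldsum`.
#' @return list with `ratio`, `median_low`, `median_moderate`.
#' @export
ld_ratio <- function(ldsum, rm2bar) {
  stopifnot(inherits(ldsum, "ld_summary"))
  if (length(rm2bar) != length(ldsum$class_per_marker))
    stop("rm2bar length does not match marker count")
  low <- rm2bar[ldsum$class_per_marker == "LOW_LD"]
  mod <- rm2bar[ldsum$class_per_marker == "MODERATE_LD"]
  if (sum(!is.na(low)) == 0 || sum(!is.na(mod)) == 0)
    stop("one of the LD classes is empty")
  ml <- stats::median(low, na.rm = TRUE)
  mm <- stats::median(mod, na.rm = TRUE)
  list(ratio = ml / mm, median_low = ml, median_moderate = mm)
}

#' Bin accuracies by an explanatory factor and take per-bin medians
#'
#' Binning rules follow the conventions of the factor analyses: MAF is
#' rounded to the nearest tenth, nonmissing counts to the nearest multiple
#' of 5, closest-relative distances to the nearest whole number, and PEV
#' (continuous, scale-dependent) falls into `n_bins` quantile bins by
#' default. A custom function mapping values to bin labels can be supplied.
#'
#' @param values numeric vector of factor values (per marker or individual).
#' @param accuracies aligned accuracy vector (`NA`s dropped).
#' @param factor one of `"MAF"`, `"N_NONMISSING"`, `"DISTANCE"`, `"PEV"`,
#'   ignored when `binning` is a function.
#' @param binning optional function `values -> bin labels`.
#' @param n_bins quantile bins for `"PEV"`.
#' @return data.frame with columns `bin`, `n`, `median_accuracy`, sorted by
#'   bin; empty bins are omitted.
#' @export
bin_accuracy_by <- function(values, accuracies,
                            factor = c("MAF", "N_NONMISSING", "DISTANCE", "PEV"),
                            binning = NULL, n_bins = 10) {
  if (length(values) != length(accuracies)) stop("length mismatch")
  if (is.null(binning)) {
    factor <- match.arg(factor)
    binning <- switch(factor,
      MAF = function(v) round(v, 1),
      N_NONMISSING = function(v) 5 * round(v / 5),
      DISTANCE = function(v) round(v),
      PEV = function(v) {
        qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                     na.rm = TRUE))
        mids <- (qs[-1] + qs[-length(qs)]) / 2
        mids[pmin(pmax(findInterval(v, qs, rightmost.closed = TRUE), 1),
                  length(mids))]
      })
  }
  keep <- !is.na(values) & !is.na(accuracies)
  b <- binning(values[keep])
  acc <- accuracies[keep]
  med <- tapply(acc, b, stats::median)
  cnt <- tapply(acc, b, length)
  out <- data.frame(bin = as.numeric(names(med)),
                    n = as.integer(cnt),
                    median_accuracy = as.numeric(med))
  out[order(out$bin), , drop = FALSE]
}

#' Euclidean distance from each individual to its closest relative
#'
#' @param gm a complete `geno_matrix` with `m >= 2` individuals.
#' @return named numeric vector: per individual, the minimum Euclidean
#'   distance between its genotype row and any other individual's row.
#' @export
closest_relative_distance <- function(gm) {
  v <- gm$values
  if (anyNA(v)) stop("matrix has missing calls; impute or use the truth matrix")
  if (nrow(v) < 2) stop("need at least 2 individuals")
  d <- as.matrix(stats::dist(v))
  diag(d) <- Inf
  stats::setNames(apply(d, 1, min), rownames(v))
}

# Restricted-likelihood variance components for y = 1*mu + g + e,
# g ~ N(0, sg2 * K): spectral form, 1-d optimisation over delta = se2/sg2.
reml_kernel <- function(y, K) {
  m <- length(y)
  P <- diag(m) - matrix(1 / m, m, m)
  A <- P %*% K %*% P
  eg <- eigen(A, symmetric = TRUE)
  keep <- seq_len(m - 1)                  # drop the null-space eigenvalue
  xi <- pmax(eg$values[keep], 0)
  eta <- drop(crossprod(eg$vectors[, keep, drop = FALSE], y))
  nloglik <- function(log_delta) {
    delta <- exp(log_delta)
    wt <- xi + delta
    sg2 <- sum(eta^2 / wt) / (m - 1)
    0.5 * ((m - 1) * log(sg2) + sum(log(wt)))
  }
  opt <- stats::optimize(nloglik, c(log(1e-8), log(1e8)))
  delta <- exp(opt$minimum)
  sg2 <- sum(eta^2 / (xi + delta)) / (m - 1)
  list(sigma2_g = sg2, sigma2_e = sg2 * delta, delta = delta)
}

#' Prediction error variance from the mixed-model equations
#'
#' Diagonal of the genetic-effect block of the inverted coefficient matrix
#' for `y = 1*mu + g + e` with `cov(g) = sigma2_g * K` and residual
#' variance `sigma2_e`.
#'
#' @param K m x m genetic covariance structure (e.g. a genomic relationship
#'   matrix).
#' @param sigma2_g,sigma2_e variance components.
#' @param ridge relative ridge added to `K` before inversion.
#' @return numeric vector of per-individual PEVs.
#' @export
pev_mme <- function(K, sigma2_g, sigma2_e, ridge = 1e-8) {
  m <- nrow(K)
  Kr <- K
  diag(Kr) <- diag(Kr) + ridge * mean(diag(Kr))
  Kinv <- solve(Kr)
  C <- matrix(0, m + 1, m + 1)
  C[1, 1] <- m / sigma2_e
  C[1, -1] <- C[-1, 1] <- 1 / sigma2_e
  C[-1, -1] <- diag(m) / sigma2_e + Kinv / sigma2_g
  diag(solve(C))[-1]
}

#' Overall prediction error variance per individual
#'
#' For each marker, the marker's genotype column is treated as the response
#' in the mixed model `y = 1*mu + g + e` with `cov(g) = sigma2_g * K(-j)`,
#' where `K(-j)` is the genomic relationship matrix built from all markers
#' except marker j. The PEV vector of that model is the diagonal of the
#' g-block of the inverted mixed-model coefficient matrix; the sum across
#' markers is the overall PEV per individual. Low PEV indicates high
#' genetic connectedness to the rest of the panel.
#'
#' Variance components come from restricted maximum likelihood per marker
#' against the marker's own leave-one-out relationship matrix
#' (`mode = "exact"`), or from a faster shared-spectrum approximation
#' (`mode = "shared"`, the default above 500 markers): the all-marker
#' relationship matrix is eigendecomposed once, the REML variance ratio is
#' profiled per marker on that shared spectrum, and the median ratio across
#' markers is reused for every marker (per-marker genetic variances are
#' still profiled individually).
#'
#' @param gm a complete `geno_matrix` with `m >= 3` individuals.
#' @param mode `"auto"`, `"exact"` or `"shared"`.
#' @return named numeric vector of summed PEVs (markers whose REML fit
#'   degenerates are skipped and the sum is rescaled to the full marker
#'   count; the number skipped is in attribute `"n_skipped"`).
#' @export
pev_per_individual <- function(gm, mode = c("auto", "exact", "shared")) {
  mode <- match.arg(mode)
  v <- gm$values
  if (anyNA(v)) stop("matrix has missing calls; impute or use the truth matrix")
  m <- nrow(v); n <- ncol(v)
  if (m < 3) stop("need at least 3 individuals")
  if (mode == "auto") mode <- if (n > 500) "shared" else "exact"
  Z <- scale(v, center = TRUE, scale = FALSE)
  G_full <- tcrossprod(Z)                 # unscaled cross-product
  shared <- NULL
  if (mode == "shared") {
    K <- G_full / mean(diag(G_full))
    P <- diag(m) - matrix(1 / m, m, m)
    eg <- eigen(P %*% K %*% P, symmetric = TRUE)
    xi <- pmax(eg$values[seq_len(m - 1)], 0)
    Ey <- crossprod(eg$vectors[, seq_len(m - 1), drop = FALSE], v)
    deltas <- vapply(seq_len(n), function(j) {
      eta2 <- Ey[, j]^2
      opt <- stats::optimize(function(ld) {
        wt <- xi + exp(ld)
        0.5 * ((m - 1) * log(sum(eta2 / wt) / (m - 1)) + sum(log(wt)))
      }, c(log(1e-8), log(1e8)))
      exp(opt$minimum)
    }, numeric(1))
    delta_shared <- stats::median(deltas)
    sg2_per <- vapply(seq_len(n), function(j)
      sum(Ey[, j]^2 / (xi + delta_shared)) / (m - 1), numeric(1))
    shared <- list(delta = delta_shared, sg2 = sg2_per)
  }
  total <- rep(0, m)
  n_used <- 0L
  for (j in seq_len(n)) {
    Gj <- G_full - tcrossprod(Z[, j])
    scale_j <- mean(diag(Gj))
    if (scale_j <= 0) next
    Kj <- Gj / scale_j
    vc <- if (mode == "shared")
      list(sigma2_g = shared$sg2[j], sigma2_e = shared$sg2[j] * shared$delta)
    else
      tryCatch(reml_kernel(v[, j], Kj), error = function(e) NULL)
    if (is.null(vc) || !is.finite(vc$sigma2_g) || vc$sigma2_g <= 1e-10) next
    # variance ratio at the search boundary: no usable genetic signal
    if (mode == "exact" && vc$sigma2_e / vc$sigma2_g >= 1e7) next
    pev <- tryCatch(pev_mme(Kj, vc$sigma2_g, vc$sigma2_e),
                    error = function(e) NULL)
    if (is.null(pev)) next
    total <- total + pev
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no marker yielded a usable REML fit")
  out <- stats::setNames(total * n / n_used, rownames(v))
  attr(out, "n_skipped") <- n - n_used
  out
}

#' Weir-Cockerham Fst per marker
#'
#' Variance-component estimator of population differentiation from group
#' allele frequencies (theta-hat with the finite-sample a, b, c terms,
#' computed from dosage genotype counts; for fully inbred data the
#' heterozygosity terms are ~0).
#'
#' @param gm a `geno_matrix`.
#' @param groups vector of group labels, one per individual; at least 2
#'   groups with at least 2 genotyped individuals each.
#' @return named numeric vector of per-marker Fst (monomorphic markers
#'   `NA`).
#' @export
fst_per_marker <- function(gm, groups) {
  v <- gm$values
  if (length(groups) != nrow(v)) stop("groups length must equal individual count")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  dos <- 2 * allele1_dosage(gm)           # 0/1/2 copies of allele 1
  out <- rep(NA_real_, ncol(v))
  for (j in seq_len(ncol(v))) {
    d <- dos[, j]; g <- groups[!is.na(d)]; d <- d[!is.na(d)]
    tab_n <- tapply(d, g, length)
    keep <- !is.na(tab_n) & tab_n >= 2
    if (sum(keep) < 2) next
    ni <- tab_n[keep]
    pi <- tapply(d, g, mean)[keep] / 2
    hi <- tapply(d == 1, g, mean)[keep]   # observed heterozygosity
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    if (is.finite(denom) && denom != 0) out[j] <- a / denom
  }
  stats::setNames(out, colnames(v))
}
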