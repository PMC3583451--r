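test_that("LD r2 equals count-based r2 on complete inbred data", {
  set.seed(12)
  v <- matrix(sample(c(-1, 1), 200, replace = TRUE), 20, 10)
  gm <- gm_from(v)
  r2 <- ld_r2_matrix(gm)
  ref <- stats::cor(v)^2                  # allele indicators: r = Pearson
  diag(ref) <- NA
  expect_equal(r2, ref, tolerance = 1e-10, ignore_attr = TRUE)
  # symmetry and sign-flip invariance
  expect_equal(r2, t(r2))
  gm_f <- gm; gm_f$values[, 3] <- -gm_f$values[, 3]
  expect_equal(ld_r2_matrix(gm_f), r2, tolerance = 1e-10)
})

test_that("LD r2 handles identical, independent and missing-data cases", {
  x <- c(1, 1, -1, -1, 1, -1)
  expect_equal(ld_r2_em(x, x, coding = "MINUS1_1"), 1)
  # exact independence: x11 = p1 * p2 -> D = 0
  a <- c(1, 1, -1, -1)
  b <- c(1, -1, 1, -1)
  expect_equal(ld_r2_em(a, b, coding = "MINUS1_1"), 0)
  # pairwise-complete deletion
  xm <- c(1, 1, -1, -1, NA, 1)
  ym <- c(1, 1, -1, -1, 1, NA)
  expect_equal(ld_r2_em(xm, ym, coding = "MINUS1_1"), 1)
  # monomorphic in the pairwise-complete subset: undefined
  expect_true(is.na(ld_r2_em(c(1, 1, 1, NA), c(1, -1, 1, -1),
                             coding = "MINUS1_1")))
})

test_that("EM resolves double-heterozygote phase like a likelihood grid search", {
  # diploid two-locus table with two double heterozygotes
  a <- c(-1, -1, 0, 0, 1, 1, 1, 0, -1, 1, 0, 1)
  b <- c(-1, -1, 0, 0, 1, 1, 1, 1, -1, 1, 0, 0)
  r2_em <- ld_r2_em(a, b, coding = "MINUS1_0_1")
  # grid search over x11 of the multinomial haplotype likelihood
  da <- a + 1; db <- b + 1                # dosage of allele "1"
  n <- length(a)
  p1 <- mean(da) / 2; p2 <- mean(db) / 2
  loglik <- function(x11) {
    h <- c(x11, p1 - x11, p2 - x11, 1 - p1 - p2 + x11)
    if (any(h <= 0)) return(-Inf)
    ll <- 0
    for (i in seq_len(n)) {
      ca <- da[i]; cb <- db[i]
      if (ca == 1 && cb == 1)             # double het: cis or trans
        ll <- ll + log(2 * h[1] * h[4] + 2 * h[2] * h[3])
      else {
        # phase known: product over the two haplotypes
        hapA <- c(ifelse(ca >= 1, 1, 0), ifelse(cb >= 1, 1, 0))
        hapB <- c(ifelse(ca == 2, 1, 0), ifelse(cb == 2, 1, 0))
        pick <- function(hap) h[c(4, 3, 2, 1)[hap[1] * 2 + hap[2] + 1]]
        mult <- if (!identical(hapA, hapB)) 2 else 1
        ll <- ll + log(mult * pick(hapA) * pick(hapB))
      }
    }
    ll
  }
  grid <- seq(max(0, p1 + p2 - 1) + 1e-6, min(p1, p2) - 1e-6, length.out = 20001)
  lls <- vapply(grid, loglik, numeric(1))
  x11_hat <- grid[which.max(lls)]
  D <- x11_hat - p1 * p2
  r2_grid <- D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  expect_equal(r2_em, r2_grid, tolerance = 1e-4)
})

test_that("markers classify by their strongest LD partner", {
  set.seed(30)
  base <- sample(c(-1, 1), 40, replace = TRUE)
  v <- cbind(base, base, sample(c(-1, 1), 40, replace = TRUE),
             sample(c(-1, 1), 40, replace = TRUE))
  gm <- gm_from(`colnames<-`(v, paste0("m", 1:4)))
  ls <- ld_classify(gm, threshold = 0.5)
  expect_identical(unname(ls$class_per_marker[1:2]),
                   c("MODERATE_LD", "MODERATE_LD"))
  ls0 <- ld_classify(gm, threshold = 0)
  expect_true(all(ls0$class_per_marker == "MODERATE_LD"))
  # mutually independent markers at large m stay in low LD
  set.seed(31)
  big <- gm_from(matrix(sample(c(-1, 1), 500 * 12, replace = TRUE), 500, 12))
  expect_true(all(ld_classify(big)$class_per_marker == "LOW_LD"))
})

test_that("LD accuracy ratio divides the class medians", {
  cls <- c(rep("LOW_LD", 3), rep("MODERATE_LD", 3))
  ls <- structure(list(class_per_marker = cls), class = "ld_summary")
  same <- ld_ratio(ls, c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4))
  expect_equal(same$ratio, 1)
  # the reduced-ratio arithmetic: 0.13 / 0.8 = 0.1625
  r <- ld_ratio(ls, c(0.13, 0.13, 0.13, 0.8, 0.8, 0.8))
  expect_equal(r$ratio, 0.1625)
  expect_error(ld_ratio(ls, c(NA, NA, NA, 1, 1, 1)), "empty")
})

test_that("factor binning follows the rounding conventions", {
  out <- bin_accuracy_by(c(0.04, 0.06), c(0.5, 0.7), factor = "MAF")
  expect_equal(out$bin, c(0.0, 0.1))
  expect_equal(out$median_accuracy, c(0.5, 0.7))
  out5 <- bin_accuracy_by(c(12, 13, 18), c(1, 2, 3), factor = "N_NONMISSING")
  expect_equal(out5$bin, c(10, 15, 20))
  outd <- bin_accuracy_by(c(1.2, 1.4, 2.6), c(1, 3, 5), factor = "DISTANCE")
  expect_equal(outd$bin, c(1, 3))
  expect_equal(outd$median_accuracy, c(2, 5))
  # monotone construction keeps monotone bin medians
  x <- seq(2, 60, by = 2)
  acc <- x / 60 + 0.01 * sin(x)
  outm <- bin_accuracy_by(x, acc, factor = "N_NONMISSING")
  expect_true(all(diff(outm$median_accuracy) > 0))
  expect_error(bin_accuracy_by(1:3, 1:2), "length mismatch")
})

test_that("closest-relative distances match a brute-force oracle", {
  set.seed(44)
  v <- matrix(sample(c(-1, 1), 40, replace = TRUE), 5, 8)
  v[2, ] <- v[1, ]                        # duplicated individual
  gm <- gm_from(v)
  d <- closest_relative_distance(gm)
  brute <- vapply(1:5, function(i)
    min(vapply(setdiff(1:5, i), function(l)
      sqrt(sum((v[i, ] - v[l, ])^2)), numeric(1))), numeric(1))
  expect_equal(unname(d), brute)
  expect_equal(unname(d[1]), 0)
  expect_equal(unname(closest_relative_distance(
    gm_from(matrix(c(1, -1, 1, 1), 2)))), c(2, 2))
  gm_na <- gm; gm_na$values[1, 1] <- NA
  expect_error(closest_relative_distance(gm_na), "missing")
})

test_that("PEV from the mixed-model equations matches dense inversion", {
  K <- matrix(c(1, 0.5, 0.2, 0.1,
                0.5, 1, 0.3, 0.2,
                0.2, 0.3, 1, 0.4,
                0.1, 0.2, 0.4, 1), 4)
  sg <- 2; se <- 1.5
  pev <- pev_mme(K, sg, se, ridge = 0)
  # oracle: dense MME coefficient matrix [X Z | mu g], X = 1, Z = I
  C <- rbind(cbind(4 / se, t(rep(1, 4)) / se),
             cbind(rep(1, 4) / se, diag(4) / se + solve(K) / sg))
  expect_equal(pev, diag(solve(C))[-1], tolerance = 1e-10)
  # sigma2_g -> 0: PEV approaches the prior variance for everyone equally
  pev0 <- pev_mme(K, 1e-9, 1, ridge = 0)
  expect_lt(max(abs(pev0 - pev0[1])), 1e-6)
})

test_that("overall PEV reflects genetic connectedness", {
  set.seed(50)
  base <- sample(c(-1, 1), 30, replace = TRUE)
  flip <- function(x, k) { i <- sample(30, k); x[i] <- -x[i]; x }
  v <- rbind(base, flip(base, 1), flip(base, 2), flip(base, 1), flip(base, 2),
             sample(c(-1, 1), 30, replace = TRUE))
  rownames(v) <- paste0("i", 1:6)
  gm <- geno_matrix(v, coding = "MINUS1_1")
  pev <- pev_per_individual(gm, mode = "exact")
  # the isolated individual is least connected -> highest PEV
  expect_identical(unname(which.max(pev)), 6L)
  # invariance to marker permutation
  gm_p <- gm; gm_p$values <- gm$values[, sample(30)]
  expect_equal(pev_per_individual(gm_p, mode = "exact"), pev, tolerance = 1e-8)
  # shared mode stays rank-correlated with exact mode
  pev_s <- pev_per_individual(gm, mode = "shared")
  expect_gt(stats::cor(pev, pev_s, method = "spearman"), 0.7)
})

test_that("Weir-Cockerham Fst separates differentiated from homogeneous markers", {
  groups <- rep(c("A", "B"), each = 10)
  v_same <- cbind(rep(c(-1, 1), 10))      # identical frequencies
  v_fix <- cbind(c(rep(-1, 10), rep(1, 10)))  # fixed difference
  gm <- gm_from(cbind(m1 = v_same[, 1], m2 = v_fix[, 1]))
  fst <- fst_per_marker(gm, groups)
  expect_lt(abs(fst[["m1"]]), 0.15)   # zero up to the finite-sample bias term
  expect_gt(fst[["m2"]], 0.95)
  # textbook two-group hand calculation
  a <- c(1, 1, 1, -1, -1, 1, 1, 1, 1, 1, -1, -1, -1, -1, 1, -1, -1, -1, -1, -1)
  gm2 <- gm_from(cbind(m = a))
  th <- fst_per_marker(gm2, groups)[["m"]]
  # Weir-Cockerham theta for n1 = n2 = 10 (20 alleles... inbred, 2N counted)
  ni <- c(10, 10); pi <- c(mean(a[1:10] == 1), mean(a[11:20] == 1))
  r <- 2; nbar <- 10; nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- mean(pi)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  A <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  B <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  expect_equal(th, A / (A + B), tolerance = 1e-10)
  expect_error(fst_per_marker(gm2, rep("A", 20)), "2 groups")
})
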