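# Independent straight-line re-implementation of the iterative SVD
# imputation pseudocode, used as an oracle.
svdi_oracle <- function(v, k, max_iter = 10, tol = 0.02) {
  obs <- !is.na(v)
  mu <- colMeans(v, na.rm = TRUE)
  X <- v
  for (j in seq_len(ncol(v))) X[!obs[, j], j] <- mu[j]
  rss_prev <- NULL
  for (it in seq_len(max_iter)) {
    U <- svd(X)$u[, seq_len(k), drop = FALSE]
    rss <- 0
    for (j in seq_len(ncol(v))) {
      o <- obs[, j]
      beta <- qr.coef(qr(U[o, , drop = FALSE]), v[o, j])
      beta[is.na(beta)] <- 0
      fit <- drop(U %*% beta)
      rss <- rss + sum((v[o, j] - fit[o])^2)
      X[!o, j] <- fit[!o]
    }
    if (!is.null(rss_prev) && abs(rss_prev - rss) / rss < tol) break
    rss_prev <- rss
  }
  X
}

test_that("SVDI recovers exact low-rank structure and matches the oracle", {
  # rank-1 matrix with holes: k = 1 recovers them to machine precision
  set.seed(3)
  u <- rnorm(12); w <- rnorm(9)
  truth <- outer(u, w)
  v <- truth
  v[cbind(c(2, 5, 8, 11), c(1, 4, 6, 9))] <- NA
  gm <- geno_matrix(v, coding = "MINUS1_1", continuous = TRUE)
  res <- impute_svdi(gm, k = 1, tol = 1e-12, max_iter = 100)
  expect_equal(res$completed$values, truth, tolerance = 1e-8,
               ignore_attr = TRUE)
  # complete matrix: identity, converges immediately
  full <- geno_matrix(truth, coding = "MINUS1_1", continuous = TRUE)
  resf <- impute_svdi(full, k = 2)
  expect_equal(resf$completed$values, truth, ignore_attr = TRUE)
  # noisy low-rank matrix: matches the independent re-implementation
  set.seed(17)
  v2 <- outer(rnorm(8), rnorm(6)) + outer(rnorm(8), rnorm(6)) +
    0.1 * matrix(rnorm(48), 8)
  v2[sample(48, 10)] <- NA
  gm2 <- geno_matrix(v2, coding = "MINUS1_1", continuous = TRUE)
  for (k in c(1, 2, 3)) {
    expect_equal(impute_svdi(gm2, k)$completed$values,
                 svdi_oracle(v2, k), tolerance = 1e-8, ignore_attr = TRUE,
                 info = paste("k =", k))
  }
  expect_error(impute_svdi(gm2, k = 99), "between 1 and")
})

test_that("SVDI convergence uses the relative RSS change rule", {
  set.seed(5)
  v <- outer(rnorm(10), rnorm(8)) + 0.05 * matrix(rnorm(80), 10)
  v[sample(80, 16)] <- NA
  gm <- geno_matrix(v, coding = "MINUS1_1", continuous = TRUE)
  res <- impute_svdi(gm, k = 1, tol = 0.02, max_iter = 10)
  tr <- res$convergence_trace
  n <- length(tr)
  if (n < 10) {
    expect_lt(abs(tr[n - 1] - tr[n]) / tr[n], 0.02)
    if (n > 2)
      expect_true(all(abs(diff(tr[seq_len(n - 1)])) /
                        tr[2:(n - 1)] >= 0.02))
  }
})

test_that("EMI fills are conditional-MVN expectations of the fitted model", {
  # duplicated individuals: the fill equals the duplicate's value
  set.seed(11)
  base <- sample(c(-1, 1), 10, replace = TRUE)
  v <- rbind(base, base, matrix(sample(c(-1, 1), 40, replace = TRUE), 4))
  rownames(v) <- NULL
  v[2, 4] <- NA
  gm <- gm_from(v)
  res <- impute_emi(gm, tol = 1e-6, max_iter = 200)
  expect_equal(res$completed$values[2, 4], v[1, 4], tolerance = 1e-4)
  # complete matrix: identity, converges immediately
  full <- gm_from(matrix(sample(c(-1, 1), 24, replace = TRUE), 4))
  resf <- impute_emi(full)
  expect_identical(resf$completed$values, full$values)
  # seeded MVN matrix: fills equal the explicit Schur-complement formula
  # evaluated at the converged parameter estimates
  set.seed(23)
  L <- matrix(rnorm(64), 8); Sig <- tcrossprod(L) / 8 + diag(8) * 0.5
  v2 <- t(chol(Sig)) %*% matrix(rnorm(8 * 12), 8)
  v2[sample(96, 14)] <- NA
  gm2 <- geno_matrix(v2, coding = "MINUS1_1", continuous = TRUE)
  res2 <- impute_emi(gm2, tol = 1e-8, max_iter = 500)
  mu <- res2$mvn_mean; S <- res2$mvn_cov
  for (j in seq_len(ncol(v2))) {
    mis <- is.na(v2[, j])
    if (!any(mis)) next
    o <- !mis
    pred <- mu[mis] + S[mis, o, drop = FALSE] %*%
      solve(S[o, o], v2[o, j] - mu[o])
    expect_equal(unname(res2$completed$values[mis, j]), unname(drop(pred)),
                 tolerance = 1e-4)
  }
})

test_that("RFI exploits duplicate markers and handles degenerate columns", {
  gm <- twin_gm(holes_in = 1, m = 60)
  res <- impute_rfi(gm, n_trees = 50, seed = 3)
  miss <- is.na(gm$values[, 1])
  expect_equal(res$completed$values[miss, 1], gm$values[miss, 2],
               tolerance = 1e-8)
  # near-constant marker with holes: fills equal the constant
  v <- cbind(a = c(rep(1, 9), NA), b = c(rep(c(-1, 1), 4), 1, -1))
  gm2 <- gm_from(v)
  res2 <- impute_rfi(gm2, n_trees = 30, seed = 1)
  expect_equal(res2$completed$values[10, 1], 1, tolerance = 1e-8)
})

test_that("RFI agrees with an independent iterative-forest reference", {
  # reference: same pseudocode written independently against randomForest
  set.seed(41)
  pop <- simulate_population(n_founders = 10, n_families = 6,
                             lines_per_family = 5, n_markers = 40,
                             n_chromosomes = 2, seed = 41)
  md <- mask_missing(pop$genotypes,
                     missingness_spec(cap = 0.5, fractions = 0.3), seed = 2)
  v <- md$observed$values
  obs <- !is.na(v)
  ord <- order(colMeans(!obs))
  ord <- ord[colSums(!obs)[ord] > 0]
  mu <- colMeans(v, na.rm = TRUE)
  X <- v
  for (j in seq_len(ncol(v))) X[!obs[, j], j] <- mu[j]
  set.seed(7)
  for (sweep in 1:2) {
    for (j in ord) {
      o <- obs[, j]
      fit <- suppressWarnings(
        randomForest::randomForest(x = X[o, -j, drop = FALSE],
                                   y = v[o, j], ntree = 100,
                                   mtry = ncol(v) - 1, nodesize = 5))
      X[!o, j] <- predict(fit, X[!o, -j, drop = FALSE])
    }
  }
  res <- impute_rfi(md$observed, n_trees = 100, max_iter = 2, seed = 9)
  fills_ref <- X[!obs]
  fills_pkg <- res$completed$values[!obs]
  expect_gt(stats::cor(fills_ref, fills_pkg), 0.95)
})
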