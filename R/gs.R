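#' Ridge-regression BLUP of marker effects
#'
#' Fits `y = 1*mu + X u + e` with i.i.d. normal marker effects
#' `u ~ N(0, sigma2_u I)`. Marker columns are mean-centred; the variance
#' ratio `lambda = sigma2_e / sigma2_u` comes from restricted maximum
#' likelihood via the spectral decomposition of the marker cross-product
#' (one-dimensional optimisation), unless a fixed `lambda` is supplied.
#' Effects are the ridge solution at that ratio, computed through the
#' equivalent kernel form `u = Xc' (Xc Xc' + lambda I)^-1 (y - mu)`.
#'
#' @param X complete m x n marker matrix (or a `geno_matrix`).
#' @param y numeric phenotype vector of length m.
#' @param lambda optional fixed ridge parameter; `NULL` (default) = REML.
#' @return object of class `rr_fit`: `mu`, `marker_effects`, `sigma2_u`,
#'   `sigma2_e`, `lambda`, `center` (training column means), `gebv`
#'   (fitted genetic values).
#' @export
fit_rrblup <- function(X, y, lambda = NULL) {
  if (inherits(X, "geno_matrix")) X <- X$values
  if (anyNA(X)) stop("marker matrix has missing calls; impute first")
  m <- nrow(X)
  if (length(y) != m) stop("phenotype length does not match individuals")
  if (m < 3) stop("need at least 3 individuals")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  G <- tcrossprod(Xc)
  if (is.null(lambda)) {
    vc <- reml_kernel(y, G)               # K = Xc Xc' directly: sg2 = sigma2_u
    lambda <- vc$delta
    sigma2_u <- vc$sigma2_g
    sigma2_e <- vc$sigma2_e
  } else {
    sigma2_u <- NA_real_; sigma2_e <- NA_real_
  }
  V <- G + lambda * diag(m)
  Vinv_1 <- solve(V, rep(1, m))
  mu <- sum(Vinv_1 * y) / sum(Vinv_1)
  alpha <- solve(V, y - mu)
  u <- drop(crossprod(Xc, alpha))
  gebv <- drop(Xc %*% u)
  structure(list(mu = mu, marker_effects = u, sigma2_u = sigma2_u,
                 sigma2_e = sigma2_e, lambda = lambda, center = ctr,
                 gebv = stats::setNames(gebv, rownames(X))),
            class = "rr_fit")
}

#' Predict genetic values from a ridge-regression BLUP fit
#' @param object an `rr_fit`.
#' @param newdata m' x n marker matrix on the same markers.
#' @param ... unused.
#' @return numeric vector of predicted genetic values (centred scale, add
#'   `object$mu` for phenotype scale).
#' @export
predict.rr_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "geno_matrix")) newdata <- newdata$values
  drop(sweep(newdata, 2, object$center) %*% object$marker_effects)
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
rinvgauss1 <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Bayesian LASSO regression of marker effects
#'
#' Park-Casella Gibbs sampler: double-exponential priors on marker effects
#' through the scale-mixture-of-normals augmentation, a Gamma hyperprior on
#' `lambda^2` (rate parameterisation) and a scaled-inverse-chi-squared prior
#' on the residual variance. Marker columns are mean-centred; posterior
#' means are taken over the post-burn-in, thinned draws.
#'
#' @param X complete m x n marker matrix (or a `geno_matrix`).
#' @param y numeric phenotype vector.
#' @param n_iter total Gibbs iterations (default 10000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin thinning interval (default 1).
#' @param seed integer seed; identical seeds give identical chains.
#' @param lambda2_shape,lambda2_rate Gamma hyperprior on `lambda^2`.
#' @param nu0,s0 scaled-inverse-chi-squared prior on the residual variance
#'   (`s0 = NULL` defaults to `var(y)/2`).
#' @return object of class `bl_fit`: `mu`, `posterior_mean_effects`,
#'   `gebv`, `center`, `chain_params`, `hyperpriors`, `posterior_lambda2`,
#'   `posterior_sigma2`.
#' @export
fit_bayesian_lasso <- function(X, y, n_iter = 10000, burn_in = 2000,
                               thin = 1, seed = 1,
                               lambda2_shape = 0.1, lambda2_rate = 0.1,
                               nu0 = 3, s0 = NULL) {
  if (inherits(X, "geno_matrix")) X <- X$values
  if (anyNA(X)) stop("marker matrix has missing calls; impute first")
  m <- nrow(X); n <- ncol(X)
  if (length(y) != m) stop("phenotype length does not match individuals")
  if (m < 3) stop("need at least 3 individuals")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (is.null(s0)) s0 <- stats::var(y) / 2
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  xtx <- colSums(Xc^2)
  with_seed(seed, {
    beta <- rep(0, n)
    tau2 <- rep(1, n)
    sigma2 <- stats::var(y) / 2
    lambda2 <- 1
    mu <- mean(y)
    e <- y - mu                           # current residual (beta = 0)
    keep <- seq(burn_in + 1, n_iter, by = thin)
    beta_sum <- rep(0, n); mu_sum <- 0
    l2_draws <- numeric(length(keep)); s2_draws <- numeric(length(keep))
    ki <- 0L
    for (it in seq_len(n_iter)) {
      # intercept
      e <- e + mu
      mu <- stats::rnorm(1, mean(e), sqrt(sigma2 / m))
      e <- e - mu
      # effects, single site
      for (j in seq_len(n)) {
        if (xtx[j] == 0) next
        e <- e + Xc[, j] * beta[j]
        cj <- xtx[j] + 1 / tau2[j]
        bj <- sum(Xc[, j] * e) / cj
        beta[j] <- stats::rnorm(1, bj, sqrt(sigma2 / cj))
        e <- e - Xc[, j] * beta[j]
      }
      # latent scales
      mu_ig <- sqrt(lambda2 * sigma2 / pmax(beta^2, 1e-12))
      tau2 <- 1 / rinvgauss1(n, mu_ig, lambda2)
      tau2 <- pmax(tau2, 1e-12)
      # shrinkage hyperparameter
      lambda2 <- stats::rgamma(1, shape = lambda2_shape + n,
                               rate = lambda2_rate + sum(tau2) / 2)
      # residual variance
      sigma2 <- 1 / stats::rgamma(1,
        shape = (m + n + nu0) / 2,
        rate = (sum(e^2) + sum(beta^2 / tau2) + nu0 * s0) / 2)
      if (!is.finite(sigma2) || !all(is.finite(beta)))
        stop("Bayesian LASSO chain diverged (non-finite draws)")
      if (it %in% keep) {
        ki <- ki + 1L
        beta_sum <- beta_sum + beta
        mu_sum <- mu_sum + mu
        l2_draws[ki] <- lambda2; s2_draws[ki] <- sigma2
      }
    }
    beta_hat <- beta_sum / length(keep)
    mu_hat <- mu_sum / length(keep)
    structure(list(mu = mu_hat, posterior_mean_effects = beta_hat,
                   gebv = stats::setNames(drop(Xc %*% beta_hat), rownames(X)),
                   center = ctr,
                   chain_params = list(n_iter = n_iter, burn_in = burn_in,
                                       thin = thin, seed = seed),
                   hyperpriors = list(lambda2_shape = lambda2_shape,
                                      lambda2_rate = lambda2_rate,
                                      nu0 = nu0, s0 = s0),
                   posterior_lambda2 = mean(l2_draws),
                   posterior_sigma2 = mean(s2_draws)),
              class = "bl_fit")
  })
}

#' Predict genetic values from a Bayesian LASSO fit
#' @param object a `bl_fit`.
#' @param newdata m' x n marker matrix on the same markers.
#' @param ... unused.
#' @return numeric vector of predicted genetic values (centred scale).
#' @export
predict.bl_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "geno_matrix")) newdata <- newdata$values
  drop(sweep(newdata, 2, object$center) %*% object$posterior_mean_effects)
}

#' Cross-validated genomic selection accuracy
#'
#' Individuals are assigned at random to `n_folds` folds; for each fold the
#' model is trained on the remaining individuals and genomic estimated
#' breeding values are predicted for the fold. Accuracy is the Pearson
#' correlation between predicted GEBVs and the supplied phenotype-estimated
#' breeding values, per fold; the mean across folds is the headline
#' accuracy.
#'
#' @param X complete m x n marker matrix (or a `geno_matrix`).
#' @param y phenotype vector (breeding-value estimates).
#' @param model `"RR"` (ridge-regression BLUP) or `"BL"` (Bayesian LASSO).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed (fold assignment, and the BL chain).
#' @param ... passed to the model fitter (e.g. `n_iter` for `"BL"`).
#' @return object of class `cv_result`: `fold_assignment`, `gebv` (each
#'   predicted from the model trained without its fold), `per_fold_accuracy`,
#'   `mean_accuracy`, `model`, `seed`.
#' @export
cross_validate <- function(X, y, model = c("RR", "BL"), n_folds = 10,
                           seed = 1, ...) {
  model <- match.arg(model)
  if (inherits(X, "geno_matrix")) X <- X$values
  m <- nrow(X)
  if (length(y) != m) stop("phenotype length does not match individuals")
  if (n_folds < 2) stop("need at least 2 folds")
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = m)))
  if (min(table(folds)) < 2) stop("a fold has fewer than 2 individuals")
  gebv <- rep(NA_real_, m)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    fit <- if (model == "RR") fit_rrblup(X[!test, , drop = FALSE], y[!test], ...)
           else fit_bayesian_lasso(X[!test, , drop = FALSE], y[!test],
                                   seed = derive_seed(seed, "bl", f), ...)
    gebv[test] <- predict(fit, X[test, , drop = FALSE])
    acc[f] <- stats::cor(gebv[test], y[test])
  }
  structure(list(fold_assignment = folds,
                 gebv = stats::setNames(gebv, rownames(X)),
                 per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 model = model, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s, %d folds): mean accuracy %.3f (sd %.3f)\n",
              x$model, length(x$per_fold_accuracy), x$mean_accuracy,
              stats::sd(x$per_fold_accuracy)))
  invisible(x)
}
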