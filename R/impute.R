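# All imputation methods operate on the numeric codes as continuous
# variables and return an `imputation_result`: the completed matrix plus
# method metadata. Observed cells are always returned bit-exact.

new_imputation_result <- function(gm, completed_values, method, hyperparams,
                                  trace = numeric(0), iterations = 0L,
                                  seed = NULL, notes = character(0)) {
  completed <- gm
  completed$values <- completed_values
  completed$continuous <- TRUE
  structure(list(completed = completed, method = method,
                 hyperparams = hyperparams,
                 convergence_trace = trace,
                 iterations_run = as.integer(iterations),
                 seed = seed, notes = notes),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: %s, %d iteration(s)\n",
              x$method, x$iterations_run))
  if (length(x$convergence_trace))
    cat("  trace:", paste(signif(x$convergence_trace, 4), collapse = " "), "\n")
  invisible(x)
}

check_imputable <- function(gm) {
  nobs <- colSums(!is.na(gm$values))
  if (any(nobs == 0))
    stop("marker(s) with no observed calls cannot be imputed: ",
         paste(colnames(gm$values)[nobs == 0], collapse = ", "))
  invisible(nobs)
}

mni_fill <- function(v) {
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  v
}

#' Marker-mean imputation (MNI)
#'
#' Replaces each missing call with the mean of the non-missing calls at the
#' same marker. The baseline every other method is compared against.
#'
#' @param gm a `geno_matrix` with at least one observed call per marker.
#' @return an `imputation_result`.
#' @export
impute_mni <- function(gm) {
  check_imputable(gm)
  new_imputation_result(gm, mni_fill(gm$values), "MNI", list())
}

#' k-nearest-neighbour imputation (kNNI)
#'
#' Missing calls at a marker are replaced by the `1/d^2`-weighted average of
#' the calls at the `k` closest markers, `d` being the Euclidean distance
#' between marker vectors computed once on a marker-mean pre-filled matrix.
#' Each marker enters the candidate set twice, in its original and
#' sign-flipped state, so that markers in strong negative LD rank as close
#' neighbours; a marker's own flipped copy is excluded from its candidates.
#' Only candidates with an *originally observed* call in the target row are
#' used; if fewer than `k` such candidates exist all available ones are
#' used, and with none at all the marker-mean fill is kept.
#'
#' Candidates at distance zero get the limiting weight: the fill is the
#' unweighted mean of the zero-distance candidates' calls. Ties at the k-th
#' distance break by ascending candidate index.
#'
#' @param gm a `geno_matrix`.
#' @param k number of neighbours, `1 <= k <= 2 * (n - 1)`.
#' @return an `imputation_result`.
#' @export
impute_knni <- function(gm, k = 5) {
  check_imputable(gm)
  n <- n_markers(gm); m <- n_individuals(gm)
  if (k < 1 || k > 2 * (n - 1))
    stop("k must be between 1 and 2*(n-1) = ", 2 * (n - 1))
  # canonicalise ZERO_1 to the symmetric coding so "flipped" = sign flip
  shift <- gm$coding == "ZERO_1"
  v_obs <- if (shift) 2 * gm$values - 1 else gm$values
  X <- mni_fill(v_obs)
  C <- cbind(X, -X)                       # doubled candidate matrix
  cn <- colSums(C^2)
  # squared distances target j vs candidate v: ||x_j||^2 + ||c_v||^2 - 2 x_j.c_v
  D2 <- outer(cn[seq_len(n)], cn, "+") - 2 * crossprod(X, C)
  D2[D2 < 0] <- 0
  obs <- !is.na(v_obs)
  filled <- X
  n_fallback <- 0L
  for (j in seq_len(n)) {
    mis_rows <- which(!obs[, j])
    if (length(mis_rows) == 0) next
    d2j <- D2[j, ]
    d2j[c(j, j + n)] <- Inf               # self and own flip excluded
    ord <- order(d2j)                     # stable: ties by ascending index
    cand_marker <- ifelse(ord > n, ord - n, ord)
    cand_sign <- ifelse(ord > n, -1, 1)
    d2_sorted <- d2j[ord]
    for (i in mis_rows) {
      avail <- obs[i, cand_marker]
      sel <- which(avail)
      if (length(sel) == 0) { n_fallback <- n_fallback + 1L; next }
      sel <- sel[seq_len(min(k, length(sel)))]
      vals <- cand_sign[sel] * v_obs[i, cand_marker[sel]]
      d2s <- d2_sorted[sel]
      if (any(d2s == 0)) {
        filled[i, j] <- mean(vals[d2s == 0])
      } else {
        w <- 1 / d2s
        filled[i, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  if (shift) filled <- (filled + 1) / 2
  out_vals <- gm$values
  out_vals[!obs] <- filled[!obs]
  new_imputation_result(gm, out_vals, "kNNI", list(k = k),
                        notes = if (n_fallback > 0)
                          sprintf("%d cell(s) kept the marker-mean fill (no candidate with an observed call in the row)",
                                  n_fallback) else character(0))
}

#' Iterative singular-value-decomposition imputation (SVDI)
#'
#' After a marker-mean pre-fill, each iteration takes the top-`k` left
#' singular vectors of the current completed matrix and, marker by marker,
#' regresses the originally observed calls on them; missing cells are
#' replaced by the regression predictions. Iteration stops when the
#' relative change in the residual sum of squares over all originally
#' observed cells drops below `tol`, or after `max_iter` iterations.
#'
#' @param gm a `geno_matrix`.
#' @param k number of singular vectors, `1 <= k <= min(m, n) - 1`.
#' @param max_iter maximum iterations (default 10).
#' @param tol relative RSS convergence threshold (default 0.02).
#' @return an `imputation_result`; `convergence_trace` holds the RSS of each
#'   iteration.
#' @export
impute_svdi <- function(gm, k, max_iter = 10, tol = 0.02) {
  check_imputable(gm)
  m <- n_individuals(gm); n <- n_markers(gm)
  if (k < 1 || k > min(m, n) - 1)
    stop("k must be between 1 and min(m, n) - 1 = ", min(m, n) - 1)
  v <- gm$values
  obs <- !is.na(v)
  X <- mni_fill(v)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sv <- svd(X, nu = k, nv = 0)
    U <- sv$u
    rss <- 0
    for (j in seq_len(n)) {
      o <- obs[, j]
      beta <- pinv_solve(U[o, , drop = FALSE], v[o, j])
      fit <- drop(U %*% beta)
      rss <- rss + sum((v[o, j] - fit[o])^2)
      if (any(!o)) X[!o, j] <- fit[!o]
    }
    trace <- c(trace, rss)
    if (it >= 2) {
      if (abs(trace[it - 1] - rss) / rss < tol) break
    }
  }
  out_vals <- v
  out_vals[!obs] <- X[!obs]
  new_imputation_result(gm, out_vals, "SVDI",
                        list(k = k, max_iter = max_iter, tol = tol),
                        trace = trace, iterations = length(trace))
}

# Minimum-norm least squares via SVD (handles rank deficiency).
pinv_solve <- function(A, b, rtol = 1e-10) {
  if (nrow(A) == 0) return(rep(0, ncol(A)))
  sv <- svd(A)
  d <- sv$d
  pos <- d > rtol * max(d, 0)
  if (!any(pos)) return(rep(0, ncol(A)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], b)) / d[pos]))
}

#' Expectation-maximisation imputation (EMI)
#'
#' Models the vector of individuals as multivariate normal with markers as
#' repeated observations. Each E-step replaces the missing entries of a
#' marker column by their conditional expectation given the observed
#' entries, the current mean vector and the current individual-by-individual
#' covariance matrix; each M-step re-estimates the mean and covariance from
#' the completed matrix, adding the Schur-complement conditional covariance
#' of the imputed entries (the expected-sufficient-statistic M-step of EM
#' for multivariate-normal missing data, which keeps the covariance from
#' collapsing onto the regression surface). Convergence is declared when
#' the maximum absolute change over the concatenation of the mean vector
#' and the entries of the covariance Gram matrix (S S') is at most `tol`.
#'
#' @param gm a `geno_matrix` with `m >= 2` individuals.
#' @param tol convergence threshold (default 0.02).
#' @param max_iter maximum EM iterations (default 50).
#' @param ridge relative ridge added to the observed-block covariance before
#'   inversion when it is numerically singular.
#' @return an `imputation_result`; `convergence_trace` holds the monitored
#'   max-absolute-change per iteration.
#' @export
impute_emi <- function(gm, tol = 0.02, max_iter = 50, ridge = 1e-8) {
  check_imputable(gm)
  m <- n_individuals(gm)
  if (m < 2) stop("EMI needs at least 2 individuals")
  v <- gm$values
  obs <- !is.na(v)
  X <- mni_fill(v)
  n <- ncol(X)
  mis_cols <- which(colSums(!obs) > 0)
  trace <- numeric(0)
  prev_stat <- NULL
  Ccum <- matrix(0, m, m)                 # summed conditional covariances
  for (it in seq_len(max_iter)) {
    mu <- rowMeans(X)
    Xc <- X - mu
    S <- (tcrossprod(Xc) + Ccum) / max(n - 1, 1)
    G <- S %*% S
    stat <- c(mu, G)
    if (!is.null(prev_stat)) {
      delta <- max(abs(stat - prev_stat))
      trace <- c(trace, delta)
      if (delta <= tol) break
    } else {
      trace <- c(trace, Inf)
    }
    prev_stat <- stat
    Ccum <- matrix(0, m, m)
    for (j in mis_cols) {
      o <- obs[, j]
      Soo <- S[o, o, drop = FALSE]
      diag(Soo) <- diag(Soo) + ridge * mean(diag(Soo))
      Smo <- S[!o, o, drop = FALSE]
      sol <- tryCatch(solve(Soo, cbind(v[o, j] - mu[o], t(Smo))),
                      error = function(e) {
                        diag(Soo) <- diag(Soo) + 1e-4 * mean(diag(Soo))
                        solve(Soo, cbind(v[o, j] - mu[o], t(Smo)))
                      })
      X[!o, j] <- mu[!o] + drop(Smo %*% sol[, 1])
      Ccum[!o, !o] <- Ccum[!o, !o] +
        (S[!o, !o, drop = FALSE] - Smo %*% sol[, -1, drop = FALSE])
    }
  }
  out_vals <- v
  out_vals[!obs] <- X[!obs]
  out <- new_imputation_result(gm, out_vals, "EMI",
                               list(tol = tol, max_iter = max_iter),
                               trace = trace, iterations = length(trace))
  out$mvn_mean <- mu                      # final MVN parameter estimates
  out$mvn_cov <- S
  out
}

#' Iterative random-forest regression imputation (RFI)
#'
#' Markers are sorted from lowest to highest missing fraction and pre-filled
#' with marker means. For each marker with missing calls, `n_trees`
#' regression trees are grown on bootstrap samples of the originally
#' observed rows, with all other markers (current completed values) as
#' predictors; the missing calls are replaced by the ensemble mean and the
#' matrix is updated in place before moving to the next marker. Full sweeps
#' repeat until the relative change
#' `sum((M1 - M0)^2) / sum(M1^2)` (over the columns that had missing calls)
#' increases for the first time — the previous matrix is then returned — or
#' until `max_iter` sweeps.
#'
#' The tree ensembles are grown with [ranger::ranger]; every tree considers
#' all `n - 1` predictor markers at each split (bagging without feature
#' subsampling), with minimum node size 5 and unlimited depth. `mtry =
#' "sqrt"` switches to conventional random-forest feature subsampling.
#'
#' @param gm a `geno_matrix`.
#' @param n_trees trees per marker (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed (tree growth is stochastic).
#' @param mtry `"all"` (default; all other markers tried at each split) or
#'   `"sqrt"`.
#' @return an `imputation_result`; `convergence_trace` holds the per-sweep
#'   change statistic.
#' @export
impute_rfi <- function(gm, n_trees = 100, max_iter = 10, seed = 1,
                       mtry = c("all", "sqrt")) {
  mtry <- match.arg(mtry)
  check_imputable(gm)
  v <- gm$values
  obs <- !is.na(v)
  n <- ncol(v)
  if (n < 2) stop("RFI needs at least 2 markers")
  mis_cols <- which(colSums(!obs) > 0)
  if (length(mis_cols) == 0) {
    return(new_imputation_result(gm, v, "RFI",
                                 list(n_trees = n_trees, max_iter = max_iter,
                                      mtry = mtry),
                                 iterations = 0L, seed = seed))
  }
  ord <- mis_cols[order(colMeans(!obs)[mis_cols])]  # lowest %missing first
  X <- mni_fill(v)
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(n))
  mtry_n <- if (mtry == "all") n - 1 else max(1, floor(sqrt(n - 1)))
  trace <- numeric(0)
  prev <- NULL
  result <- X
  with_seed(seed, {
    for (sweep in seq_len(max_iter)) {
      M0 <- X
      for (j in ord) {
        o <- obs[, j]
        fit <- ranger::ranger(x = X[o, -j, drop = FALSE], y = v[o, j],
                              num.trees = n_trees, mtry = mtry_n,
                              min.node.size = 5, num.threads = 1,
                              oob.error = FALSE,
                              seed = sample.int(.Machine$integer.max, 1))
        X[!o, j] <- stats::predict(fit, X[!o, -j, drop = FALSE],
                                   num.threads = 1)$predictions
      }
      dn <- sum((X[, ord] - M0[, ord])^2) / sum(X[, ord]^2)
      trace <- c(trace, dn)
      if (!is.null(prev) && dn > prev) {
        result <- M0                       # previous estimate is final
        break
      }
      prev <- dn
      result <- X
    }
  })
  out_vals <- v
  out_vals[!obs] <- result[!obs]
  new_imputation_result(gm, out_vals, "RFI",
                        list(n_trees = n_trees, max_iter = max_iter,
                             mtry = mtry),
                        trace = trace, iterations = length(trace),
                        seed = seed)
}

#' Dispatch an imputation method by name
#'
#' @param gm a `geno_matrix`.
#' @param method `"MNI"`, `"kNNI"`, `"SVDI"`, `"EMI"` or `"RFI"`.
#' @param k neighbours (kNNI) or singular vectors (SVDI); defaults: 5 for
#'   kNNI, `max(1, min(m, n) %/% 10)` for SVDI.
#' @param seed seed for RFI.
#' @param ... further arguments passed to the method.
#' @return an `imputation_result`.
#' @export
impute <- function(gm, method = c("MNI", "kNNI", "SVDI", "EMI", "RFI"),
                   k = NULL, seed = 1, ...) {
  method <- match.arg(method)
  switch(method,
         MNI = impute_mni(gm),
         kNNI = impute_knni(gm, k = if (is.null(k)) 5 else k, ...),
         SVDI = impute_svdi(gm, k = if (is.null(k))
           max(1, min(dim(gm)) %/% 10) else k, ...),
         EMI = impute_emi(gm, ...),
         RFI = impute_rfi(gm, seed = seed, ...))
}

#' Choose k by cross-validation for kNNI or SVDI
#'
#' Each fold hides a random 5% of the observed cells, imputes with every k
#' in the grid, and scores mean squared error against the held-out truth;
#' errors are averaged over folds and the k with the minimal error wins
#' (ties go to the smallest k).
#'
#' @param gm a `geno_matrix`.
#' @param method `"kNNI"` or `"SVDI"`.
#' @param grid integer vector of candidate k values.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @param holdout_frac fraction of observed cells hidden per fold.
#' @return object of class `k_selection_report`: list with `method`, `grid`,
#'   `cv_error_per_k`, `chosen_k`.
#' @export
select_k_cv <- function(gm, method = c("kNNI", "SVDI"), grid,
                        n_folds = 10, seed = 1, holdout_frac = 0.05) {
  method <- match.arg(method)
  if (length(grid) == 0) stop("empty k grid")
  grid <- sort(unique(as.integer(grid)))
  m <- n_individuals(gm); n <- n_markers(gm)
  kmax <- if (method == "kNNI") 2 * (n - 1) else min(m, n) - 1
  if (any(grid < 1 | grid > kmax))
    stop("grid contains k outside [1, ", kmax, "] for ", method)
  v <- gm$values
  obs_idx <- which(!is.na(v))
  errs <- matrix(NA_real_, n_folds, length(grid))
  with_seed(seed, {
    for (f in seq_len(n_folds)) {
      hide <- sample(obs_idx, max(1, round(holdout_frac * length(obs_idx))))
      gm_f <- gm
      gm_f$values[hide] <- NA_real_
      # a marker left with no observed calls cannot be imputed; restore one
      empty <- which(colSums(!is.na(gm_f$values)) == 0)
      for (j in empty) {
        cell <- intersect(hide, (j - 1) * m + seq_len(m))[1]
        gm_f$values[cell] <- v[cell]
        hide <- setdiff(hide, cell)
      }
      for (g in seq_along(grid)) {
        res <- if (method == "kNNI") impute_knni(gm_f, k = grid[g])
               else impute_svdi(gm_f, k = grid[g])
        errs[f, g] <- mean((res$completed$values[hide] - v[hide])^2)
      }
    }
  })
  cv_err <- colMeans(errs)
  chosen <- grid[which.min(cv_err)]       # which.min takes the first = smallest k
  structure(list(method = method, grid = grid, cv_error_per_k = cv_err,
                 chosen_k = chosen, per_fold_error = errs, seed = seed),
            class = "k_selection_report")
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat(sprintf("k selection (%s): chosen k = %d\n", x$method, x$chosen_k))
  print(stats::setNames(signif(x$cv_error_per_k, 4), x$grid))
  invisible(x)
}
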