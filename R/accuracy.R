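#' Imputation R-squared between truth and imputed values
#'
#' `R2 = 1 - sum((true - imputed)^2) / sum((true - mean(true))^2)`, computed
#' over whatever cells the caller supplies (typically the simulated-missing
#' cells of one marker or one individual). Equals 1 for perfect imputation,
#' 0 for the mean predictor, and can be negative. A constant truth vector
#' has an undefined denominator and returns `NA` (excluded from aggregates).
#'
#' @param truth,imputed numeric vectors of equal length >= 1.
#' @return a single value `<= 1`, or `NA` if undefined.
#' @export
imputation_r2 <- function(truth, imputed) {
  if (length(truth) != length(imputed)) stop("length mismatch")
  if (length(truth) == 0) stop("empty vectors")
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((truth - imputed)^2) / sst
}

new_accuracy_report <- function(rm2 = NULL, ri2 = NULL, method = NA_character_,
                                level = NA_character_, replicate_id = NA_integer_,
                                n_undefined = 0L) {
  structure(list(rm2 = rm2, ri2 = ri2, method = method, level = level,
                 replicate_id = replicate_id,
                 n_undefined = as.integer(n_undefined)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report: %s %s replicate %s\n", x$method, x$level,
              x$replicate_id))
  if (!is.null(x$rm2))
    cat(sprintf("  median Rm2 = %.3f over %d marker(s)\n",
                stats::median(x$rm2, na.rm = TRUE), sum(!is.na(x$rm2))))
  if (!is.null(x$ri2))
    cat(sprintf("  median Ri2 = %.3f over %d individual(s)\n",
                stats::median(x$ri2, na.rm = TRUE), sum(!is.na(x$ri2))))
  invisible(x)
}

acc_over_margin <- function(md, res, margin) {
  truth <- md$truth$values
  imp <- res$completed$values
  mask <- md$simulated_mask
  stopifnot(identical(dim(truth), dim(imp)))
  idx <- if (margin == 2) seq_len(ncol(truth)) else seq_len(nrow(truth))
  vals <- rep(NA_real_, length(idx))
  n_undef <- 0L
  for (i in idx) {
    sel <- if (margin == 2) mask[, i] else mask[i, ]
    if (!any(sel)) next                   # no simulated-missing cell: absent
    tt <- if (margin == 2) truth[sel, i] else truth[i, sel]
    ii <- if (margin == 2) imp[sel, i] else imp[i, sel]
    r2 <- imputation_r2(tt, ii)
    if (is.na(r2)) n_undef <- n_undef + 1L
    vals[i] <- r2
  }
  names(vals) <- if (margin == 2) colnames(truth) else rownames(truth)
  list(vals = vals, n_undefined = n_undef)
}

#' Per-marker imputation accuracy (Rm2)
#'
#' For each marker with at least one simulated-missing cell, the imputation
#' R-squared over exactly those cells; the reference mean is taken over the
#' masked-truth subset of that marker. Markers without simulated-missing
#' cells, and markers whose masked truth is constant (undefined
#' denominator), carry `NA`.
#'
#' @param md a `masked_dataset` from [mask_missing()].
#' @param res an `imputation_result` produced from `md$observed`.
#' @param method,level,replicate_id optional labels stored in the report.
#' @return an `accuracy_report` with `rm2` filled.
#' @export
per_marker_accuracy <- function(md, res, method = res$method,
                                level = NA_character_,
                                replicate_id = NA_integer_) {
  a <- acc_over_margin(md, res, margin = 2)
  new_accuracy_report(rm2 = a$vals, method = method, level = level,
                      replicate_id = replicate_id, n_undefined = a$n_undefined)
}

#' Per-individual imputation accuracy (Ri2)
#'
#' As [per_marker_accuracy()] with rows and columns exchanged.
#'
#' @inheritParams per_marker_accuracy
#' @return an `accuracy_report` with `ri2` filled.
#' @export
per_individual_accuracy <- function(md, res, method = res$method,
                                    level = NA_character_,
                                    replicate_id = NA_integer_) {
  a <- acc_over_margin(md, res, margin = 1)
  new_accuracy_report(ri2 = a$vals, method = method, level = level,
                      replicate_id = replicate_id, n_undefined = a$n_undefined)
}

#' Aggregate accuracy reports across replicates
#'
#' Element-wise mean across replicate reports (markers or individuals with
#' an undefined entry in a replicate are averaged over the replicates where
#' they are defined), giving the replicate-averaged vectors Rm2-bar /
#' Ri2-bar. [median_accuracy()] then collapses such a vector to the scalar
#' reported in the result tables, and averaging the replicate-averaged
#' vectors across missingness levels gives the across-level summaries used
#' by the factor analyses.
#'
#' @param reports list of `accuracy_report`s sharing method/level labels.
#' @param which `"rm2"` or `"ri2"`.
#' @return named numeric vector: the element-wise replicate mean.
#' @export
aggregate_accuracy <- function(reports, which = c("rm2", "ri2")) {
  which <- match.arg(which)
  if (length(reports) == 0) stop("no reports")
  labs <- unique(vapply(reports, function(r)
    paste(r$method, r$level, sep = "/"), character(1)))
  if (length(labs) != 1)
    stop("reports carry inconsistent method/level labels: ",
         paste(labs, collapse = " vs "))
  mats <- lapply(reports, function(r) {
    v <- r[[which]]
    if (is.null(v)) stop("report lacks ", which)
    v
  })
  len <- unique(lengths(mats))
  if (length(len) != 1) stop("reports have different lengths")
  M <- do.call(rbind, mats)
  out <- colMeans(M, na.rm = TRUE)
  out[colSums(!is.na(M)) == 0] <- NA_real_
  out
}

#' Median of an accuracy vector, excluding undefined entries
#'
#' @param x numeric vector (e.g. a replicate-averaged Rm2-bar vector).
#' @return the median over non-`NA` entries.
#' @export
median_accuracy <- function(x) stats::median(x, na.rm = TRUE)

#' Equivalent percent-correct of a continuous imputation accuracy
#'
#' Continuous imputed dosages cannot be scored as percent-correct directly;
#' instead a marker's accuracy is translated by simulation. Biallelic truth
#' values are simulated at the marker's minor allele frequency, "imputed"
#' values are generated from a mean-reverting Gaussian model calibrated so
#' the expected imputation R-squared equals `r2`
#' (`imputed = mu + r2 * (truth - mu) + noise`, noise variance
#' `r2 * (1 - r2) * var(truth)`), each imputed value is rounded to the
#' nearest legal code, and the percentage of rounded calls that match the
#' truth is returned. At `r2 = 0` the model collapses to the marker mean and
#' the percent correct converges to `100 * (1 - maf)`; at `r2 = 1` it is 100.
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param r2 imputation R-squared (`<= 1`; negative values are treated as 0
#'   for the mean-reversion slope but keep full-variance noise off).
#' @param n_sims simulated truth values (default 10000).
#' @param seed integer seed.
#' @param coding legal code set for rounding, `"MINUS1_1"` (default) or
#'   `"MINUS1_0_1"`.
#' @return percent of simulated calls imputed correctly, in `[0, 100]`.
#' @export
equivalent_percent_correct <- function(maf, r2, n_sims = 10000, seed = 1,
                                       coding = c("MINUS1_1", "MINUS1_0_1")) {
  coding <- match.arg(coding)
  if (maf < 0 || maf > 0.5) stop("maf must be in [0, 0.5]")
  if (r2 > 1) stop("r2 cannot exceed 1")
  a <- min(max(r2, 0), 1)
  with_seed(seed, {
    truth <- ifelse(stats::runif(n_sims) < maf, -1, 1)
    mu <- 1 - 2 * maf                    # expected dosage of the major allele
    v <- 4 * maf * (1 - maf)             # var of a -1/1 call at this maf
    noise <- stats::rnorm(n_sims, 0, sqrt(a * (1 - a) * v))
    imputed <- mu + a * (truth - mu) + noise
    codes <- .CODINGS[[coding]]
    rounded <- codes[max.col(-abs(outer(imputed, codes, "-")),
                             ties.method = "first")]
    100 * mean(rounded == truth)
  })
}
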