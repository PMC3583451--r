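# Allowed genotype codes per coding scheme. Codes are treated as continuous
# allele dosages by every downstream algorithm; the coding only constrains
# what an *unimputed* matrix may contain.
.CODINGS <- list(
  MINUS1_1   = c(-1, 1),
  ZERO_1     = c(0, 1),
  MINUS1_0_1 = c(-1, 0, 1)
)

#' Construct a genotype matrix
#'
#' The central container of the package: an `m x n` numeric matrix of
#' allele-dosage codes with individuals in rows and markers in columns.
#' Missing calls are stored as `NA`. Before imputation all non-missing
#' values must belong to the declared coding's allowed set; after
#' imputation entries are real-valued and the object is flagged
#' `continuous`.
#'
#' @param values numeric matrix, individuals x markers; `NA` = missing call.
#' @param coding one of `"MINUS1_1"`, `"ZERO_1"`, `"MINUS1_0_1"`.
#' @param individual_ids,marker_ids unique identifiers; taken from
#'   `dimnames(values)` when present, generated otherwise.
#' @param continuous logical; `TRUE` for imputed (real-valued) matrices,
#'   which disables the coding-set check.
#' @return an object of class `geno_matrix` with fields `values`, `coding`,
#'   `continuous`.
#' @export
geno_matrix <- function(values, coding = c("MINUS1_1", "ZERO_1", "MINUS1_0_1"),
                        individual_ids = NULL, marker_ids = NULL,
                        continuous = FALSE) {
  coding <- match.arg(coding)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(individual_ids)) individual_ids <- rownames(values)
  if (is.null(marker_ids)) marker_ids <- colnames(values)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(marker_ids))
    marker_ids <- paste0("mrk", seq_len(ncol(values)))
  if (length(individual_ids) != nrow(values))
    stop("individual_ids length does not match row count")
  if (length(marker_ids) != ncol(values))
    stop("marker_ids length does not match column count")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  dimnames(values) <- list(individual_ids, marker_ids)
  gm <- structure(list(values = values, coding = coding,
                       continuous = isTRUE(continuous)),
                  class = "geno_matrix")
  validate_geno(gm)
  gm
}

validate_geno <- function(gm) {
  v <- gm$values
  if (!gm$continuous) {
    allowed <- .CODINGS[[gm$coding]]
    bad <- which(!is.na(v) & !(v %in% allowed), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "value %s at individual '%s', marker '%s' not allowed under coding %s",
        format(v[bad[1, , drop = FALSE]]),
        rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]], gm$coding))
  }
  invisible(gm)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers, coding %s%s\n",
              nrow(x$values), ncol(x$values), x$coding,
              if (x$continuous) " (continuous/imputed)" else ""))
  cat(sprintf("  missing: %.2f%% of cells\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

n_individuals <- function(gm) nrow(gm$values)
n_markers <- function(gm) ncol(gm$values)

#' Missing mask of a genotype matrix
#' @param gm a `geno_matrix`.
#' @return logical matrix, `TRUE` where the call is missing.
#' @export
missing_mask <- function(gm) is.na(gm$values)

#' Per-marker missing-data fraction
#' @param gm a `geno_matrix`.
#' @return named numeric vector of length `n` markers.
#' @export
missing_fraction <- function(gm) colMeans(is.na(gm$values))

#' Read a genotype matrix from delimited text
#'
#' Default dialect: tab-delimited, header row of marker ids, first column the
#' individual id, `"NA"` as the missing token, individuals in rows. Files with
#' markers in rows are transposed at read time (`orientation =
#' "markers_in_rows"`).
#'
#' @param path file path.
#' @param coding declared coding of the stored codes.
#' @param sep field delimiter.
#' @param header logical; first row holds marker ids.
#' @param missing_token string standing for a missing call.
#' @param orientation `"individuals_in_rows"` (default) or
#'   `"markers_in_rows"`.
#' @return a validated [geno_matrix()].
#' @examples
#' demo <- system.file("extdata", "demo_genotypes.tsv", package = "gbsimpute")
#' gm <- read_geno(demo, coding = "MINUS1_0_1")
#' minor_allele_frequency(gm)
#' @export
read_geno <- function(path, coding = c("MINUS1_1", "ZERO_1", "MINUS1_0_1"),
                      sep = "\t", header = TRUE, missing_token = "NA",
                      orientation = c("individuals_in_rows", "markers_in_rows")) {
  coding <- match.arg(coding)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || (header && length(lines) == 1))
    stop("no records in ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(fields)
  if (length(unique(lens)) != 1)
    stop(sprintf("malformed file %s: row %d has %d fields, expected %d",
                 path, which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]))
  if (header) {
    col_ids <- fields[[1]][-1]
    fields <- fields[-1]
  } else {
    col_ids <- NULL
  }
  row_ids <- vapply(fields, `[[`, character(1), 1)
  cells <- lapply(fields, `[`, -1)
  raw <- do.call(rbind, cells)
  is_na <- raw == missing_token
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is_na & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unparseable genotype '%s' at row '%s', column %d of %s",
                 raw[bad[1, , drop = FALSE]], row_ids[bad[1, 1]], bad[1, 2], path))
  num[is_na] <- NA_real_
  mat <- matrix(num, nrow = length(row_ids))
  rownames(mat) <- row_ids
  if (!is.null(col_ids)) colnames(mat) <- col_ids
  if (orientation == "markers_in_rows") mat <- t(mat)
  geno_matrix(mat, coding = coding)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_geno()]: the written file round-trips values, mask, ids
#' and (given the same `coding` argument on re-read) the coding.
#'
#' @param gm a `geno_matrix`.
#' @param path output path.
#' @param sep,missing_token dialect, as in [read_geno()].
#' @export
write_geno <- function(gm, path, sep = "\t", missing_token = "NA") {
  v <- gm$values
  chr <- matrix(format(v, trim = TRUE, digits = 15), nrow = nrow(v))
  chr[is.na(v)] <- missing_token
  out <- c(paste(c("id", colnames(v)), collapse = sep),
           vapply(seq_len(nrow(v)), function(i)
             paste(c(rownames(v)[i], chr[i, ]), collapse = sep), character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Read a phenotype vector
#'
#' Two-column delimited file: individual id, value. No missing entries are
#' allowed (complete-case contract for downstream model fitting).
#'
#' @param path file path.
#' @param sep delimiter.
#' @param header logical.
#' @param trait_name optional trait label stored as an attribute.
#' @return named numeric vector, names = individual ids.
#' @export
read_phenotype <- function(path, sep = "\t", header = TRUE, trait_name = NULL) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype file needs id and value columns")
  y <- as.numeric(df[[2]])
  if (anyNA(y)) stop("phenotype file contains missing values")
  names(y) <- as.character(df[[1]])
  if (anyDuplicated(names(y))) stop("duplicate individual ids in phenotype file")
  if (!is.null(trait_name)) attr(y, "trait_name") <- trait_name
  y
}

#' Recode a genotype matrix between biallelic codings
#'
#' `ZERO_1` and `MINUS1_1` are related by the affine map `x -> 2x - 1`.
#' A three-state matrix (`MINUS1_0_1`) can only move to a two-state coding
#' if it contains no heterozygote (0) calls.
#'
#' @param gm a `geno_matrix`.
#' @param target target coding.
#' @return recoded `geno_matrix`; recoding back restores the original.
#' @export
recode <- function(gm, target = c("MINUS1_1", "ZERO_1", "MINUS1_0_1")) {
  target <- match.arg(target)
  if (gm$continuous) stop("cannot recode a continuous (imputed) matrix")
  v <- gm$values
  src <- gm$coding
  if (src == target) return(gm)
  has_het <- any(!is.na(v) & v == 0) && src == "MINUS1_0_1"
  to_m11 <- function(x, from) switch(from,
    MINUS1_1 = x, MINUS1_0_1 = x, ZERO_1 = 2 * x - 1)
  from_m11 <- function(x, to) switch(to,
    MINUS1_1 = x, MINUS1_0_1 = x, ZERO_1 = (x + 1) / 2)
  if (src == "MINUS1_0_1" && target != "MINUS1_0_1" && has_het)
    stop("matrix contains heterozygote code 0; cannot recode MINUS1_0_1 to ",
         target)
  if (target == "MINUS1_0_1" && src == "ZERO_1")
    stop("ZERO_1 cannot be recoded to MINUS1_0_1: 2-state data has no ",
         "heterozygote representation under the 3-state map used here")
  out <- from_m11(to_m11(v, src), target)
  geno_matrix(out, coding = target)
}

#' Minor allele frequency per marker
#'
#' Computed from non-missing calls only. Under the two-state codings each
#' individual contributes a single allele observation (fully-inbred
#' assumption); under `MINUS1_0_1` each individual contributes two alleles
#' and a heterozygote contributes one of each.
#'
#' @param gm a `geno_matrix`.
#' @return named vector of frequencies in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(gm) {
  v <- gm$values
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0))
    stop("all calls missing at marker(s): ",
         paste(colnames(v)[nobs == 0], collapse = ", "))
  d <- allele1_dosage(gm)                # in [0, 1] per cell
  p <- colMeans(d, na.rm = TRUE)
  stats::setNames(pmin(p, 1 - p), colnames(v))
}

# Fraction of allele "1" carried per cell, on a 0..1 scale.
allele1_dosage <- function(gm) {
  switch(gm$coding,
         MINUS1_1   = (gm$values + 1) / 2,
         MINUS1_0_1 = (gm$values + 1) / 2,
         ZERO_1     = gm$values)
}

#' Drop markers exceeding a missing-data fraction
#'
#' @param gm a `geno_matrix`.
#' @param max_frac maximum tolerated fraction of missing calls per marker.
#' @return `geno_matrix` with exactly the markers whose missing fraction is
#'   `<= max_frac`, original order preserved.
#' @export
filter_markers_by_missingness <- function(gm, max_frac) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  keep <- missing_fraction(gm) <= max_frac
  subset_markers(gm, which(keep))
}

#' Randomly subsample markers without replacement
#'
#' @param gm a `geno_matrix`.
#' @param n_keep number of markers to retain.
#' @param seed integer seed; identical seeds give identical selections.
#' @return `geno_matrix` with `n_keep` markers (kept in original column order).
#' @export
subsample_markers <- function(gm, n_keep, seed) {
  n <- n_markers(gm)
  if (n_keep > n) stop("n_keep (", n_keep, ") exceeds marker count (", n, ")")
  keep <- sort(with_seed(seed, sample.int(n, n_keep)))
  subset_markers(gm, keep)
}

subset_markers <- function(gm, idx) {
  out <- gm
  out$values <- gm$values[, idx, drop = FALSE]
  out
}

subset_individuals <- function(gm, idx) {
  out <- gm
  out$values <- gm$values[idx, , drop = FALSE]
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit seed derived from a base seed and string labels.
derive_seed <- function(base_seed, ...) {
  labels <- paste(c(base_seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}
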