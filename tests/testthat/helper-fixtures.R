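# Small fixtures built in code.

gm_from <- function(values, coding = "MINUS1_1") {
  geno_matrix(values, coding = coding)
}

# 4 x 3 inbred matrix with one missing cell
tiny_gm <- function() {
  v <- matrix(c(1, 1, -1, 1,
                -1, 1, 1, -1,
                1, NA, -1, -1), nrow = 4)
  gm_from(v)
}

# inbred matrix whose columns 1 and 2 are exact duplicates, column 3 is the
# sign-flip of column 1, column 4 is independent
twin_gm <- function(holes_in = 1, m = 12) {
  set.seed(99)
  base <- sample(c(-1, 1), m, replace = TRUE)
  v <- cbind(m1 = base, m2 = base, m3 = -base,
             m4 = sample(c(-1, 1), m, replace = TRUE))
  v[unique(pmin(c(2, 5, 9, if (m > 20) seq(12, m, by = 7)), m)), holes_in] <- NA
  gm_from(v)
}

# seeded random inbred matrix with a given fraction of holes
holey_gm <- function(m, n, frac, seed = 1, coding = "MINUS1_1") {
  set.seed(seed)
  v <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
  holes <- sample(m * n, round(frac * m * n))
  # keep at least one observed call per column
  for (j in seq_len(n)) {
    cells <- (j - 1) * m + seq_len(m)
    if (all(cells %in% holes)) holes <- setdiff(holes, cells[1])
  }
  v[holes] <- NA
  gm_from(v, coding)
}

# brute-force kNN imputation oracle, straight from the algorithm definition
knni_oracle <- function(gm, k) {
  v <- gm$values
  obs <- !is.na(v)
  mu <- colMeans(v, na.rm = TRUE)
  X <- v
  for (j in seq_len(ncol(v))) X[!obs[, j], j] <- mu[j]
  n <- ncol(v)
  C <- cbind(X, -X)
  out <- v
  for (j in seq_len(n)) for (i in which(!obs[, j])) {
    d <- sqrt(colSums((C - X[, j])^2))
    d[c(j, j + n)] <- Inf
    ord <- order(d)
    cand <- ord[obs[i, ifelse(ord > n, ord - n, ord)]]
    cand <- cand[seq_len(min(k, length(cand)))]
    vals <- ifelse(cand > n, -1, 1) * v[i, ifelse(cand > n, cand - n, cand)]
    dd <- d[cand]
    out[i, j] <- if (any(dd == 0)) mean(vals[dd == 0])
                 else sum(vals / dd^2) / sum(1 / dd^2)
  }
  out
}
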