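# Shared fixtures and independent oracles for the test suite.

rand_peptides <- function(n, len, seed) {
  set.seed(seed)
  apply(matrix(sample(AA_ALPHABET, n * len, replace = TRUE), nrow = n),
        1L, paste, collapse = "")
}

shuffle_seq <- function(s, seed) {
  set.seed(seed)
  paste(sample(strsplit(s, "")[[1L]]), collapse = "")
}

# Independent CFS oracle: enumerates every non-empty subset and computes
# the merit straight from the formula with stats::cor, sharing no code
# with the package's search.
exhaustive_best_merit <- function(X, y) {
  p <- ncol(X)
  rcf <- abs(suppressWarnings(stats::cor(X, y)))
  rcf[is.na(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(X)))
  rff[is.na(rff)] <- 0
  best <- 0
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    k <- length(idx)
    m <- if (k == 1L) rcf[idx] else {
      sub <- rff[idx, idx]
      k * mean(rcf[idx]) / sqrt(k + k * (k - 1) * mean(sub[upper.tri(sub)]))
    }
    if (m > best) best <- m
  }
  best
}

# iid-Gaussian regression fixture with a sparse linear signal
cfs_fixture <- function(seed) {
  set.seed(seed)
  p <- sample(4:12, 1L)
  n <- 30L
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  w <- stats::rnorm(p) * stats::rbinom(p, 1L, 0.5)
  list(X = X, y = as.numeric(X %*% w) + stats::rnorm(n))
}

# small fixed half-life dataset (distinct compositions, distinct targets)
toy_dataset <- function(n = 12L, len = 10L, seed = 101L) {
  seqs <- rand_peptides(n, len, seed)
  set.seed(seed + 1L)
  hl_dataset(seqs, stats::runif(n, 0.1, 5))
}
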