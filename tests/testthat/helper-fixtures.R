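# Small programmatic fixtures shared across test files.

# one small study's feature table
small_cohort <- function(seed = 11, effect_size = 0, n_regions = 30,
                         n_cases = 15, n_controls = 15, ...) {
  generate_cohort(cohort_spec(n_cases = n_cases, n_controls = n_controls,
                              n_regions = n_regions,
                              effect_size = effect_size, seed = seed, ...))
}

# deterministic region-by-feature slice (no RNG)
fixed_slice <- function(n_regions = 4, n_features = 7) {
  m <- outer(seq_len(n_regions), seq_len(n_features),
             function(i, j) sin(i * j) + 0.1 * i)
  rownames(m) <- sprintf("r%02d", seq_len(n_regions))
  m
}

# independent brute-force pairwise Pearson correlation matrix
brute_force_cor <- function(m) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- m[i, ]; y <- m[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# exhaustive Benjamini-Hochberg step-up
brute_force_bh <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  passed <- which(p[ord] <= thresh)
  flags <- logical(n)
  if (length(passed)) flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

# small aligned expression + response fixture for PLS tests
pls_fixture <- function(n_regions = 50, n_genes = 200, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n_regions * n_genes), n_regions, n_genes,
              dimnames = list(sprintf("r%03d", seq_len(n_regions)),
                              sprintf("g%03d", seq_len(n_genes))))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n_regions, sd = 2)
  names(y) <- rownames(X)
  list(X = X, y = y)
}
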