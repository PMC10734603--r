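# Shared fixture builders. Everything is generated in code at test time.

# Tiny factorial design (8 genotypes x 1 timepoint x n reps).
tiny_design <- function(n_replicates = 2, timepoints = 8) {
  generate_design(n_replicates, timepoints)
}

# Deterministic count tibble from a matrix of means (Poisson-free: exact).
counts_from_means <- function(means, design) {
  m <- round(means)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))), design$sample_id)
  out <- tibble::as_tibble(m)
  out$gene_id <- rownames(m)
  out[, c("gene_id", design$sample_id)]
}

# Block-structured expression matrix: `blocks` modules with within-block
# correlation via a shared latent factor, plus noise genes.
block_expression <- function(block_sizes, n_noise, n_samples, loading = 0.9,
                             seed = 42) {
  set.seed(seed)
  n <- sum(block_sizes) + n_noise
  lab <- rep(c(seq_along(block_sizes), 0),
             c(block_sizes, n_noise))
  x <- matrix(rnorm(n * n_samples), n, n_samples)
  for (b in seq_along(block_sizes)) {
    z <- rnorm(n_samples)
    idx <- which(lab == b)
    x[idx, ] <- loading * matrix(z, length(idx), n_samples, byrow = TRUE) +
      sqrt(1 - loading^2) * x[idx, , drop = FALSE]
  }
  rownames(x) <- sprintf("g%03d", seq_len(n))
  colnames(x) <- paste0("s", seq_len(n_samples))
  list(expr = x, modules = lab)
}

# Exhaustive hypergeometric upper-tail oracle by enumeration of all draws.
hyper_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Step-up BH oracle straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive O(n^3) TOM oracle.
tom_oracle <- function(a) {
  n <- nrow(a)
  ad <- a
  diag(ad) <- 0
  k <- rowSums(ad)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
        next
      }
      num <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + ad[i, u] * ad[u, j]
      }
      tom[i, j] <- (num + ad[i, j]) / (min(k[i], k[j]) + 1 - ad[i, j])
    }
  }
  tom
}

# Adjusted Rand index (mclust's implementation, used as external oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
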