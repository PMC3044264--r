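# Shared fixtures and an independent ReliefF oracle. Everything is built in
# code at test time; no stored data.

# The 4-sample, 2-SNP dataset whose ReliefF weights are (+1, -1) at K = 1:
# SNP A separates the classes perfectly, SNP B separates within-class pairs.
toy4 <- function() {
  genotype_dataset(matrix(c(0L, 0L, 2L, 2L,
                            0L, 1L, 0L, 1L), nrow = 4),
                   labels = c(1L, 1L, 0L, 0L),
                   snp_names = c("A", "B"),
                   sample_ids = paste0("s", 1:4))
}

# Random valid dataset with a balanced-as-possible class split.
random_dataset <- function(m, n, seed, maf = 0.3) {
  set.seed(seed)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  g <- matrix(sample(0:2, m * n, replace = TRUE, prob = p), nrow = m)
  labels <- sample(rep(c(0L, 1L), c(m %/% 2L, m - m %/% 2L)))
  genotype_dataset(g, labels, snp_names = paste0("S", seq_len(n)),
                   sample_ids = paste0("s", seq_len(m)))
}

# Independent brute-force ReliefF: explicit loops, explicit sorts, no shared
# code with the package internals. Neighbour ties broken by current sample
# position, weights divided by M*K.
relieff_oracle <- function(dataset, K) {
  g <- dataset$genotypes
  lab <- dataset$labels
  m <- nrow(g)
  n <- ncol(g)
  d <- matrix(0L, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    d[a, b] <- sum(g[a, ] != g[b, ])
  }
  w <- numeric(n)
  for (i in seq_len(m)) {
    same <- setdiff(which(lab == lab[i]), i)
    other <- which(lab != lab[i])
    hits <- same[order(d[i, same], same)][seq_len(K)]
    misses <- other[order(d[i, other], other)][seq_len(K)]
    for (k in seq_len(K)) {
      for (j in seq_len(n)) {
        w[j] <- w[j] - (g[i, j] != g[hits[k], j]) / (m * K) +
          (g[i, j] != g[misses[k], j]) / (m * K)
      }
    }
  }
  setNames(w, dataset$snp_names)
}

# A dataset with no tie-flagged sample at this K, built by tie removal from
# a larger random dataset (used for exact order-invariance checks).
tie_free_dataset <- function(m, n, K, seed = 1) {
  ds <- random_dataset(max(m, 4L * (K + 1L)), n, seed)
  remove_tie_samples(ds, K = K, scope = "relieff", seed = seed)
}

# Small simulated epistasis dataset collection (shared across tests).
sim_collection <- function(n_datasets, h2, n_cases, n_controls, n_snps,
                           seed) {
  model <- make_penetrance_model(h2, seed = seed)
  lapply(seq_len(n_datasets), function(i)
    simulate_dataset(model, n_cases, n_controls, n_snps, seed = seed + i))
}
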