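# Stub core: weights assigned from a fixed table, independent of the data,
# so the removal schedule and composite ranking can be checked by hand.
fixed_core <- function(tbl) {
  function(dataset, gt, dist, snps) tbl[snps]
}

test_that("removal schedule conserves SNPs and uses floor(N/R) blocks", {
  for (cfg in list(c(20, 4), c(23, 5), c(10, 10), c(37, 7))) {
    n <- cfg[1]; r <- cfg[2]
    ds <- random_dataset(12, n, n + r)
    res <- turf_ranking(ds, core = fixed_core(seq_len(n)), R = r, K = 2)
    blocks <- lapply(res$trace, `[[`, "removed")
    sizes <- lengths(blocks)
    expect_equal(sizes[seq_len(r - 1)], rep(n %/% r, r - 1))
    expect_equal(sizes[r], 0L)
    removed <- unlist(blocks)
    expect_equal(anyDuplicated(removed), 0L)
    survivors <- names(res$trace[[r]]$weights)
    expect_setequal(c(removed, survivors), ds$snp_names)
    expect_setequal(res$ranking$ranks, seq_len(n))
  }
})

test_that("composite ranking equals single-pass order for a fixed core", {
  n <- 10
  ds <- random_dataset(10, n, 99)
  tbl <- setNames(c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6), ds$snp_names)
  res <- turf_ranking(ds, core = fixed_core(tbl), R = 10, K = 2)
  single <- weights_to_ranking(weight_vector(tbl, ds$snp_names))
  expect_equal(res$ranking$ranks[ds$snp_names], single$ranks[ds$snp_names])
  # one SNP removed per iteration, in ascending weight order
  removed <- unlist(lapply(res$trace, `[[`, "removed"))
  expect_equal(unname(tbl[removed]), unname(sort(tbl)[1:9]))
})

test_that("weight ties are removed highest-index-first", {
  n <- 6
  ds <- random_dataset(10, n, 7)
  tbl <- setNames(rep(0, n), ds$snp_names)
  res <- turf_ranking(ds, core = fixed_core(tbl), R = 3, K = 2)
  # 2 removed per iteration; all weights tied, so highest indices go first
  expect_equal(res$trace[[1]]$removed, ds$snp_names[c(6, 5)])
  expect_equal(res$trace[[2]]$removed, ds$snp_names[c(4, 3)])
  # final ranking: survivors (1,2) first, then blocks by removal iteration
  expect_equal(unname(res$ranking$ranks), c(1L, 2L, 3L, 4L, 5L, 6L))
})

test_that("dominated SNPs are removed no later than their dominators", {
  n <- 12
  ds <- random_dataset(10, n, 31)
  tbl <- setNames(seq_len(n), ds$snp_names)
  res <- turf_ranking(ds, core = fixed_core(tbl), R = 4, K = 2)
  it <- as.numeric(res$ranking$removal_iteration[ds$snp_names])
  it[it == 0] <- 999  # survivors outlast every removal iteration
  # SNP j has strictly larger weight than SNP i < j in every iteration
  expect_true(all(diff(it) >= 0))
})

test_that("constant SNPs are removed in the first iteration", {
  # ten perfectly class-separating SNPs (weight +1) and two constant SNPs
  # (weight 0): with floor(12/6) = 2 removed per pass, the constants go
  # first
  labels <- rep(c(0L, 1L), each = 8)
  g <- matrix(rep(2L * labels, 12), ncol = 12)
  g[, c(2, 9)] <- 1L
  ds <- genotype_dataset(g, labels, snp_names = paste0("S", 1:12))
  res <- turf_ranking(ds, core = "relieff", R = 6, K = 3)
  w1 <- res$trace[[1]]$weights
  expect_equal(unname(w1[c("S2", "S9")]), c(0, 0))
  expect_true(all(unname(w1[setdiff(names(w1), c("S2", "S9"))]) > 0))
  expect_setequal(res$trace[[1]]$removed, c("S2", "S9"))
})

test_that("SURFTuRF is invariant under sample-order permutation", {
  ds <- random_dataset(20, 12, 77)
  a <- surfturf_ranking(ds, R = 4)$ranking
  b <- surfturf_ranking(permute_samples(ds, 13), R = 4)$ranking
  expect_identical(a$ranks[ds$snp_names], b$ranks[ds$snp_names])
})

test_that("TuRF inherits order dependence from the first-K tie rule", {
  # duplicated samples guarantee distance ties
  base <- random_dataset(10, 30, 41)
  idx <- c(1, 1, 2, 2, 3:10)
  tied <- genotype_dataset(base$genotypes[idx, ], base$labels[idx],
                           snp_names = base$snp_names,
                           sample_ids = paste0("s", seq_along(idx)))
  r0 <- turf_ranking(tied, R = 3, K = 2)$ranking
  changed <- any(vapply(1:20, function(s) {
    rp <- turf_ranking(permute_samples(tied, s), R = 3, K = 2)$ranking
    !identical(rp$ranks[tied$snp_names], r0$ranks[tied$snp_names])
  }, logical(1)))
  expect_true(changed)
})

test_that("TuRF rejects undersized problems", {
  ds <- random_dataset(10, 5, 3)
  expect_error(turf_ranking(ds, R = 6, K = 2), "fewer than R")
  expect_error(turf_ranking(ds, R = 1, K = 2), "at least 2")
})
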