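test_that("genotype difference is 0/1, symmetric, equality-based", {
  codes <- expand.grid(a = 0:2, b = 0:2)
  expect_equal(genotype_diff(codes$a, codes$b),
               as.integer(codes$a != codes$b))
  expect_equal(genotype_diff(codes$a, codes$b),
               genotype_diff(codes$b, codes$a))
})

test_that("sample distance is the Hamming distance over the SNP subset", {
  ds <- random_dataset(5, 4, 3)
  expect_equal(sample_distance(ds, 2, 2), 0)
  # brute-force pairwise comparison
  D <- distance_matrix(ds)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), rep(0L, 5))
  for (a in 1:5) for (b in 1:5)
    expect_equal(D[a, b], sum(ds$genotypes[a, ] != ds$genotypes[b, ]))
  # subset recomputation equals matrix on the reduced subset
  sub <- c(1L, 3L)
  D2 <- distance_matrix(ds, sub)
  expect_equal(D2[2, 4], sample_distance(ds, 2, 4, sub))
  expect_true(all(D2 <= length(sub)))
  expect_error(distance_matrix(ds, integer(0)), "non-empty")
})

test_that("neighbour selection follows the first-K rule and flags ties", {
  # 4-sample toy: from s1, hit side s2 at 1; miss side s3 at 1, s4 at 2
  ds <- toy4()
  D <- distance_matrix(ds)
  nb <- find_neighbors(D[1, ], ds$labels, 1, K = 1)
  expect_equal(nb$hits, 2L)
  expect_equal(nb$misses, 3L)
  expect_false(nb$tie_flag)

  # three same-class candidates all at distance 2, K = 2: first two chosen,
  # tie flagged, and permuting the order changes the chosen set
  labels <- c(1L, 1L, 1L, 1L, 0L, 0L)
  drow <- c(0, 2, 2, 2, 1, 3)
  nb2 <- find_neighbors(drow, labels, 1, K = 2)
  expect_equal(nb2$hits, c(2L, 3L))
  expect_true(nb2$tie_hit)
  # same geometry with candidate positions swapped
  perm <- c(1L, 4L, 3L, 2L, 5L, 6L)
  nb3 <- find_neighbors(drow[perm], labels[perm], 1, K = 2)
  expect_equal(nb3$hits, c(2L, 3L))  # positions 2,3 now hold other samples
  expect_true(nb3$tie_hit)

  # exhaustion: K = class size - 1 with distinct distances, no tie
  labels4 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  drow4 <- c(0, 1, 2, 1, 2, 3)
  nb4 <- find_neighbors(drow4, labels4, 1, K = 2)
  expect_equal(nb4$hits, c(2L, 3L))
  expect_false(nb4$tie_flag)
  expect_error(find_neighbors(drow4, labels4, 1, K = 3), "class")
})

test_that("ReliefF reproduces the hand-traced toy weights", {
  w <- relieff_weights(toy4(), K = 1)
  expect_equal(unname(w$weights), c(1, -1))
  expect_equal(w$meta$family, "relieff")
})

test_that("a constant SNP always gets weight zero", {
  ds <- random_dataset(20, 5, 7)
  g <- ds$genotypes
  g[, 3] <- 1L
  ds2 <- genotype_dataset(g, ds$labels)
  expect_equal(unname(relieff_weights(ds2, K = 3)$weights[3]), 0)
  expect_equal(unname(surf_weights(ds2)$weights[3]), 0)
})

test_that("ReliefF weights stay in [-1, 1] on random datasets", {
  for (seed in 1:200) {
    m <- sample(8:24, 1)
    ds <- random_dataset(m, sample(2:6, 1), seed)
    k <- min(tabulate(ds$labels + 1L, 2L)) - 1L
    if (k < 1L) next
    w <- relieff_weights(ds, K = min(k, 3L))$weights
    expect_true(all(abs(w) <= 1))
  }
})

test_that("ReliefF matches the brute-force oracle on small instances", {
  for (seed in 1:40) {
    set.seed(seed)
    m <- sample(4:8, 1)
    n <- sample(1:4, 1)
    ds <- random_dataset(m, n, seed * 13)
    k <- min(tabulate(ds$labels + 1L, 2L)) - 1L
    if (k < 1L) next
    k <- sample(seq_len(min(k, 3L)), 1)
    expect_equal(unname(relieff_weights(ds, K = k)$weights),
                 unname(relieff_oracle(ds, k)), tolerance = 1e-12)
  }
})

test_that("sample-order invariance holds iff no neighbour tie occurs", {
  # tie-free fixture: permuted runs give bit-identical weights
  ds <- tie_free_dataset(14, 40, K = 2)
  w0 <- relieff_weights(ds, K = 2)
  wp <- relieff_weights(permute_samples(ds, 9), K = 2)
  expect_identical(sort(w0$weights), sort(wp$weights))

  # constructed tie: duplicated samples force ties and order dependence
  set.seed(5)
  base <- random_dataset(8, 6, 21)
  g <- base$genotypes[c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8), ]
  tied <- genotype_dataset(g, base$labels[c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8)],
                           sample_ids = paste0("s", 1:10))
  wt <- relieff_weights(tied, K = 2)
  expect_gt(length(attr(wt, "tie_samples")), 0)
  diffs <- vapply(1:30, function(s) {
    wq <- relieff_weights(permute_samples(tied, s), K = 2)
    max(abs(sort(wq$weights) - sort(wt$weights)))
  }, numeric(1))
  expect_gt(max(diffs), 0)
})

test_that("SURF neighbours are threshold-based and order-invariant", {
  ds <- toy4()
  D <- distance_matrix(ds)
  # threshold below the minimum pairwise distance: empty
  nb <- surf_neighbors(D, ds$labels, 1, threshold = 0.5)
  expect_length(nb$hits, 0)
  expect_length(nb$misses, 0)
  # threshold above the maximum: everything
  nb2 <- surf_neighbors(D, ds$labels, 1, threshold = 10)
  expect_setequal(c(nb2$hits, nb2$misses), 2:4)

  # toy with threshold 1.5 reproduces the K = 1 neighbour sets and weights
  w <- surf_weights(ds, threshold = 1.5)
  expect_equal(unname(w$weights), c(1, -1))

  # order invariance on a random dataset
  ds2 <- random_dataset(16, 10, 11)
  w1 <- surf_weights(ds2)
  w2 <- surf_weights(permute_samples(ds2, 3))
  expect_equal(sort(w1$weights), sort(w2$weights), tolerance = 1e-12)
  expect_true(all(abs(w1$weights) <= 1))
})

test_that("class size preconditions are enforced with informative errors", {
  ds <- random_dataset(12, 5, 2)
  expect_error(relieff_weights(ds, K = 12), "more than K")
  expect_error(relieff_weights(ds, K = min(tabulate(ds$labels + 1L, 2L))),
               "more than K")
})
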