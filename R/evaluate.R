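#' Pearson correlation between two SNP rankings
#'
#' Stability measure for a filter: run it twice under different sample
#' orders and correlate the two rank vectors. Ranks are log10-transformed
#' by default, which emphasises agreement among the top-ranked SNPs (the
#' ones filtering actually keeps); raw-rank correlation is available with
#' `log10_transform = FALSE`. An order-invariant filter gives exactly 1.
#'
#' @param r1,r2 [snp_ranking] objects over the same SNP set.
#' @param log10_transform correlate `log10(rank)` instead of raw ranks.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
rank_correlation <- function(r1, r2, log10_transform = TRUE) {
  stopifnot(inherits(r1, "snp_ranking"), inherits(r2, "snp_ranking"))
  if (!setequal(r1$snp_names, r2$snp_names))
    stop("rankings cover different SNP sets")
  a <- as.numeric(r1$ranks[r1$snp_names])
  b <- as.numeric(r2$ranks[r1$snp_names])
  if (log10_transform) {
    a <- log10(a)
    b <- log10(b)
  }
  cor(a, b)
}

#' Detect samples whose k-NN neighbour selection is tied
#'
#' A sample is tie-causing when, on the full-dataset distance matrix, more
#' than K same-class (or more than K other-class) candidates lie at or
#' within the distance of its K-th hit (miss) neighbour: any rule that
#' forces exactly K neighbours must then make an arbitrary, order-dependent
#' choice. These samples are the entire source of ReliefF's sample-order
#' dependence.
#'
#' @param dataset a [genotype_dataset].
#' @param K neighbours per side (default 10).
#' @return Character vector of tie-causing `sample_ids` (possibly empty).
#' @export
find_tie_causing_samples <- function(dataset, K = 10L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  check_classes_for_k(dataset$labels, K)
  w <- relieff_weights(dataset, K = K)
  attr(w, "tie_samples")
}

# Tie-flagged sample ids for a sample subset, under either tie scope.
# `dist` is the full-dataset distance matrix (sample removal does not change
# pairwise distances, so the subset's matrix is just a submatrix).
scan_tie_ids <- function(dataset, keep, K, scope, R, dist) {
  sub <- subset_samples(dataset, keep)
  if (scope == "relieff") {
    res <- .relieff_core_cpp(t(sub$genotypes), dist[keep, keep, drop = FALSE],
                             sub$labels, as.integer(K),
                             seq_along(keep) - 1L)
    sub$sample_ids[res$tie_hit | res$tie_miss]
  } else {
    tr <- turf_ranking(sub, core = "relieff", R = R, K = K,
                       dist = dist[keep, keep, drop = FALSE])
    unique(unlist(lapply(tr$trace, `[[`, "tie_samples")))
  }
}

# Count of tied (target, side, iteration) events for a subset, plus a
# per-kept-sample participation tally used to direct the subset search.
count_ties <- function(dataset, keep, K, scope, R, dist) {
  if (scope == "relieff") {
    sub_labels <- dataset$labels[keep]
    res <- .relieff_core_cpp(t(dataset$genotypes[keep, , drop = FALSE]),
                             dist[keep, keep, drop = FALSE],
                             sub_labels, as.integer(K),
                             seq_along(keep) - 1L)
    flagged <- res$tie_hit | res$tie_miss
    list(n = sum(res$tie_hit) + sum(res$tie_miss),
         part = as.integer(flagged))
  } else {
    res <- .turf_tie_count_cpp(t(dataset$genotypes[keep, , drop = FALSE]),
                               dataset$labels[keep], as.integer(K),
                               as.integer(R))
    list(n = res$ties, part = res$participation)
  }
}

#' Remove tie-causing samples until none remain
#'
#' Produces a subset of the samples on which the k-NN neighbour selection is
#' free of ties, so that ReliefF (and, with `scope = "turf"`, TuRF) becomes
#' exactly sample-order invariant: bit-identical weights under permutation.
#' This is a diagnostic for the origin of the order dependence, not a fix --
#' on realistic SNP data it must discard most samples, destroying power.
#'
#' The procedure first iterates [find_tie_causing_samples] and blanket
#' removal (removing samples changes the candidate neighbour sets and can
#' create new ties, so a single pass is not enough). On data where ties are
#' pervasive that cascade would exhaust a class, so when the next blanket
#' round would leave a class with fewer than `K + 1` samples the procedure
#' switches to a seeded simulated-annealing search for a tie-free subset
#' with exactly `K + 1` samples per class -- the most favourable size, since
#' a class of `K + 1` gives each same-class target exactly `K` hit
#' candidates (a forced, tie-free choice) and each opposite-class target
#' `K + 1` miss candidates (tied only when the two farthest are equidistant).
#'
#' With `scope = "turf"` the tie scan covers every iteration of the TuRF
#' path: TuRF recomputes distances on each surviving SNP subset, so a
#' dataset that is tie-free on the full SNP set can still be tied on a
#' reduced one. At the fixed point the canonical TuRF run raises no tie
#' anywhere, making TuRF itself exactly order invariant.
#'
#' @param dataset a [genotype_dataset].
#' @param K neighbours per side.
#' @param scope `"relieff"` (full-SNP-set ties only, default) or `"turf"`
#'   (ties anywhere along the TuRF path).
#' @param R TuRF iterations when `scope = "turf"`.
#' @param seed seed for the annealing phase (which is otherwise
#'   deterministic given the dataset).
#' @param max_rounds bound on blanket-removal rounds.
#' @param anneal_evals move budget for the annealing phase.
#' @return A tie-free [genotype_dataset]; attribute `removed_samples` lists
#'   the discarded sample ids.
#' @export
remove_tie_samples <- function(dataset, K = 10L, scope = c("relieff", "turf"),
                               R = 10L, seed = 1L, max_rounds = 100L,
                               anneal_evals = 200000L) {
  scope <- match.arg(scope)
  stopifnot(inherits(dataset, "genotype_dataset"))
  labels <- dataset$labels
  if (any(tabulate(labels + 1L, 2L) <= K))
    stop("both classes need more than K = ", K, " samples")
  dist <- distance_matrix(dataset)
  keep <- seq_len(n_samples(dataset))

  finish <- function(keep) {
    out <- subset_samples(dataset, sort(keep))
    attr(out, "removed_samples") <-
      setdiff(dataset$sample_ids, dataset$sample_ids[keep])
    out
  }

  # Phase 1: blanket removal of all tie-flagged samples, while safe.
  for (round in seq_len(max_rounds)) {
    ties <- scan_tie_ids(dataset, keep, K, scope, R, dist)
    if (length(ties) == 0L) return(finish(keep))
    prospective <- keep[!(dataset$sample_ids[keep] %in% ties)]
    if (any(tabulate(labels[prospective] + 1L, 2L) < K + 1L)) break
    keep <- prospective
  }

  # Phase 2: annealing at K + 1 samples per class.
  pool0 <- which(labels == 0L)
  pool1 <- which(labels == 1L)
  with_seed(seed, {
    cur_keep <- c(sample(intersect(keep, pool0), K + 1L),
                  sample(intersect(keep, pool1), K + 1L))
    state <- count_ties(dataset, cur_keep, K, scope, R, dist)
    best <- state$n
    ev <- 0L
    while (state$n > 0L && ev < anneal_evals) {
      ev <- ev + 1L
      # focused move: swap out a sample participating in a tie; occasionally
      # a random one to escape local structure
      out_idx <- if (runif(1) < 0.85 && sum(state$part) > 0) {
        sample(seq_along(cur_keep), 1L, prob = state$part + 0.01)
      } else {
        sample(seq_along(cur_keep), 1L)
      }
      sw_out <- cur_keep[out_idx]
      pool <- setdiff(if (labels[sw_out] == 0L) pool0 else pool1, cur_keep)
      cand <- c(cur_keep[-out_idx], sample(pool, 1L))
      v <- count_ties(dataset, cand, K, scope, R, dist)
      if (v$n <= state$n || runif(1) < exp(-(v$n - state$n) / 0.4)) {
        cur_keep <- cand
        state <- v
        best <- min(best, state$n)
      }
    }
    if (state$n > 0L)
      stop("no tie-free sample subset found within ", anneal_evals,
           " search moves (best residual: ", best,
           " tied neighbourhoods); increase anneal_evals")
    keep <- cur_keep
  })
  finish(keep)
}

#' Number of top SNPs at a ranking percentile
#'
#' Percentile `q` of an N-SNP ranking keeps the top `round(N * q / 100)`
#' SNPs: percentile 1 of 1000 SNPs is the top 10, percentile 10 the top 100.
#'
#' @param n_snps total number of SNPs.
#' @param percentile integer in `1..100`.
#' @return Integer cutoff.
#' @export
percentile_cutoff <- function(n_snps, percentile) {
  if (any(percentile < 1L) || any(percentile > 100L))
    stop("percentile must be in 1..100")
  as.integer(round(n_snps * percentile / 100))
}

#' Success rate of retaining a functional SNP pair
#'
#' Over a collection of per-dataset rankings, the percentage of datasets in
#' which *both* SNPs of the functional pair rank within the percentile
#' cutoff. Retaining only one member of an interacting pair is useless for
#' downstream pairwise analysis, so the pair counts only as a unit.
#'
#' @param rankings list of [snp_ranking], one per dataset.
#' @param functional_pair two SNP names (default `c("X0", "X1")`).
#' @param percentile percentile defining the retained subset.
#' @return Success rate in percent (0-100).
#' @export
success_rate <- function(rankings, functional_pair = c("X0", "X1"),
                         percentile) {
  stopifnot(length(functional_pair) == 2L, length(rankings) >= 1L)
  hits <- vapply(rankings, function(r) {
    if (!all(functional_pair %in% r$snp_names))
      stop("functional pair ", paste(functional_pair, collapse = "/"),
           " missing from a ranking")
    cut <- percentile_cutoff(length(r$ranks), percentile)
    max(r$ranks[functional_pair]) <= cut
  }, logical(1))
  100 * mean(hits)
}

#' Success-rate curve over percentiles 1..50
#'
#' @inheritParams success_rate
#' @param percentiles percentile grid (default `1:50`).
#' @return Object of class `success_curve`: data frame with `percentile`
#'   and `success` plus attribute `acsr`, the average cumulative success
#'   rate (mean of the curve).
#' @export
success_curve <- function(rankings, functional_pair = c("X0", "X1"),
                          percentiles = 1:50) {
  success <- vapply(percentiles, function(q)
    success_rate(rankings, functional_pair, q), numeric(1))
  out <- data.frame(percentile = percentiles, success = success)
  class(out) <- c("success_curve", "data.frame")
  attr(out, "acsr") <- mean(success)
  out
}

#' Average cumulative success rate (ACSR)
#'
#' Mean of the success rates from percentile 1 to 50 -- the single-number
#' summary used to compare filters.
#'
#' @param curve a [success_curve] over percentiles 1..50.
#' @return ACSR in percent.
#' @export
avg_cumulative_success <- function(curve) {
  stopifnot(inherits(curve, "success_curve"))
  if (!identical(as.integer(curve$percentile), 1:50))
    stop("ACSR is defined over the complete percentile grid 1..50")
  mean(curve$success)
}

#' Stability as a function of ensemble size
#'
#' For each candidate ensemble size L, runs the ensemble filter twice with
#' different master seeds and records the rank correlation of the two final
#' rankings. Stability typically rises with L and plateaus around 40.
#'
#' @param dataset a [genotype_dataset].
#' @param base base filter, `"relieff"` or `"turf"`.
#' @param sizes ensemble sizes to test (default `c(10, 20, 30, 40, 50)`).
#' @param seeds two master seeds.
#' @param K,R base filter parameters.
#' @param log10_transform passed to [rank_correlation].
#' @return Data frame with columns `size` and `r`.
#' @export
ensemble_size_sweep <- function(dataset, base = "turf",
                                sizes = c(10L, 20L, 30L, 40L, 50L),
                                seeds = c(1L, 2L), K = 10L, R = 10L,
                                log10_transform = TRUE) {
  stopifnot(length(seeds) == 2L)
  r <- vapply(sizes, function(L) {
    e1 <- ensemble_filter(dataset, base = base, L = L, K = K, R = R,
                          master_seed = seeds[1L])
    e2 <- ensemble_filter(dataset, base = base, L = L, K = K, R = R,
                          master_seed = seeds[2L])
    rank_correlation(e1$final_ranking, e2$final_ranking, log10_transform)
  }, numeric(1))
  data.frame(size = as.integer(sizes), r = r)
}
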