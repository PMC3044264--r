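#' Tuned ReliefF (TuRF) iterative SNP ranking
#'
#' Runs a ReliefF-family core filter `R` times, discarding the
#' `floor(N/R)` lowest-weighted SNPs after each of the first `R - 1`
#' scoring passes so that later passes see an improved signal-to-noise
#' ratio; distances are recomputed on the surviving SNP subset every
#' iteration. With N = 1000 and R = 10 this removes 100 SNPs per iteration
#' and scores the final 100 survivors in the last pass.
#'
#' Two conventions are provided for ranking the SNPs that did not survive
#' to the last pass. The default composite (`"blocked"`) places survivors
#' first, ordered by their last-iteration weights, followed by the removed
#' SNPs in blocks by removal iteration (later removal = better), ordered
#' within each block by their weight at removal: surviving longer is itself
#' treated as evidence. The `"last_estimate"` composite ranks every SNP
#' directly by its last computed weight (final weight for survivors, weight
#' at removal otherwise), mixing weights from different iterations; it
#' penalises removed SNPs more mildly, which matters when many rankings are
#' averaged (see [ensemble_filter]). Weight ties are always broken by
#' ascending SNP index for ranking and, mirror-image, by descending index
#' for removal, so the whole procedure is deterministic given a sample
#' order.
#'
#' @param dataset a [genotype_dataset].
#' @param core `"relieff"` (default), `"surf"`, or a function
#'   `f(dataset, gt, dist, snps)` returning a numeric weight per surviving
#'   SNP (in `snps` order) -- the plug-in interface used by SURFTuRF and by
#'   tests.
#' @param R number of iterations (default 10); requires `N >= R`.
#' @param K neighbours per side for the ReliefF core.
#' @param dist optional precomputed full-SNP-set distance matrix for this
#'   dataset; later iterations always derive their subset distances
#'   incrementally from it.
#' @param composite `"blocked"` (default) or `"last_estimate"`; see above.
#' @return List with `ranking` (the composite [snp_ranking], with
#'   `removal_iteration` bookkeeping) and `trace` (class `turf_trace`): one
#'   entry per iteration holding the surviving SNP weights, the names
#'   removed after that iteration, and the ids of tie-flagged samples.
#' @export
turf_ranking <- function(dataset, core = "relieff", R = 10L, K = 10L,
                         dist = NULL,
                         composite = c("blocked", "last_estimate")) {
  composite <- match.arg(composite)
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- n_snps(dataset)
  if (R < 2L) stop("R must be at least 2")
  if (n < R) stop("N = ", n, " SNPs is fewer than R = ", R, " iterations")
  core_fun <- turf_core_fun(core, K)
  if (identical(core, "relieff")) check_classes_for_k(dataset$labels, K)

  gt_full <- t(dataset$genotypes)
  if (is.null(dist)) dist <- .hamming_dist_cpp(gt_full)
  surviving <- seq_len(n)
  n_remove <- n %/% R
  trace <- vector("list", R)
  removal_iter <- integer(n)
  removal_weight <- numeric(n)

  for (iter in seq_len(R)) {
    gt <- gt_full[surviving, , drop = FALSE]
    w <- core_fun(dataset, gt, dist, surviving)
    trace[[iter]] <- list(weights = setNames(w$weights, dataset$snp_names[surviving]),
                          removed = character(0),
                          tie_samples = w$tie_samples)
    if (iter < R) {
      # lowest weight removed first; among equal weights the higher SNP
      # index goes first (the mirror of the ranking tie rule)
      ord <- order(w$weights, -surviving)
      drop_local <- ord[seq_len(n_remove)]
      dropped <- surviving[drop_local]
      removal_iter[dropped] <- iter
      removal_weight[dropped] <- w$weights[drop_local]
      trace[[iter]]$removed <- dataset$snp_names[dropped]
      dist <- dist - .hamming_dist_cpp(gt_full[dropped, , drop = FALSE])
      surviving <- surviving[-drop_local]
    }
  }

  final_w <- trace[[R]]$weights
  removal_weight[surviving] <- final_w
  ranking <- turf_composite_ranking(dataset$snp_names, surviving,
                                    removal_iter, removal_weight, composite,
                                    meta = list(filter = if (is.character(core))
                                      paste0(core, "-turf") else "turf",
                                      R = R, K = K, composite = composite))
  structure(list(ranking = ranking,
                 trace = structure(trace, class = "turf_trace", R = R)),
            class = "turf_result")
}

turf_core_fun <- function(core, K) {
  if (is.function(core)) {
    function(dataset, gt, dist, snps) {
      w <- core(dataset, gt, dist, snps)
      list(weights = as.numeric(w), tie_samples = character(0))
    }
  } else if (identical(core, "relieff")) {
    function(dataset, gt, dist, snps) {
      w <- relieff_weights_from_dist(dataset, gt, dist, K)
      list(weights = unname(w$weights), tie_samples = attr(w, "tie_samples"))
    }
  } else if (identical(core, "surf")) {
    function(dataset, gt, dist, snps) {
      w <- surf_weights_from_dist(dataset, gt, dist, threshold = NULL)
      list(weights = unname(w$weights), tie_samples = character(0))
    }
  } else stop("unknown TuRF core: ", core)
}

# Build the composite ranking. "blocked": survivors first by final weight,
# removed SNPs after, blocked by removal iteration (later = better), within
# a block by weight at removal. "last_estimate": everything by its last
# computed weight. All weight ties by ascending SNP index.
turf_composite_ranking <- function(snp_names, surviving, removal_iter,
                                   removal_weight, composite, meta) {
  n <- length(snp_names)
  if (composite == "blocked") {
    survived <- seq_len(n) %in% surviving
    # sort key: survivors (removal_iter 0 treated as +Inf block), then weight
    block <- ifelse(survived, Inf, removal_iter)
    ord <- order(-block, -removal_weight, seq_len(n))
  } else {
    ord <- order(-removal_weight, seq_len(n))
  }
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  snp_ranking(ranks, snp_names, removal_iteration = removal_iter, meta = meta)
}

#' @export
print.turf_result <- function(x, ...) {
  cat(sprintf("turf_result (%s): %d iterations over %d SNPs\n",
              x$ranking$meta$filter, attr(x$trace, "R"),
              length(x$ranking$ranks)))
  invisible(x)
}

#' SURFTuRF: TuRF with the SURF threshold-neighbour core
#'
#' Identical removal schedule to [turf_ranking] but each iteration scores the
#' surviving SNPs with [surf_weights]; the distance threshold (mean pairwise
#' distance) is recomputed on the surviving subset every iteration. Because
#' the SURF core has no forced-K tie-breaking, the composite ranking is
#' invariant under sample-order permutation.
#'
#' @param dataset a [genotype_dataset].
#' @param R number of iterations (default 10).
#' @return As [turf_ranking].
#' @export
surfturf_ranking <- function(dataset, R = 10L) {
  turf_ranking(dataset, core = "surf", R = R)
}

# Reconstruct a full-length ranking as it stood at iteration `iter`:
# SNPs alive at that iteration ranked by its weights, earlier-removed SNPs
# blocked below exactly as in the composite rule. Used by the
# per-iteration aggregation mode of TuRF-E.
turf_iteration_rankings <- function(dataset_snp_names, turf_res) {
  trace <- turf_res$trace
  R <- attr(trace, "R")
  n <- length(dataset_snp_names)
  idx <- setNames(seq_len(n), dataset_snp_names)
  removal_iter <- integer(n)
  removal_weight <- numeric(n)
  out <- vector("list", R)
  for (iter in seq_len(R)) {
    w <- trace[[iter]]$weights
    alive <- idx[names(w)]
    block <- rep(-Inf, n)
    key_w <- removal_weight
    block[alive] <- Inf
    key_w[alive] <- w
    if (iter > 1L) {
      prev <- removal_iter > 0L
      block[prev] <- removal_iter[prev]
    }
    ord <- order(-block, -key_w, seq_len(n))
    ranks <- integer(n)
    ranks[ord] <- seq_len(n)
    out[[iter]] <- snp_ranking(ranks, dataset_snp_names,
                               meta = list(filter = "turf-iteration",
                                           iteration = iter))
    rem <- idx[trace[[iter]]$removed]
    if (length(rem)) {
      removal_iter[rem] <- iter
      removal_weight[rem] <- w[match(dataset_snp_names[rem], names(w))]
    }
  }
  out
}
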