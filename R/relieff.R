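#' Genotype difference between two samples at one SNP
#'
#' The categorical difference function: 0 when the genotype codes are equal,
#' 1 otherwise. Any recoding of the three genotype classes leaves it
#' unchanged, which is why the `{0,1,2}` coding is purely conventional.
#'
#' @param a,b genotype codes (vectors are compared elementwise).
#' @return Integer 0/1 vector.
#' @export
genotype_diff <- function(a, b) as.integer(a != b)

#' Hamming distance between two samples over a SNP subset
#'
#' The sample distance used by all ReliefF-family filters: the number of
#' SNPs in `snps` at which the two samples' genotypes differ.
#'
#' @param dataset a [genotype_dataset].
#' @param a,b sample indices (row numbers).
#' @param snps SNP index subset; all SNPs by default.
#' @return Non-negative integer.
#' @export
sample_distance <- function(dataset, a, b, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(snps)) snps <- seq_len(n_snps(dataset))
  if (length(snps) == 0L) stop("SNP subset must be non-empty")
  sum(genotype_diff(dataset$genotypes[a, snps], dataset$genotypes[b, snps]))
}

#' Pairwise sample distance matrix
#'
#' @param dataset a [genotype_dataset].
#' @param snps SNP index subset over which distances are summed; all SNPs by
#'   default. TuRF recomputes this on the surviving subset each iteration.
#' @return Symmetric M x M integer matrix with zero diagonal.
#' @export
distance_matrix <- function(dataset, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(snps)) snps <- seq_len(n_snps(dataset))
  if (length(snps) == 0L) stop("SNP subset must be non-empty")
  .hamming_dist_cpp(t(dataset$genotypes[, snps, drop = FALSE]))
}

#' k-nearest hit and miss neighbours of a target sample
#'
#' Selects the K nearest same-class ("hit") and K nearest other-class
#' ("miss") samples by distance, excluding the target itself. Distance ties
#' are broken by smallest current sample position (the "first-K" rule); this
#' deliberately reproduces the sample-order dependence of the classic
#' implementation. A side is flagged as tied when more than K candidates
#' have a distance equal to or less than that of the K-th neighbour, i.e.
#' when the forced choice of exactly K is not determined by the distances.
#'
#' @param dist_row integer vector of distances from the target to every
#'   sample (`dist_row[target]` is ignored).
#' @param labels class vector.
#' @param target target sample index.
#' @param K number of neighbours per side.
#' @return List with `hits`, `misses` (each K sample indices in selection
#'   order), `tie_hit`, `tie_miss`, and `tie_flag = tie_hit || tie_miss`.
#' @export
find_neighbors <- function(dist_row, labels, target, K) {
  m <- length(labels)
  stopifnot(length(dist_row) == m, target >= 1L, target <= m)
  pick <- function(cand) {
    ord <- cand[order(dist_row[cand], cand)]
    sel <- ord[seq_len(K)]
    dk <- dist_row[sel[K]]
    list(sel = sel, tie = sum(dist_row[cand] <= dk) > K)
  }
  same <- setdiff(which(labels == labels[target]), target)
  other <- which(labels != labels[target])
  if (length(same) < K)
    stop("class ", labels[target], " has ", length(same) + 1L,
         " samples; needs more than K = ", K)
  if (length(other) < K)
    stop("class ", 1L - labels[target], " has ", length(other),
         " samples; needs at least K = ", K)
  h <- pick(same)
  m_ <- pick(other)
  list(hits = h$sel, misses = m_$sel,
       tie_hit = h$tie, tie_miss = m_$tie,
       tie_flag = h$tie || m_$tie)
}

# Shared precondition check for K-NN filters.
check_classes_for_k <- function(labels, K) {
  sizes <- tabulate(labels + 1L, 2L)
  if (any(sizes <= K))
    stop("class ", which.min(sizes) - 1L, " has ", min(sizes),
         " samples; ReliefF with K = ", K,
         " needs more than K samples in each class")
}

#' ReliefF SNP weights
#'
#' Estimates a weight in `[-1, 1]` for each SNP by contrasting, for every
#' sample, its genotype with those of its K nearest hits and misses: a SNP
#' is rewarded when it separates a sample from its misses and penalised when
#' it separates it from its hits. Samples are evaluated exhaustively in the
#' dataset's current presentation order; with K neighbours per side each of
#' the M*K hit/miss updates is divided by M*K, which keeps the weights in
#' `[-1, 1]` (the single-neighbour form divides by M alone). The rescaling
#' by K is rank-preserving, so rankings are unaffected by this convention.
#'
#' @param dataset a [genotype_dataset]; both classes must have more than K
#'   samples.
#' @param K neighbours per side (default 10, the standard setting).
#' @param sample_size optional number of target samples to evaluate instead
#'   of all M (random selection; weights are then divided by
#'   `sample_size * K`). Exhaustive evaluation is the default and is what
#'   every reported result uses.
#' @param seed seed for the random target selection (required with
#'   `sample_size`).
#' @param dist optional precomputed full-SNP-set distance matrix for this
#'   dataset (see [distance_matrix]); computed when `NULL`.
#' @return A [weight_vector] with `meta$family = "relieff"`. Attribute
#'   `tie_samples` lists sample ids whose neighbour selection was tied.
#' @examples
#' g <- matrix(c(0L, 0L, 2L, 2L, 0L, 1L, 0L, 1L), nrow = 4)
#' d <- genotype_dataset(g, c(1L, 1L, 0L, 0L), snp_names = c("A", "B"))
#' relieff_weights(d, K = 1)$weights  # A = +1, B = -1
#' @export
relieff_weights <- function(dataset, K = 10L, sample_size = NULL, seed = NULL,
                            dist = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  check_classes_for_k(dataset$labels, K)
  gt <- t(dataset$genotypes)
  if (is.null(dist)) dist <- .hamming_dist_cpp(gt)
  relieff_weights_from_dist(dataset, gt, dist, K, sample_size, seed)
}

# Core shared with TuRF so distance matrices can be updated incrementally.
relieff_weights_from_dist <- function(dataset, gt, dist, K, sample_size = NULL,
                                      seed = NULL, snp_names = rownames(gt)) {
  m <- ncol(gt)
  targets <- if (is.null(sample_size)) {
    seq_len(m) - 1L
  } else {
    if (is.null(seed)) stop("random sample selection requires a seed")
    with_seed(seed, sample.int(m, sample_size)) - 1L
  }
  res <- .relieff_core_cpp(gt, dist, as.integer(dataset$labels), as.integer(K),
                           targets)
  if (is.null(snp_names)) snp_names <- dataset$snp_names
  w <- weight_vector(res$weights, snp_names,
                     meta = list(filter = "relieff", family = "relieff", K = K))
  attr(w, "tie_hit") <- res$tie_hit
  attr(w, "tie_miss") <- res$tie_miss
  attr(w, "tie_samples") <- dataset$sample_ids[res$tie_hit | res$tie_miss]
  w
}

#' Threshold neighbours of a target sample (SURF rule)
#'
#' All non-target samples strictly within a distance threshold of the target
#' are neighbours; there is no forced count, so no tie-breaking is needed and
#' the neighbour sets are invariant under sample-order permutation.
#'
#' @param dist_matrix M x M distance matrix.
#' @param labels class vector.
#' @param target target sample index.
#' @param threshold positive distance threshold.
#' @return List with `hits` and `misses` (possibly empty index vectors).
#' @export
surf_neighbors <- function(dist_matrix, labels, target, threshold) {
  stopifnot(threshold > 0)
  d <- dist_matrix[target, ]
  near <- setdiff(which(d < threshold), target)
  list(hits = near[labels[near] == labels[target]],
       misses = near[labels[near] != labels[target]])
}

#' SURF SNP weights
#'
#' ReliefF-style updates over all threshold neighbours instead of a forced
#' K. The default threshold is the mean of all off-diagonal pairwise
#' distances (the published SURF rule). Hit- and miss-side updates for each
#' sample are normalised by that sample's own hit/miss neighbour counts (and
#' by M), keeping weights in `[-1, 1]`; samples with no neighbours on a side
#' contribute nothing on that side.
#'
#' @param dataset a [genotype_dataset].
#' @param threshold distance threshold; `NULL` (default) uses the mean
#'   pairwise distance.
#' @return A [weight_vector] with `meta$family = "relieff"`.
#' @export
surf_weights <- function(dataset, threshold = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  gt <- t(dataset$genotypes)
  d <- .hamming_dist_cpp(gt)
  surf_weights_from_dist(dataset, gt, d, threshold)
}

surf_weights_from_dist <- function(dataset, gt, dist, threshold = NULL,
                                   snp_names = rownames(gt)) {
  m <- ncol(gt)
  if (is.null(threshold)) threshold <- sum(dist) / (m * (m - 1))
  w <- .surf_core_cpp(gt, dist, as.integer(dataset$labels), threshold)
  if (is.null(snp_names)) snp_names <- dataset$snp_names
  weight_vector(w, snp_names,
                meta = list(filter = "surf", family = "relieff",
                            threshold = threshold))
}
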