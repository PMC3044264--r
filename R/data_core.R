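#' Case-control SNP genotype dataset
#'
#' Container for a case-control genotype matrix in minor-allele-count coding.
#' Sample presentation order is explicit and meaningful: the ReliefF-family
#' filters evaluate samples in this order, and their k-nearest-neighbour
#' tie-breaking makes results depend on it.
#'
#' @param genotypes integer matrix, M samples x N SNPs, entries in `{0, 1, 2}`
#'   (count of minor alleles).
#' @param labels integer vector of length M, `0` = control, `1` = case.
#' @param snp_names character vector of N unique SNP identifiers; defaults to
#'   `colnames(genotypes)`.
#' @param sample_ids character vector of M identifiers recording the current
#'   presentation order; defaults to `rownames(genotypes)` or `s1..sM`.
#' @return An object of class `genotype_dataset` with elements `genotypes`,
#'   `labels`, `snp_names`, `sample_ids`.
#' @examples
#' g <- matrix(c(0L, 0L, 2L, 2L, 0L, 1L, 0L, 1L), nrow = 4)
#' d <- genotype_dataset(g, labels = c(1L, 1L, 0L, 0L),
#'                       snp_names = c("X0", "X1"))
#' @export
genotype_dataset <- function(genotypes, labels, snp_names = colnames(genotypes),
                             sample_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  m <- nrow(genotypes)
  n <- ncol(genotypes)
  if (is.null(snp_names)) snp_names <- paste0("S", seq_len(n))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  labels <- as.integer(labels)
  if (n < 1L) stop("dataset must contain at least one SNP")
  if (m < 2L) stop("dataset must contain at least two samples")
  if (length(labels) != m) stop("labels length must equal the number of samples")
  if (anyNA(genotypes) || !all(genotypes %in% 0:2))
    stop("genotype codes must all be in {0, 1, 2}")
  if (anyNA(labels) || !all(labels %in% 0:1))
    stop("class labels must all be in {0, 1}")
  if (!all(tabulate(labels + 1L, 2L) >= 1L))
    stop("dataset must contain at least one case and one control")
  if (length(snp_names) != n || anyDuplicated(snp_names))
    stop("snp_names must be ", n, " unique identifiers")
  if (length(sample_ids) != m || anyDuplicated(sample_ids))
    stop("sample_ids must be ", m, " unique identifiers")
  dimnames(genotypes) <- list(sample_ids, snp_names)
  structure(list(genotypes = genotypes,
                 labels = labels,
                 snp_names = as.character(snp_names),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls) x %d SNPs\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              length(x$snp_names)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

n_snps <- function(x) ncol(x$genotypes)
n_samples <- function(x) nrow(x$genotypes)

#' Read a genotype dataset from an MDR flat file
#'
#' The MDR flat-file format is tab-delimited text: a header of SNP names
#' whose last column is `Class` (matched case-insensitively), then one row
#' per sample of genotype codes `0/1/2` followed by the class code `0/1`.
#' Sample order in the returned dataset equals file row order.
#'
#' @param path path to the file.
#' @param sep field separator, tab by default (use `","` for CSV exports).
#' @return A [genotype_dataset].
#' @export
read_mdr <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2L) stop("parse error: need a header row and at least one sample row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ncol_total <- length(header)
  if (ncol_total < 2L || tolower(header[ncol_total]) != "class")
    stop("parse error at line 1: header must end with a 'Class' column")
  snp_names <- header[-ncol_total]
  m <- length(lines) - 1L
  body <- fields[-1L]
  bad_len <- which(lengths(body) != ncol_total)
  if (length(bad_len))
    stop("parse error at line ", bad_len[1L] + 1L, ": expected ",
         ncol_total, " fields, found ", lengths(body)[bad_len[1L]])
  vals <- suppressWarnings(as.integer(unlist(body, use.names = FALSE)))
  mat <- matrix(vals, nrow = m, ncol = ncol_total, byrow = TRUE)
  geno <- mat[, -ncol_total, drop = FALSE]
  cls <- mat[, ncol_total]
  bad_g <- which(is.na(geno) | geno < 0L | geno > 2L, arr.ind = TRUE)
  if (nrow(bad_g))
    stop("parse error at line ", bad_g[1L, 1L] + 1L,
         ": genotype code not in {0, 1, 2} for SNP '", snp_names[bad_g[1L, 2L]], "'")
  bad_c <- which(is.na(cls) | !cls %in% 0:1)
  if (length(bad_c))
    stop("parse error at line ", bad_c[1L] + 1L, ": class code not in {0, 1}")
  genotype_dataset(geno, cls, snp_names = snp_names,
                   sample_ids = paste0("s", seq_len(m)))
}

#' Write a genotype dataset as an MDR flat file
#'
#' @param dataset a [genotype_dataset].
#' @param path output path.
#' @param sep field separator, tab by default.
#' @return Invisibly, `path`.
#' @export
write_mdr <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  header <- paste(c(dataset$snp_names, "Class"), collapse = sep)
  body <- apply(cbind(dataset$genotypes, dataset$labels), 1L,
                paste, collapse = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Permute the sample presentation order of a dataset
#'
#' Draws a uniform random permutation of the rows from `seed`, preserving the
#' pairing of each genotype row with its class label. This is the elementary
#' move of the ensemble filters: ReliefF/TuRF results can change under it,
#' although the data are unchanged as a set.
#'
#' @param dataset a [genotype_dataset].
#' @param seed integer seed for the permutation.
#' @return A new [genotype_dataset]; the input is unmodified.
#' @export
permute_samples <- function(dataset, seed) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  m <- n_samples(dataset)
  perm <- with_seed(seed, sample.int(m))
  genotype_dataset(dataset$genotypes[perm, , drop = FALSE],
                   dataset$labels[perm],
                   snp_names = dataset$snp_names,
                   sample_ids = dataset$sample_ids[perm])
}

#' Per-SNP filter weights
#'
#' A named vector of per-SNP scores together with provenance. For
#' ReliefF-family filters every weight lies in `[-1, 1]`; univariate filters
#' (chi-squared statistic, |log odds ratio|) are unbounded above.
#'
#' @param weights numeric vector of per-SNP scores, larger = more
#'   discriminative.
#' @param snp_names aligned SNP identifiers.
#' @param meta list of provenance fields (filter name, `K`, `R`, `L`, seeds).
#'   A `family = "relieff"` entry switches on the `[-1, 1]` bound check.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights, snp_names, meta = list()) {
  if (length(weights) != length(snp_names))
    stop("weights and snp_names must have equal length")
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights must be finite")
  if (identical(meta$family, "relieff") && any(abs(weights) > 1 + 1e-12))
    stop("ReliefF-family weights must lie in [-1, 1]")
  structure(list(weights = setNames(as.numeric(weights), snp_names),
                 snp_names = as.character(snp_names),
                 meta = meta),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector (%s): %d SNPs, range [%.4g, %.4g]\n",
              if (is.null(x$meta$filter)) "?" else x$meta$filter,
              length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Per-SNP ranking
#'
#' Ranks are a permutation of `1..N` with rank 1 = most discriminative.
#'
#' @param ranks integer vector, a permutation of `1..N`.
#' @param snp_names aligned SNP identifiers.
#' @param removal_iteration optional per-SNP integer recording the TuRF
#'   iteration at which a SNP was discarded (0 = survived all iterations).
#' @param meta provenance list.
#' @return An object of class `snp_ranking`.
#' @export
snp_ranking <- function(ranks, snp_names, removal_iteration = NULL,
                        meta = list()) {
  ranks <- as.integer(ranks)
  n <- length(snp_names)
  if (length(ranks) != n || !identical(sort(ranks), seq_len(n)))
    stop("ranks must be a permutation of 1..", n)
  if (!is.null(removal_iteration)) {
    removal_iteration <- setNames(as.integer(removal_iteration), snp_names)
  }
  structure(list(ranks = setNames(ranks, snp_names),
                 snp_names = as.character(snp_names),
                 removal_iteration = removal_iteration,
                 meta = meta),
            class = "snp_ranking")
}

#' @export
print.snp_ranking <- function(x, ...) {
  top <- names(sort(x$ranks))[seq_len(min(5L, length(x$ranks)))]
  cat(sprintf("snp_ranking (%s): %d SNPs; top: %s\n",
              if (is.null(x$meta$filter)) "?" else x$meta$filter,
              length(x$ranks), paste(top, collapse = ", ")))
  invisible(x)
}

# Rank order used everywhere: descending weight, ties broken by ascending
# SNP index so every ranking is reproducible from (weights, names).
rank_order <- function(weights) order(-weights, seq_along(weights))

#' Convert filter weights to a SNP ranking
#'
#' Rank 1 goes to the largest weight; ties in weight are broken by ascending
#' SNP index (position in `snp_names`), making the ranking a deterministic
#' function of the weight vector.
#'
#' @param w a [weight_vector].
#' @return A [snp_ranking].
#' @examples
#' w <- weight_vector(c(0.5, -0.2, 0.9), c("a", "b", "c"))
#' weights_to_ranking(w)$ranks  # a=2 b=3 c=1
#' @export
weights_to_ranking <- function(w) {
  stopifnot(inherits(w, "weight_vector"))
  if (anyNA(w$weights)) stop("weights must not contain NaN")
  ord <- rank_order(w$weights)
  ranks <- integer(length(ord))
  ranks[ord] <- seq_along(ord)
  snp_ranking(ranks, w$snp_names, meta = w$meta)
}

# Restrict a dataset to a sample subset (used by tie removal).
subset_samples <- function(dataset, keep) {
  genotype_dataset(dataset$genotypes[keep, , drop = FALSE],
                   dataset$labels[keep],
                   snp_names = dataset$snp_names,
                   sample_ids = dataset$sample_ids[keep])
}
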