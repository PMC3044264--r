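#' Per-SNP chi-squared association statistic
#'
#' Pearson chi-squared statistic on the 2 (class) x 3 (genotype) contingency
#' table of one SNP. Genotype columns with zero margin are dropped (the
#' degrees of freedom shrink accordingly); if fewer than two genotype
#' columns remain the statistic is 0. The statistic itself is used as the
#' ranking weight (monotone in the p-value at fixed df, and immune to
#' p-value underflow at large effects). It depends on the data only through
#' counts, so it is exactly invariant under sample-order permutation.
#'
#' @param snp_column genotype vector in `{0,1,2}`.
#' @param labels class vector in `{0,1}`; both classes must be present.
#' @return Non-negative chi-squared statistic.
#' @examples
#' chi2_score(rep(c(0, 2), each = 10), rep(c(1, 0), each = 10))  # 20
#' @export
chi2_score <- function(snp_column, labels) {
  if (length(unique(labels)) < 2L)
    stop("chi-squared score needs both classes present")
  tab <- table(factor(labels, levels = 0:1),
               factor(snp_column, levels = 0:2))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(0)
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' Per-SNP allelic odds-ratio score
#'
#' Builds the 2 x 2 table of minor/major allele counts in cases versus
#' controls (each sample contributes two alleles; the genotype code is the
#' minor-allele count), applies the Haldane-Anscombe 0.5 correction when any
#' cell is zero, and returns `|log(OR)|` so that protective and risk
#' deviations from the null rank equally. Exactly sample-order invariant.
#'
#' @param snp_column genotype vector in `{0,1,2}`.
#' @param labels class vector in `{0,1}`.
#' @param return_or if `TRUE` return the odds ratio itself instead of
#'   `|log(OR)|`.
#' @return Non-negative score (or the OR).
#' @examples
#' # cases 10 minor / 10 major alleles, controls 5 / 15: OR = 3
#' snp <- c(rep(1, 10), rep(c(1, 0), c(5, 5)))
#' lab <- rep(c(1, 0), each = 10)
#' odds_ratio_score(snp, lab, return_or = TRUE)
#' @export
odds_ratio_score <- function(snp_column, labels, return_or = FALSE) {
  if (length(unique(labels)) < 2L)
    stop("odds-ratio score needs both classes present")
  minor_case <- sum(snp_column[labels == 1])
  minor_ctrl <- sum(snp_column[labels == 0])
  major_case <- 2 * sum(labels == 1) - minor_case
  major_ctrl <- 2 * sum(labels == 0) - minor_ctrl
  cells <- c(minor_case, major_case, minor_ctrl, major_ctrl)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (return_or) or else abs(log(or))
}

#' Univariate filter weights for a whole dataset
#'
#' Applies [chi2_score] or [odds_ratio_score] to every SNP column.
#'
#' @param dataset a [genotype_dataset].
#' @param method `"chi2"` or `"oddsratio"`.
#' @return A [weight_vector] (unbounded; `meta$family = "univariate"`).
#' @export
univariate_weights <- function(dataset, method = c("chi2", "oddsratio")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "genotype_dataset"))
  f <- if (method == "chi2") chi2_score else odds_ratio_score
  w <- apply(dataset$genotypes, 2L, f, labels = dataset$labels)
  weight_vector(w, dataset$snp_names,
                meta = list(filter = method, family = "univariate"))
}
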