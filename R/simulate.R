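#' Hardy-Weinberg genotype probabilities
#'
#' @param maf minor allele frequency `p`, in `(0, 0.5]`.
#' @return Probabilities `((1-p)^2, 2p(1-p), p^2)` for genotype codes 0/1/2.
#' @export
hwe_genotype_probs <- function(maf) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Prevalence implied by a two-locus penetrance table
#'
#' @param table 3 x 3 penetrance matrix `f[a, b]` indexed by the genotype
#'   codes of the two loci.
#' @param maf minor allele frequency shared by both loci (HWE assumed).
#' @return Marginal disease probability `sum(pi_a * pi_b * f[a, b])`.
#' @export
prevalence_of <- function(table, maf) {
  p <- hwe_genotype_probs(maf)
  sum(outer(p, p) * table)
}

#' Broad-sense heritability of a two-locus penetrance model
#'
#' Variance of the penetrance around the prevalence, relative to the
#' Bernoulli variance of the phenotype:
#' `h2 = sum(pi_a pi_b (f_ab - K)^2) / (K (1 - K))` with `K` the prevalence.
#' This is the knob that controls how hard the interaction is to detect.
#'
#' @inheritParams prevalence_of
#' @return Heritability in `[0, 1)`.
#' @export
heritability_of <- function(table, maf) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(3L, 3L)), all(table >= 0), all(table <= 1))
  p <- hwe_genotype_probs(maf)
  k <- sum(outer(p, p) * table)
  if (k <= 0 || k >= 1)
    stop("degenerate penetrance table: prevalence is ", k)
  sum(outer(p, p) * (table - k)^2) / (k * (1 - k))
}

# Weighted double-centering: returns E with zero pi-weighted row and column
# sums, the deviation space of marginal-effect-free penetrance tables.
center_deviation <- function(e0, p) {
  r <- as.vector(e0 %*% p)        # row a: sum_b p_b e0[a,b]
  cc <- as.vector(t(e0) %*% p)    # col b: sum_a p_a e0[a,b]
  tt <- sum(p * r)
  sweep(sweep(e0, 1, r), 2, cc) + tt
}

#' Construct a purely epistatic two-locus penetrance model
#'
#' Random search for a 3 x 3 penetrance table with a given heritability and
#' exactly zero marginal effects: every row and column of the table has
#' pi-weighted mean equal to the prevalence, so neither locus carries any
#' single-SNP association signal -- the interaction is only visible jointly.
#' Random deviation tables are projected onto the marginal-effect-free
#' space by pi-weighted double-centering, rescaled to the target
#' heritability, and rejected if any penetrance leaves `[0, 1]`.
#'
#' @param h2 target heritability, in `(0, 1)`.
#' @param maf minor allele frequency of both functional loci (default 0.4).
#' @param prevalence marginal disease probability `K` (default 0.25).
#' @param seed integer seed for the random search.
#' @param max_tries retry budget before declaring the target infeasible.
#' @return An object of class `penetrance_model`: list with `table` (3 x 3),
#'   `maf`, `prevalence`, `h2`.
#' @export
make_penetrance_model <- function(h2, maf = 0.4, prevalence = 0.25, seed,
                                  max_tries = 10000L) {
  stopifnot(h2 > 0, h2 < 1, prevalence > 0, prevalence < 1)
  if (missing(seed)) stop("seed is required")
  p <- hwe_genotype_probs(maf)
  pp <- outer(p, p)
  target_var <- h2 * prevalence * (1 - prevalence)
  tab <- with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_tries)) {
      e <- center_deviation(matrix(rnorm(9), 3, 3), p)
      v <- sum(pp * e^2)
      if (v < 1e-12) next
      f <- prevalence + e * sqrt(target_var / v)
      if (all(f >= 0 & f <= 1)) {
        found <- f
        break
      }
    }
    found
  })
  if (is.null(tab))
    stop("no feasible marginal-effect-free table found for h2 = ", h2,
         ", maf = ", maf, ", prevalence = ", prevalence,
         " within ", max_tries, " tries; lower h2 or raise maf/prevalence")
  dimnames(tab) <- list(paste0("A", 0:2), paste0("B", 0:2))
  structure(list(table = tab, maf = maf, prevalence = prevalence, h2 = h2),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance_model: h2 = %g, maf = %g, prevalence = %g\n",
              x$h2, x$maf, x$prevalence))
  print(round(x$table, 4))
  invisible(x)
}

# Stream of functional-pair draws: genotypes (a, b) from the HWE joint and
# case status from the penetrance, in batches. Used by the rejection
# sampler and directly testable for unbiasedness.
draw_functional <- function(model, n) {
  p <- hwe_genotype_probs(model$maf)
  a <- sample(0:2, n, replace = TRUE, prob = p)
  b <- sample(0:2, n, replace = TRUE, prob = p)
  f <- model$table[cbind(a + 1L, b + 1L)]
  list(a = a, b = b, case = runif(n) < f)
}

#' Simulate a balanced case-control epistasis dataset
#'
#' Generates one dataset of the standard design: one functional purely
#' epistatic SNP pair, named `X0` and `X1`, plus independent HWE noise SNPs
#' with no case-control signal. Case/control status for the functional pair
#' is drawn by rejection (retrospective sampling): genotype pairs are drawn
#' from the HWE joint and accepted as a case with probability `f[a, b]`,
#' otherwise as a control, until both quotas are filled -- so the genotype
#' distribution within each class is exactly the retrospective one. All
#' other SNPs are drawn identically for cases and controls. SNP column
#' order is randomised so the functional pair holds no privileged position;
#' samples are ordered cases first, then controls.
#'
#' @param model a [make_penetrance_model] result.
#' @param n_cases,n_controls class quotas (e.g. 200/200 or 400/400).
#' @param n_snps total SNP count including the functional pair
#'   (default 1000).
#' @param seed integer seed.
#' @param noise_maf minor allele frequency of the noise SNPs; defaults to
#'   the model's MAF.
#' @return A [genotype_dataset]; attribute `functional_pair` gives
#'   `c("X0", "X1")`.
#' @export
simulate_dataset <- function(model, n_cases, n_controls, n_snps = 1000L,
                             seed, noise_maf = model$maf) {
  stopifnot(inherits(model, "penetrance_model"),
            n_cases >= 1L, n_controls >= 1L, n_snps >= 2L)
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    ca <- cb <- integer(0)
    ka <- kb <- integer(0)
    guard <- 0L
    while (length(ka) < n_cases || length(ca) < n_controls) {
      d <- draw_functional(model, 4L * (n_cases + n_controls))
      ka <- c(ka, d$a[d$case]); kb <- c(kb, d$b[d$case])
      ca <- c(ca, d$a[!d$case]); cb <- c(cb, d$b[!d$case])
      guard <- guard + 1L
      if (guard > 10000L)
        stop("rejection sampler failed to fill case/control quotas; ",
             "degenerate penetrance model")
    }
    m <- n_cases + n_controls
    x0 <- c(ka[seq_len(n_cases)], ca[seq_len(n_controls)])
    x1 <- c(kb[seq_len(n_cases)], cb[seq_len(n_controls)])
    pn <- hwe_genotype_probs(noise_maf)
    noise <- matrix(sample(0:2, m * (n_snps - 2L), replace = TRUE, prob = pn),
                    nrow = m)
    geno <- cbind(x0, x1, noise)
    nm <- paste0("X", seq_len(n_snps) - 1L)
    ord <- sample.int(n_snps)
    ds <- genotype_dataset(geno[, ord, drop = FALSE],
                           labels = rep(c(1L, 0L), c(n_cases, n_controls)),
                           snp_names = nm[ord],
                           sample_ids = c(paste0("case", seq_len(n_cases)),
                                          paste0("ctrl", seq_len(n_controls))))
    attr(ds, "functional_pair") <- c("X0", "X1")
    attr(ds, "model") <- model
    ds
  })
}

#' Standard epistatic simulation models
#'
#' The eight standard model configurations: 1000 SNPs, balanced
#' case-control of total size 400 or 800, heritability 0.05/0.1/0.2/0.3,
#' one functional pair.
#'
#' @return Data frame with columns `model`, `n_snps`, `n_cases`,
#'   `n_controls`, `h2`.
#' @export
epistasis_models <- function() {
  grid <- expand.grid(h2 = c(0.05, 0.1, 0.2, 0.3), size = c(400L, 800L))
  data.frame(model = sprintf("Epistatic_%d_%s", grid$size, as.character(grid$h2)),
             n_snps = 1000L,
             n_cases = grid$size %/% 2L,
             n_controls = grid$size %/% 2L,
             h2 = grid$h2,
             stringsAsFactors = FALSE)
}

# Resolve "Epistatic_<size>_<h2>" to its configuration row.
lookup_model <- function(name) {
  models <- epistasis_models()
  i <- match(name, models$model)
  if (is.na(i))
    stop("unknown model '", name, "'; available: ",
         paste(models$model, collapse = ", "))
  models[i, ]
}
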