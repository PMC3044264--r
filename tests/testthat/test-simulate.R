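test_that("HWE genotype probabilities are correct and normalized", {
  expect_equal(hwe_genotype_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_probs(0.2), c(0.64, 0.32, 0.04))
  for (maf in seq(0.05, 0.5, by = 0.05))
    expect_equal(sum(hwe_genotype_probs(maf)), 1)
  expect_error(hwe_genotype_probs(0), "\\(0, 0.5\\]")
  expect_error(hwe_genotype_probs(0.6), "\\(0, 0.5\\]")
})

test_that("heritability formula matches direct evaluation", {
  # constant table: zero variance
  expect_equal(heritability_of(matrix(0.3, 3, 3), 0.3), 0)
  # XOR-like table at maf 0.5, evaluated against independent arithmetic
  f <- matrix(0.1, 3, 3)
  a <- 0.35
  f[2, 2] <- a
  f[1, 2] <- f[2, 1] <- f[2, 3] <- f[3, 2] <- 0.1
  p <- c(0.25, 0.5, 0.25)
  k <- sum(outer(p, p) * f)
  h_expected <- sum(outer(p, p) * (f - k)^2) / (k * (1 - k))
  expect_equal(heritability_of(f, 0.5), h_expected)
  # scaling deviations by c scales h2 by c^2 at fixed prevalence
  m <- make_penetrance_model(0.08, seed = 3)
  k0 <- m$prevalence
  half <- k0 + (m$table - k0) * 0.5
  expect_equal(heritability_of(half, m$maf), 0.08 / 4, tolerance = 1e-9)
})

test_that("penetrance models hit the target exactly with no marginal effects", {
  for (h2 in c(0.05, 0.1, 0.2, 0.3)) {
    m <- make_penetrance_model(h2, seed = 17)
    p <- hwe_genotype_probs(m$maf)
    expect_equal(heritability_of(m$table, m$maf), h2, tolerance = 1e-6)
    expect_equal(prevalence_of(m$table, m$maf), m$prevalence,
                 tolerance = 1e-6)
    # every row and column marginal penetrance equals the prevalence
    expect_equal(unname(as.vector(m$table %*% p)), rep(m$prevalence, 3),
                 tolerance = 1e-6)
    expect_equal(unname(as.vector(t(m$table) %*% p)), rep(m$prevalence, 3),
                 tolerance = 1e-6)
    expect_true(all(m$table >= 0 & m$table <= 1))
  }
  # determinism
  expect_identical(make_penetrance_model(0.1, seed = 5)$table,
                   make_penetrance_model(0.1, seed = 5)$table)
  # infeasible target reported as such: h2 0.3 is beyond the maf 0.2 /
  # prevalence 0.1 feasibility bound
  expect_error(make_penetrance_model(0.3, maf = 0.2, prevalence = 0.1,
                                     seed = 1, max_tries = 2000),
               "no feasible")
})

test_that("simulated datasets have the configured shape and naming", {
  m <- make_penetrance_model(0.1, seed = 23)
  ds <- simulate_dataset(m, 200, 200, 1000, seed = 4)
  expect_equal(dim(ds), c(400L, 1000L))
  expect_equal(sum(ds$labels == 1L), 200)
  expect_equal(sum(ds$labels == 0L), 200)
  expect_true(all(c("X0", "X1") %in% ds$snp_names))
  expect_equal(attr(ds, "functional_pair"), c("X0", "X1"))
  # cases first, then controls
  expect_equal(ds$labels, rep(c(1L, 0L), each = 200))
  # determinism
  ds2 <- simulate_dataset(m, 200, 200, 1000, seed = 4)
  expect_identical(ds$genotypes, ds2$genotypes)
  # written file shape: header + 400 rows, 1001 columns
  f <- withr::local_tempfile()
  write_mdr(ds, f)
  lines <- readLines(f)
  expect_length(lines, 401)
  expect_length(strsplit(lines[1], "\t")[[1]], 1001)
})

test_that("the rejection sampler is unbiased for P(case | genotypes)", {
  m <- make_penetrance_model(0.2, seed = 31)
  set.seed(99)
  d <- epifilter:::draw_functional(m, 2e5)
  for (a in 0:2) for (b in 0:2) {
    sel <- d$a == a & d$b == b
    n <- sum(sel)
    if (n < 200) next
    f <- m$table[a + 1, b + 1]
    se <- sqrt(f * (1 - f) / n)
    expect_lt(abs(mean(d$case[sel]) - f), 3 * se + 1e-12)
  }
})

test_that("noise SNPs carry no marginal association signal", {
  # aggregate chi-squared calibration: about 5% of noise SNPs exceed the
  # 0.95 quantile of their null distribution
  dss <- sim_collection(20, h2 = 0.2, n_cases = 100, n_controls = 100,
                        n_snps = 150, seed = 404)
  exceed <- 0L; total <- 0L
  for (ds in dss) {
    noise <- setdiff(ds$snp_names, c("X0", "X1"))
    for (s in noise) {
      tab <- table(factor(ds$labels, levels = 0:1),
                   factor(ds$genotypes[, s], levels = 0:2))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      stat <- chi2_score(ds$genotypes[, s], ds$labels)
      df <- ncol(tab) - 1L
      if (df < 1) next
      total <- total + 1L
      if (stat > stats::qchisq(0.95, df)) exceed <- exceed + 1L
    }
  }
  rate <- exceed / total
  # binomial sd ~ 0.4% at ~3000 SNPs; allow a generous band
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("the standard model catalogue covers the full simulation grid", {
  models <- epistasis_models()
  expect_equal(nrow(models), 8)
  expect_true(all(models$n_snps == 1000))
  expect_setequal(models$n_cases + models$n_controls, c(400, 800))
  expect_true("Epistatic_400_0.05" %in% models$model)
  expect_true("Epistatic_800_0.3" %in% models$model)
  cfg <- epifilter:::lookup_model("Epistatic_800_0.3")
  expect_equal(cfg$n_cases, 400L)
  expect_equal(cfg$h2, 0.3)
  expect_error(epifilter:::lookup_model("nope"), "Epistatic_400_0.05")
})
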