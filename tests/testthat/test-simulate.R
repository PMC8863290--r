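test_that("haplotype simulation is deterministic and respects block LD structure", {
  a <- simulate_haplotypes(200, list(c(4, 1), c(4, 4)), seed = 101)
  b <- simulate_haplotypes(200, list(c(4, 1), c(4, 4)), seed = 101)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$variants, b$variants)

  # one derived founder: every within-block pair in perfect LD
  for (i in 1:3) expect_equal(r2_phased(a, i, i + 1), 1)

  # minor-allele frequencies honour the requested range
  freq <- colMeans(a$haplotypes)
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf >= 0.05 & maf <= 0.5))
})

test_that("cross-block LD is at chance level in a large panel", {
  pan <- simulate_haplotypes(2000, list(c(4, 2), c(4, 2)), seed = 7)
  cross <- c(
    r2_phased(pan, 1, 5), r2_phased(pan, 1, 6), r2_phased(pan, 2, 7),
    r2_phased(pan, 3, 8), r2_phased(pan, 4, 5), r2_phased(pan, 2, 6),
    r2_phased(pan, 3, 5), r2_phased(pan, 4, 8)
  )
  expect_lt(median(cross), 0.01)
})

test_that("an unsatisfiable MAF constraint errors naming the variant", {
  # with one derived founder the achievable frequency is the founder-class
  # share (~0.5); a MAF band near 0.02 cannot be hit
  expect_error(
    simulate_haplotypes(100, list(c(2, 1)), maf_range = c(0.01, 0.02),
                        seed = 3, max_retries = 20),
    "maf_range.*v0001"
  )
  expect_error(simulate_haplotypes(1, list(c(2, 1))), "n_samples")
  expect_error(simulate_haplotypes(10, list()), "non-empty")
})

test_that("simulated genotypes are consistent with Hardy-Weinberg equilibrium", {
  pan <- simulate_haplotypes(5000, list(c(6, 4)), seed = 13)
  d <- panel_dosages(pan)
  for (j in seq_len(ncol(d))) {
    p <- mean(d[, j]) / 2
    expected <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(d[, j] + 1L, nbins = 3L)
    chi2 <- sum((observed - expected)^2 / expected)
    expect_gt(stats::pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
  }
})

test_that("expression simulation plants the genotype-class mean pattern", {
  pan <- simulate_haplotypes(2000, list(c(2, 4)), seed = 31)
  d <- panel_dosages(pan)
  # delta = 0.2 around mu = 10: class means 8 / 10 / 12
  e <- simulate_expression(d, list(GX = list(variants = "v0001", delta = 0.2)),
                           mu = 10, noise_sd = 1, seed = 32)
  for (g in 0:2) {
    sel <- d[, "v0001"] == g
    se <- 1 / sqrt(sum(sel))
    expect_lt(abs(mean(e[sel, "GX"]) - (10 + 2 * (g - 1))), 2.5 * se)
  }
})

test_that("a null effect leaves only sampling noise in the slope", {
  pan <- simulate_haplotypes(1000, list(c(2, 4)), seed = 41)
  d <- panel_dosages(pan)
  e <- simulate_expression(d, list(GX = list(variants = "v0001", delta = 0)),
                           mu = 10, noise_sd = 1, seed = 42)
  fit <- summary(lm(e[, "GX"] ~ d[, "v0001"]))
  expect_gt(fit$coefficients[2, 4], 0.001)
  expect_lt(abs(fit$coefficients[2, 1]), 0.2)
})

test_that("two unlinked causal variants are both recovered by a joint model", {
  pan <- simulate_haplotypes(2000, list(c(1, 3), c(1, 3)), seed = 51)
  d <- panel_dosages(pan)
  expect_lt(r2_phased(pan, 1, 2), 0.05)
  e <- simulate_expression(
    d, list(GX = list(variants = c("v0001", "v0002"), delta = c(0.2, 0.1))),
    mu = 10, noise_sd = 1, seed = 52
  )
  fit <- lm(e[, "GX"] ~ d[, "v0001"] + d[, "v0002"])
  cf <- summary(fit)$coefficients
  # per-allele raw effects mu * delta = 2 and 1
  expect_lt(abs(cf[2, 1] - 2), 2.5 * cf[2, 2])
  expect_lt(abs(cf[3, 1] - 1), 2.5 * cf[3, 2])
})

test_that("expression simulation validates its causal specification", {
  pan <- simulate_haplotypes(50, list(c(2, 2)), seed = 61)
  d <- panel_dosages(pan)
  expect_error(
    simulate_expression(d, list(G = list(variants = "nope", delta = 0.2))),
    "absent"
  )
  expect_error(
    simulate_expression(d, list(G = list(variants = "v0001", delta = -0.1))),
    "delta"
  )
})

test_that("allelic count simulation matches its binomial model", {
  # balanced null: E[REF_RATIO] = NULL_RATIO = 0.5
  null <- simulate_ase(1000, afc = 1, rho = 0.5, depth_mean = 100, seed = 71)
  expect_lt(abs(mean(null$REF_RATIO, na.rm = TRUE) - 0.5), 0.01)
  expect_equal(unique(null$NULL_RATIO), 0.5)

  # reference bias absorbed by the null ratio: expected deviation 0
  bias <- simulate_ase(1000, afc = 1, rho = 0.55, depth_mean = 100, seed = 72)
  dev <- bias$REF_RATIO - bias$NULL_RATIO
  expect_lt(abs(mean(dev, na.rm = TRUE)), 0.01)
  expect_equal(unique(bias$NULL_RATIO), 0.55)

  # allelic fold-change 2: E[REF_RATIO] = 2/3, mean deviation ~ +1/6
  afc2 <- simulate_ase(1000, afc = 2, rho = 0.5, depth_mean = 100, seed = 73)
  dev2 <- afc2$REF_RATIO - afc2$NULL_RATIO
  expect_lt(abs(mean(dev2, na.rm = TRUE) - 1 / 6), 0.01)

  expect_error(simulate_ase(10, afc = 0), "fold-change")
  expect_error(simulate_ase(10, rho = 1), "rho")
})

test_that("zero-depth allelic rows are emitted but flagged uninformative", {
  obs <- simulate_ase(2000, afc = 1, rho = 0.5, depth_mean = 2,
                      depth_dispersion = 0.5, seed = 81)
  expect_true(any(obs$uninformative))
  expect_true(all(is.na(obs$REF_RATIO[obs$uninformative])))
  expect_equal(nrow(obs), 2000)
})

test_that("locus catalog emits every requested tier and is reproducible on disk", {
  cat1 <- simulate_locus_catalog(seed = 91)
  expect_setequal(cat1$truth$true_tier, c("1", "2A", "2B", "2C", "3"))
  # multi-SNP tier-1 locus
  expect_equal(sum(cat1$gwas$locus == cat1$truth$locus[cat1$truth$true_tier == "1"]), 2)
  # tier-3 locus has no QTL rows
  t3 <- cat1$truth$locus[cat1$truth$true_tier == "3"]
  t3_rs <- cat1$gwas$rs_id[cat1$gwas$locus == t3]
  expect_false(any(cat1$qtl$rs_id %in% t3_rs))

  empty <- simulate_locus_catalog(character(0), seed = 91)
  expect_equal(nrow(empty$gwas), 0)
  expect_equal(nrow(empty$qtl), 0)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_locus_catalog(cat1, d1)
  write_locus_catalog(simulate_locus_catalog(seed = 91), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # the written files re-read into equivalent tables
  expect_equal(nrow(read_gwas_tsv(file.path(d1, "gwas.tsv"))), nrow(cat1$gwas))
  eq <- read_qtl_tsv(file.path(d1, "eqtl.tsv"))
  expect_true(all(eq$qtl_type == "eQTL"))
})
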