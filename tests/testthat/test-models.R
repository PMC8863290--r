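sim_pheno <- function(n = 400, seed = 1, beta = c(g1 = 0.8, g2 = 0, g3 = 0.5),
                      proxy = FALSE) {
  set.seed(seed)
  d <- data.frame(
    g1 = rbinom(n, 2, 0.35), g2 = rbinom(n, 2, 0.3), g3 = rbinom(n, 2, 0.25),
    sex = rbinom(n, 1, 0.5), age = rnorm(n, 60, 8)
  )
  if (proxy) d$g2 <- d$g1
  d$xp <- 10 + beta["g1"] * d$g1 + beta["g2"] * d$g2 + beta["g3"] * d$g3 +
    0.02 * d$age + 0.1 * d$sex + rnorm(n)
  lp <- -1 + 0.4 * d$g1 + 0.01 * (d$age - 60)
  d$cad <- rbinom(n, 1, plogis(lp))
  d
}

test_that("gaussian log-likelihood and AIC match the closed form", {
  y <- c(2, 4, 5, 7, 8, 9, 12, 13, 15, 16)
  d <- data.frame(y = y)
  f <- fit_glm_model("y", character(0), character(0), d, "gaussian")
  n <- length(y)
  sigma2_mle <- sum((y - mean(y))^2) / n
  ll_closed <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  expect_equal(f$logLik, ll_closed, tolerance = 1e-8)
  # AIC identity with k = 2 (mean + variance)
  expect_equal(f$aic, 2 * 2 - 2 * ll_closed, tolerance = 1e-8)
  expect_equal(f$aic, AIC(f$fit), tolerance = 1e-8)
})

test_that("logistic fits behave under the null and fail on separation", {
  d <- sim_pheno(300, seed = 3, beta = c(g1 = 0, g2 = 0, g3 = 0))
  f <- fit_glm_model("cad", "g2", c("sex", "age"), d, "binomial")
  expect_lt(abs(f$coefficients["g2"]), 0.5)
  sep <- data.frame(y = rep(c(0, 1), each = 10), x = rep(c(0, 1), each = 10))
  expect_error(fit_glm_model("y", "x", character(0), sep, "binomial"),
               "separation")
})

test_that("collinear designs drop an aliased term with a warning and still fit", {
  d <- sim_pheno(200, seed = 5, proxy = TRUE)
  expect_warning(
    f <- fit_glm_model("xp", c("g1", "g2"), c("sex", "age"), d, "gaussian"),
    "aliased"
  )
  expect_true("g2" %in% f$aliased)
  expect_equal(f$n_params, 4) # intercept, g1, sex, age
})

test_that("nested comparisons compute the LRT and flag uninformative additions", {
  d <- sim_pheno(400, seed = 7)
  base <- fit_glm_model("xp", character(0), c("sex", "age"), d)
  full <- fit_glm_model("xp", "g1", c("sex", "age"), d)
  cmp <- compare_nested(base, full, m = 3)
  expect_equal(cmp$lrt_stat, 2 * (full$logLik - base$logLik), tolerance = 1e-8)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$pval_bonf, min(1, 3 * cmp$pval))
  expect_lt(full$aic, base$aic)

  # a model against itself: statistic 0, p 1
  self <- compare_nested(base, base)
  expect_equal(self$lrt_stat, 0)
  expect_equal(self$pval, 1)

  # perfect-proxy addition: aliased, df 0, uninformative, p = 1
  dp <- sim_pheno(400, seed = 9, proxy = TRUE)
  f1 <- fit_glm_model("xp", "g1", c("sex", "age"), dp)
  f2 <- suppressWarnings(
    fit_glm_model("xp", c("g1", "g2"), c("sex", "age"), dp)
  )
  cmp2 <- compare_nested(f1, f2)
  expect_false(cmp2$informative)
  expect_equal(cmp2$pval, 1)

  expect_error(compare_nested(full, base), "not nested")
  d2 <- sim_pheno(399, seed = 7)
  full2 <- fit_glm_model("xp", "g1", c("sex", "age"), d2)
  expect_error(compare_nested(base, full2), "different sample rows")
})

test_that("null LRT p-values are uniform and agree with the F test", {
  set.seed(11)
  pvals <- numeric(200)
  agree <- logical(200)
  for (k in 1:200) {
    n <- 150
    d <- data.frame(y = rnorm(n), x = rbinom(n, 2, 0.3), z = rnorm(n))
    base <- fit_glm_model("y", character(0), "z", d)
    full <- fit_glm_model("y", "x", "z", d)
    pvals[k] <- compare_nested(base, full)$pval
    f_p <- anova(base$fit, full$fit, test = "F")$`Pr(>F)`[2]
    agree[k] <- (pvals[k] < 0.05) == (f_p < 0.05)
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_gte(mean(agree), 0.95)
})

test_that("sequential analysis reproduces the in-context row pattern", {
  d <- sim_pheno(500, seed = 13)
  tab <- sequential_marker_analysis(d, "xp", c("g1", "g2", "g3"),
                                    c("sex", "age"))
  # three single-marker rows plus two in-context rows
  expect_equal(nrow(tab), 5)
  expect_true(all(grepl("in context of", tab$variable_of_interest[4:5])))
  # true markers significant alone; the null marker's in-context row is not
  expect_lt(tab$anova_p[tab$variable_of_interest == "g1"], 1e-6)
  g2row <- tab[tab$variable_of_interest == "g1 in context of g2", ]
  expect_gt(g2row$anova_p, 0.05)
  expect_false(g2row$accepted)
  # g3 is causal: accepted into the context set
  g3row <- tab[grepl("in context of g3", tab$variable_of_interest), ]
  expect_true(g3row$accepted)
  expect_lt(g3row$aic2, g3row$aic1)

  # base-only call
  base_only <- sequential_marker_analysis(d, "xp", character(0),
                                          c("sex", "age"))
  expect_equal(nrow(base_only), 1)
})

test_that("a perfect proxy yields an uninformative in-context comparison", {
  d <- sim_pheno(500, seed = 17, proxy = TRUE)
  tab <- suppressWarnings(
    sequential_marker_analysis(d, "xp", c("g1", "g2"), c("sex", "age"))
  )
  row <- tab[tab$variable_of_interest == "g1 in context of g2", ]
  expect_false(row$informative)
  expect_equal(row$anova_p, 1)
})

test_that("planted slopes are recovered with near-nominal coverage", {
  set.seed(19)
  hits <- replicate(200, {
    n <- 250
    g <- rbinom(n, 2, 0.3)
    y <- 10 + 0.5 * g + rnorm(n)
    f <- fit_glm_model("y", "g", character(0), data.frame(y = y, g = g))
    se <- summary(f$fit)$coefficients["g", 2]
    abs(f$coefficients["g"] - 0.5) <= 2 * se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("genotype-stratified rank-sum tests localize a class-specific shift", {
  set.seed(23)
  hits <- replicate(100, {
    n <- 300
    g <- rbinom(n, 2, 0.4)
    cad <- rbinom(n, 1, 0.5)
    y <- rnorm(n)
    y[g == 2 & cad == 0] <- y[g == 2 & cad == 0] + 1.5
    res <- genotype_stratified_test(y, cad, g)
    (res$pval[res$genotype == 2] < 0.05) &&
      (res$pval[res$genotype == 0] > 0.05)
  })
  expect_gte(mean(hits), 0.8)

  # untestable group and tied exact case
  y <- c(1, 1, 1, 1); cad <- c(0, 0, 1, 1); g <- c(0, 0, 0, 0)
  res <- genotype_stratified_test(y, cad, g)
  expect_equal(res$pval[res$genotype == 0], 1)
  expect_false(res$testable[res$genotype == 2])
})
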