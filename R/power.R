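#' ANOVA-based cis-eQTL detection power
#'
#' One-way ANOVA power across the three genotype classes of a biallelic
#' variant under Hardy-Weinberg genotype weights
#' \eqn{w = ((1-p)^2, 2p(1-p), p^2)}. Genotype-class means follow the
#' fractional-effect convention \eqn{\mu(1-\delta), \mu, \mu(1+\delta)}:
#' with \eqn{\delta = 0.2} the homozygous classes sit 20 percent below and
#' above the median expression — a 40 percent spread between homozygotes.
#' The noncentrality parameter is
#' \eqn{\lambda = n \sum_i w_i (\mu_i - \bar\mu)^2 / \sigma^2} with
#' \eqn{\bar\mu = \sum_i w_i \mu_i}; power is the upper tail of the
#' noncentral F(2, n-3) distribution at the central-F critical value for
#' the Bonferroni per-test level `alpha / n_tests`.
#'
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param delta Fractional effect per genotype class (>= 0).
#' @param mu Median expression level.
#' @param sigma Residual standard deviation; defaults to `cv * mu`.
#' @param n Sample size (>= 4).
#' @param n_tests Multiple-testing burden (default 5e6 tested variants).
#' @param alpha Family-wise significance level (default 0.05).
#' @param cv Coefficient of variation used when `sigma` is not given
#'   (default 0.3).
#' @return Power in `[0, 1]`.
#' @export
eqtl_anova_power <- function(maf, delta, mu, sigma = cv * mu, n,
                             n_tests = 5e6, alpha = 0.05, cv = 0.3) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (delta < 0) stop("delta must be >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  if (n < 4) stop("n must be >= 4")
  p <- maf
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mu_g <- mu * c(1 - delta, 1, 1 + delta)
  mu_bar <- sum(w * mu_g)
  lambda <- n * sum(w * (mu_g - mu_bar)^2) / sigma^2
  a_per <- alpha / n_tests
  crit <- stats::qf(a_per, 2, n - 3, lower.tail = FALSE)
  if (lambda == 0) {
    # central case: power is exactly the per-test size
    stats::pf(crit, 2, n - 3, lower.tail = FALSE)
  } else {
    stats::pf(crit, 2, n - 3, ncp = lambda, lower.tail = FALSE)
  }
}

#' Per-tissue eQTL power table
#'
#' Applies [eqtl_anova_power()] tissue by tissue with the tissue's sample
#' size and median expression, holding the variant parameters fixed —
#' barplot-ready output for comparing detection power across tissues.
#'
#' @param tissues Tibble with columns `tissue`, `n`, `median_expression`.
#' @param maf,delta,n_tests,alpha,cv,sigma Passed to [eqtl_anova_power()];
#'   when `sigma` is `NULL` (default) it is derived per tissue as
#'   `cv * median_expression`.
#' @return Tibble with `tissue`, `n`, `median_expression`, `power`.
#' @export
power_by_tissue <- function(tissues, maf = 0.05, delta = 0.2,
                            n_tests = 5e6, alpha = 0.05, cv = 0.3,
                            sigma = NULL) {
  tissues <- tibble::as_tibble(tissues)
  if (nrow(tissues) == 0) stop("tissue table must be non-empty")
  needed <- c("tissue", "n", "median_expression")
  missing <- setdiff(needed, names(tissues))
  if (length(missing)) {
    stop("tissue table lacks columns: ", paste(missing, collapse = ", "))
  }
  pw <- vapply(seq_len(nrow(tissues)), function(k) {
    mu <- tissues$median_expression[k]
    s <- if (is.null(sigma)) cv * mu else sigma
    eqtl_anova_power(maf = maf, delta = delta, mu = mu, sigma = s,
                     n = tissues$n[k], n_tests = n_tests, alpha = alpha)
  }, numeric(1))
  tibble::tibble(
    tissue = tissues$tissue, n = tissues$n,
    median_expression = tissues$median_expression, power = pw
  )
}
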