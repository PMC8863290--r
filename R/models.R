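#' Fit a marker/covariate generalized linear model
#'
#' Expression responses are fitted as Gaussian linear models, disease
#' responses as additive logistic regressions (dosage-coded markers).
#' Rows with missing values in any used column are dropped (listwise
#' deletion, with the count recorded). Perfectly collinear terms are
#' dropped as aliased with a warning and recorded in the result; perfect
#' separation of a logistic fit is an error.
#'
#' @param response Name of the response column.
#' @param markers Character vector of marker (dosage) columns; may be
#'   empty for a covariate-only base model.
#' @param covariates Character vector of covariate columns.
#' @param data Data frame holding all columns.
#' @param family `"gaussian"` (expression) or `"binomial"` (disease).
#' @return A `glm_fit`: list with the `glm` object, `logLik`, `aic`
#'   (2k - 2 logLik counting all estimated parameters, the dispersion
#'   included for Gaussian fits), `n_params`, `aliased`, `n_used`,
#'   `n_dropped`, `terms` and `formula`.
#' @export
fit_glm_model <- function(response, markers = character(0),
                          covariates = character(0), data,
                          family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (length(intersect(markers, covariates))) {
    stop("markers and covariates must be disjoint")
  }
  cols <- c(response, markers, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[, cols, drop = FALSE]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  rhs <- c(markers, covariates)
  fml <- stats::as.formula(paste(
    response, "~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"
  ))
  k_expected <- length(rhs) + 1L
  if (nrow(df) < k_expected + 5L) {
    stop("too few complete cases (", nrow(df), ") for ", k_expected,
         " parameters")
  }
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = family),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (family == "binomial") {
    cf <- stats::coef(fit)
    blown_up <- any(abs(cf[!is.na(cf)]) > 15)
    if (sep_warning || !fit$converged || blown_up) {
      stop("logistic fit failed: perfect or quasi-perfect separation")
    }
  }
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    warning("aliased (collinear) terms dropped: ",
            paste(aliased, collapse = ", "))
  }
  ll <- stats::logLik(fit)
  structure(
    list(
      fit = fit,
      coefficients = stats::coef(fit),
      logLik = as.numeric(ll),
      df = attr(ll, "df"),
      aic = 2 * attr(ll, "df") - 2 * as.numeric(ll),
      n_params = sum(!is.na(stats::coef(fit))),
      aliased = aliased,
      n_used = nrow(df),
      n_dropped = n_dropped,
      rows = which(cc),
      response = response,
      markers = markers,
      covariates = covariates,
      family = family,
      formula = paste(deparse(fml), collapse = "")
    ),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s | logLik %.3f | AIC %.2f | n %d\n",
              x$formula, x$logLik, x$aic, x$n_used))
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Computes the LRT statistic `2 (logLik_full - logLik_reduced)`, its
#' chi-square p-value on the difference in estimated (non-aliased)
#' parameters, and the Bonferroni-corrected p given a comparison family of
#' size `m`. When the full model adds only aliased terms (e.g. a marker in
#' perfect LD with one already present), the parameter difference is zero
#' and the comparison is reported as uninformative with `p = 1`.
#'
#' @param reduced,full `glm_fit` objects on identical data rows; the
#'   reduced model's terms must be a subset of the full model's.
#' @param m Bonferroni family size (default 1).
#' @return Tibble with `lrt_stat`, `df`, `pval`, `pval_bonf`, `aic_reduced`,
#'   `aic_full`, `informative`.
#' @export
compare_nested <- function(reduced, full, m = 1L) {
  stopifnot(inherits(reduced, "glm_fit"), inherits(full, "glm_fit"))
  r_terms <- c(reduced$markers, reduced$covariates)
  f_terms <- c(full$markers, full$covariates)
  if (!all(r_terms %in% f_terms)) {
    stop("models are not nested: reduced terms not a subset of full terms")
  }
  if (reduced$n_used != full$n_used ||
      !identical(reduced$rows, full$rows)) {
    stop("models were fitted on different sample rows")
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_params - reduced$n_params
  informative <- df >= 1L
  p <- if (informative) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  tibble::tibble(
    lrt_stat = stat, df = df, pval = p,
    pval_bonf = min(1, m * p),
    aic_reduced = reduced$aic, aic_full = full$aic,
    informative = informative
  )
}

#' Sequential multi-marker model comparison
#'
#' Reproduces the two-phase design used to ask how many marker variants a
#' response needs. Phase one tests each marker alone against the
#' covariate-only base model. Phase two grows a context set greedily: the
#' first marker is accepted, and each subsequent marker is tested "in
#' context of" the currently accepted set (accepted set vs accepted set +
#' marker); a marker joins the set when its comparison is informative and
#' significant at `accept_alpha`. A candidate in perfect LD with an
#' accepted marker yields an aliased, uninformative row (p = 1) and is not
#' accepted. Reported p-values are Bonferroni-corrected over the emitted
#' comparisons.
#'
#' @param data Data frame with response, marker and covariate columns.
#' @param response Response column name.
#' @param markers Ordered character vector of marker columns.
#' @param covariates Covariate column names.
#' @param family `"gaussian"` or `"binomial"`.
#' @param accept_alpha Acceptance threshold for growing the context set
#'   (default 0.05, on the uncorrected LRT p).
#' @return Tibble with one row per comparison: `variable_of_interest`,
#'   `anova_p`, `anova_p_bonf`, `model1`, `aic1`, `model2`, `aic2`,
#'   `informative`, `accepted`.
#' @export
sequential_marker_analysis <- function(data, response, markers, covariates,
                                       family = c("gaussian", "binomial"),
                                       accept_alpha = 0.05) {
  family <- match.arg(family)
  base <- fit_glm_model(response, character(0), covariates, data, family)
  rows <- list()
  add_row <- function(label, cmp, reduced, full, accepted) {
    tibble::tibble(
      variable_of_interest = label,
      anova_p = cmp$pval,
      model1 = reduced$formula, aic1 = reduced$aic,
      model2 = full$formula, aic2 = full$aic,
      informative = cmp$informative,
      accepted = accepted
    )
  }
  if (length(markers) == 0) {
    out <- tibble::tibble(
      variable_of_interest = "(base)", anova_p = NA_real_,
      model1 = base$formula, aic1 = base$aic,
      model2 = base$formula, aic2 = base$aic,
      informative = FALSE, accepted = FALSE
    )
    out$anova_p_bonf <- NA_real_
    return(out)
  }
  # phase 1: each marker alone against the base model
  for (mk in markers) {
    full <- suppressWarnings(
      fit_glm_model(response, mk, covariates, data, family)
    )
    cmp <- compare_nested(base, full, m = 1L)
    rows[[length(rows) + 1L]] <- add_row(mk, cmp, base, full, NA)
  }
  # phase 2: greedy growth of the context set
  accepted <- markers[1]
  cur <- suppressWarnings(
    fit_glm_model(response, accepted, covariates, data, family)
  )
  for (mk in markers[-1]) {
    full <- suppressWarnings(
      fit_glm_model(response, c(accepted, mk), covariates, data, family)
    )
    cmp <- compare_nested(cur, full, m = 1L)
    take <- cmp$informative && cmp$pval < accept_alpha
    label <- paste(paste(accepted, collapse = " & "), "in context of", mk)
    rows[[length(rows) + 1L]] <- add_row(label, cmp, cur, full, take)
    if (take) {
      accepted <- c(accepted, mk)
      cur <- full
    }
  }
  out <- dplyr::bind_rows(rows)
  out$anova_p_bonf <- pmin(1, out$anova_p * nrow(out))
  out
}

#' Genotype-stratified expression comparison between disease classes
#'
#' Within each genotype dosage group (0, 1, 2 copies of the effect
#' allele), performs a two-sided Wilcoxon rank-sum test of expression
#' between disease and non-disease samples (exact for small groups without
#' ties, normal approximation otherwise). Groups lacking at least two
#' observations per disease class are reported untestable.
#'
#' @param expression Numeric expression vector.
#' @param disease Logical or 0/1 disease status.
#' @param dosage Genotype dosage vector in \{0, 1, 2\}.
#' @return Tibble with `genotype`, `n_disease`, `n_control`, `pval`,
#'   `testable`.
#' @export
genotype_stratified_test <- function(expression, disease, dosage) {
  disease <- as.logical(disease)
  out <- lapply(0:2, function(g) {
    sel <- !is.na(dosage) & dosage == g
    x <- expression[sel & disease]
    y <- expression[sel & !disease]
    testable <- length(x) >= 2L && length(y) >= 2L
    p <- if (testable) {
      pv <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      if (is.nan(pv)) 1 else pv  # fully tied groups carry no evidence
    } else {
      NA_real_
    }
    tibble::tibble(genotype = g, n_disease = length(x),
                   n_control = length(y), pval = p, testable = testable)
  })
  dplyr::bind_rows(out)
}
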