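#' Cis-eQTL scan by per-variant linear regression
#'
#' For every variant-gene pair, fits expression ~ dosage + covariates by
#' least squares (covariates are projected out once, then each variant is
#' tested against the residuals) and reports the slope, its standard error
#' and the two-sided p-value. Dosages are standardized by default so that
#' slopes of proxies of a single causal variant scale as `r` times the
#' causal slope regardless of allele-frequency differences. Variants with a
#' single genotype class are excluded with a message. Significance is
#' flagged at `alpha` after Bonferroni correction over all tested pairs.
#'
#' @param dosages Sample-by-variant dosage matrix with variant ids as
#'   column names.
#' @param expression Numeric vector (one gene) or sample-by-gene matrix.
#' @param covariates Optional data frame / matrix of covariates; must be of
#'   full column rank.
#' @param positions Optional named vector of variant positions (carried
#'   into results for deterministic tie-breaking).
#' @param alpha Family-wise significance level (default 0.05).
#' @param standardize Standardize dosages to unit variance (default TRUE).
#' @return Tibble with `variant`, `gene`, `pos`, `slope`, `slope_se`,
#'   `pval`, `pval_bonf`, `significant`, `n`.
#' @export
cis_eqtl_scan <- function(dosages, expression, covariates = NULL,
                          positions = NULL, alpha = 0.05,
                          standardize = TRUE) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  }
  if (is.vector(expression)) expression <- matrix(expression, ncol = 1,
                                                  dimnames = list(NULL, "gene1"))
  expression <- as.matrix(expression)
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("gene", seq_len(ncol(expression)))
  }
  n <- nrow(dosages)
  if (nrow(expression) != n) stop("samples misaligned between inputs")
  z <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    z <- cm
    if (qr(z)$rank < ncol(z)) stop("rank-deficient covariate design")
  }
  qz <- qr(z)
  poly <- apply(dosages, 2, function(x) length(unique(x)) >= 2L)
  if (any(!poly)) {
    message("excluding ", sum(!poly),
            " variant(s) with a single genotype class: ",
            paste(colnames(dosages)[!poly], collapse = ", "))
  }
  dosages <- dosages[, poly, drop = FALSE]
  if (standardize) dosages <- scale(dosages)
  xr <- qr.resid(qz, dosages)
  yr <- qr.resid(qz, expression)
  df <- n - ncol(z) - 1L
  res <- list()
  xss <- colSums(xr^2)
  for (g in colnames(expression)) {
    y <- yr[, g]
    xy <- colSums(xr * y)
    slope <- xy / xss
    rss <- sum(y^2) - slope * xy
    sigma2 <- rss / df
    se <- sqrt(sigma2 / xss)
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
    res[[g]] <- tibble::tibble(
      variant = colnames(dosages), gene = g,
      pos = if (!is.null(positions)) unname(positions[colnames(dosages)]) else NA_real_,
      slope = unname(slope), slope_se = unname(se), pval = unname(p), n = n
    )
  }
  out <- dplyr::bind_rows(res)
  m <- nrow(out)
  out$pval_bonf <- pmin(1, out$pval * m)
  out$significant <- out$pval_bonf < alpha
  out
}

#' Lead (top) eQTL of a gene-tissue result set
#'
#' The variant with the smallest nominal p-value; ties are broken by larger
#' absolute slope, then smaller genomic position, then variant id, so the
#' lead is deterministic.
#'
#' @param results Tibble of eQTL results for one gene-tissue pair.
#' @return The lead variant id.
#' @export
top_eqtl <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) stop("no eQTL results to rank")
  pos <- if ("pos" %in% names(results)) results$pos else rep(NA_real_, nrow(results))
  pos[is.na(pos)] <- Inf
  ord <- order(results$pval, -abs(results$slope), pos, results$variant)
  results$variant[ord[1]]
}

#' Single-causal expectation for a proxy's effect size
#'
#' Under one functional variant and standardized dosages, the population
#' slope of a proxy equals `r` times the causal slope, so its magnitude is
#' `sqrt(r2) * |beta_lead|`.
#'
#' @param r2 r-squared with the lead variant, in `[0, 1]`.
#' @param beta_lead Lead slope.
#' @return Expected absolute slope.
#' @export
expected_beta <- function(r2, beta_lead) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 must lie in [0, 1]")
  sqrt(r2) * abs(beta_lead)
}

#' Effect-size versus LD profile relative to the lead eQTL
#'
#' One row per significant eQTL (the lead included, with r2 = 1 against
#' itself): the variant's r-squared with the lead and its absolute slope,
#' together with the single-causal expectation [expected_beta()]. Points
#' falling well above the expectation mark candidate additional signals.
#'
#' @param results Significant eQTL results for one gene-tissue pair.
#' @param ld An [ld_matrix()] covering all result variants.
#' @param lead Lead variant id (defaults to [top_eqtl()] of `results`).
#' @return Tibble with `variant`, `r2_with_lead`, `abs_beta`,
#'   `expected_beta`.
#' @export
beta_r2_profile <- function(results, ld, lead = top_eqtl(results)) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    return(tibble::tibble(variant = character(0), r2_with_lead = double(0),
                          abs_beta = double(0), expected_beta = double(0)))
  }
  if (!lead %in% results$variant) stop("lead variant not among results")
  missing <- setdiff(results$variant, ld$variant_id)
  if (length(missing)) {
    stop("variant missing from LD matrix: ", paste(missing, collapse = ", "))
  }
  r2 <- ld$r2[results$variant, lead]
  r2[results$variant == lead] <- 1
  beta_lead <- results$slope[results$variant == lead][1]
  tibble::tibble(
    variant = results$variant,
    r2_with_lead = unname(r2),
    abs_beta = abs(results$slope),
    expected_beta = expected_beta(unname(r2), beta_lead)
  )
}

#' Tight-LD clusters of variants
#'
#' Connected components of the graph whose edges join variant pairs with
#' `r2 > r2_min` and `D' > dprime_min` (both strict) — the "tightly linked"
#' grouping used to colour signal clusters.
#'
#' @param variants Variant ids to cluster.
#' @param ld An [ld_matrix()] with both `r2` and `dprime` components.
#' @param r2_min,dprime_min Strict edge thresholds (defaults 0.9 / 0.9).
#' @return Named integer vector of cluster memberships.
#' @export
tight_ld_clusters <- function(variants, ld, r2_min = 0.9, dprime_min = 0.9) {
  missing <- setdiff(variants, ld$variant_id)
  if (length(missing)) {
    stop("variant missing from LD matrix: ", paste(missing, collapse = ", "))
  }
  if (is.null(ld$dprime)) stop("LD matrix lacks a D' component")
  r2 <- ld$r2[variants, variants, drop = FALSE]
  dp <- ld$dprime[variants, variants, drop = FALSE]
  adj <- (r2 > r2_min) & (dp > dprime_min)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), variants)
}

#' Enumerate independent cis-eQTL signals
#'
#' Iteratively seeds signals from the significant eQTLs of one gene-tissue
#' pair. The first signal is the tight-LD cluster of the lead eQTL.
#' Variants with `r2 < independence_r2` to every current lead whose
#' absolute slope exceeds the single-causal expectation (relative to their
#' best-linked lead) by more than `tau` times the first lead's slope
#' magnitude are "more significant than their LD predicts"; the best such
#' variant (smallest p) seeds the next signal. Iteration stops when no
#' excess variant remains.
#'
#' @param results eQTL results for one gene-tissue pair (only rows with
#'   `significant = TRUE` are used; if the flag is absent all rows are).
#' @param ld An [ld_matrix()] with r2 and D' covering the result variants.
#' @param tau Excess margin as a fraction of the first lead's |slope|
#'   (default 0.25).
#' @param independence_r2 Strict upper r2 bound for a variant to be
#'   considered unexplained by existing leads (default 0.5).
#' @param r2_min,dprime_min Tight-cluster thresholds (defaults 0.9).
#' @return A `signal_report`: list with `n_signals`, `leads` and `table`
#'   (per-variant signal index, lead flag, r2 with own lead, observed and
#'   expected |beta|). The table is ordered by variant id, invariant to
#'   input row order.
#' @export
count_signals <- function(results, ld, tau = 0.25, independence_r2 = 0.5,
                          r2_min = 0.9, dprime_min = 0.9) {
  results <- tibble::as_tibble(results)
  if ("significant" %in% names(results)) {
    results <- results[results$significant, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no significant eQTLs to enumerate")
  results <- results[order(results$variant), , drop = FALSE]
  clusters <- tight_ld_clusters(results$variant, ld,
                                r2_min = r2_min, dprime_min = dprime_min)
  signal <- stats::setNames(rep(NA_integer_, nrow(results)), results$variant)
  leads <- character(0)
  first_lead_slope <- NA_real_
  repeat {
    unassigned <- names(signal)[is.na(signal)]
    if (length(unassigned) == 0) break
    if (length(leads) == 0) {
      seed <- top_eqtl(results[results$variant %in% unassigned, , drop = FALSE])
      first_lead_slope <- abs(results$slope[results$variant == seed][1])
    } else {
      r2_to_leads <- ld$r2[unassigned, leads, drop = FALSE]
      max_r2 <- apply(r2_to_leads, 1, max)
      best_lead <- leads[apply(r2_to_leads, 1, which.max)]
      free <- max_r2 < independence_r2
      if (!any(free)) break
      lead_slope <- abs(results$slope[match(best_lead, results$variant)])
      obs <- abs(results$slope[match(unassigned, results$variant)])
      excess <- obs - expected_beta(pmin(max_r2, 1), lead_slope)
      flagged <- unassigned[free & excess > tau * first_lead_slope]
      if (length(flagged) == 0) break
      seed <- top_eqtl(results[results$variant %in% flagged, , drop = FALSE])
    }
    leads <- c(leads, seed)
    members <- names(clusters)[clusters == clusters[seed]]
    members <- intersect(members, names(signal)[is.na(signal)])
    signal[members] <- length(leads)
  }
  ids <- names(signal)
  own_lead <- leads[signal]
  r2_own <- rep(NA_real_, length(signal))
  assigned <- !is.na(signal)
  r2_own[assigned] <- ld$r2[cbind(ids[assigned], own_lead[assigned])]
  r2_own[assigned & ids == own_lead] <- 1
  lead_slope_own <- abs(results$slope[match(own_lead, results$variant)])
  exp_beta <- ifelse(assigned,
                     expected_beta(pmin(r2_own, 1), lead_slope_own),
                     NA_real_)
  tab <- tibble::tibble(
    variant = ids,
    signal = unname(signal),
    is_lead = ids %in% leads,
    r2_with_lead = unname(r2_own),
    abs_beta = abs(results$slope),
    expected_beta = exp_beta
  )
  structure(
    list(n_signals = length(leads), leads = leads, table = tab),
    class = "signal_report"
  )
}

#' @export
print.signal_report <- function(x, ...) {
  cat(sprintf("<signal_report> %d signal(s); leads: %s\n",
              x$n_signals, paste(x$leads, collapse = ", ")))
  invisible(x)
}
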