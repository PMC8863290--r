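#' Allelic-imbalance deviation of an observation
#'
#' The deviation of the observed reference-allele read fraction
#' (`REF_RATIO`) from the expected fraction under balanced allelic
#' expression (`NULL_RATIO`, which absorbs mapping/reference bias).
#'
#' @param ref_count,alt_count Non-negative allele read counts.
#' @param null_ratio Expected reference fraction under the null, in (0, 1).
#' @return Deviation in `[-1, 1]`.
#' @export
aei_deviation <- function(ref_count, alt_count, null_ratio) {
  total <- ref_count + alt_count
  if (any(total <= 0)) stop("zero total count: observation uninformative")
  if (any(null_ratio <= 0 | null_ratio >= 1)) {
    stop("null_ratio must lie in (0, 1)")
  }
  ref_count / total - null_ratio
}

#' Per-sample allelic-imbalance call
#'
#' Two-sided exact binomial test of the reference count against
#' `null_ratio`. Samples with fewer than `min_total` reads are
#' `insufficient`; otherwise the sample is called imbalanced (with the
#' direction of the deviation) when `p < alpha`, else `balanced`.
#'
#' @param ref_count,alt_count Allele read counts (scalars or vectors).
#' @param null_ratio Null reference fraction(s) in (0, 1).
#' @param alpha Per-sample significance level (default 0.05).
#' @param min_total Minimum informative read depth (default 8).
#' @return Character vector in `c("imbalanced_ref_high",
#'   "imbalanced_ref_low", "balanced", "insufficient")`.
#' @export
call_sample_aei <- function(ref_count, alt_count, null_ratio,
                            alpha = 0.05, min_total = 8L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- max(length(ref_count), length(alt_count), length(null_ratio))
  ref_count <- rep_len(ref_count, n)
  alt_count <- rep_len(alt_count, n)
  null_ratio <- rep_len(null_ratio, n)
  vapply(seq_len(n), function(k) {
    total <- ref_count[k] + alt_count[k]
    if (total < min_total) return("insufficient")
    p <- stats::binom.test(ref_count[k], total, p = null_ratio[k])$p.value
    if (p >= alpha) return("balanced")
    if (ref_count[k] / total > null_ratio[k]) "imbalanced_ref_high"
    else "imbalanced_ref_low"
  }, character(1))
}

#' Summarize allelic imbalance for one variant in one tissue
#'
#' Counts per-sample imbalance calls, their direction consistency (the
#' larger of the ref-high and ref-low shares among imbalanced calls) and
#' the median deviation. Tissues with fewer than `min_samples` observations
#' are flagged insufficient. A single balanced sample is also surfaced as
#' `all_imbalanced = FALSE`: a marker at which even one heterozygote shows
#' no imbalance is likely itself non-functional and merely in LD with the
#' functional site — a marker-quality annotation, not a filter.
#'
#' @param obs Tibble of observations for a single variant-tissue cell
#'   (`REF_COUNT`, `ALT_COUNT`, `NULL_RATIO`; `VARIANT_ID`/`TISSUE_ID`
#'   checked for uniqueness when present).
#' @param alpha,min_total Passed to [call_sample_aei()].
#' @param min_samples Minimum samples for the tissue to count (default 5).
#' @return One-row tibble: `variant`, `tissue`, `n_samples`, `n_informative`,
#'   `n_called`, `consistency`, `median_deviation`, `sufficient`,
#'   `all_imbalanced`.
#' @export
summarize_variant_tissue <- function(obs, alpha = 0.05, min_total = 8L,
                                     min_samples = 5L) {
  obs <- tibble::as_tibble(obs)
  for (col in c("VARIANT_ID", "TISSUE_ID")) {
    if (col %in% names(obs) && length(unique(obs[[col]])) > 1L) {
      stop("observations mix more than one ", col)
    }
  }
  calls <- call_sample_aei(obs$REF_COUNT, obs$ALT_COUNT, obs$NULL_RATIO,
                           alpha = alpha, min_total = min_total)
  informative <- calls != "insufficient"
  imb <- calls %in% c("imbalanced_ref_high", "imbalanced_ref_low")
  consistency <- if (any(imb)) {
    max(mean(calls[imb] == "imbalanced_ref_high"),
        mean(calls[imb] == "imbalanced_ref_low"))
  } else {
    NA_real_
  }
  total <- obs$REF_COUNT + obs$ALT_COUNT
  dev <- ifelse(total > 0, obs$REF_COUNT / total - obs$NULL_RATIO, NA_real_)
  tibble::tibble(
    variant = if ("VARIANT_ID" %in% names(obs) && nrow(obs)) obs$VARIANT_ID[1] else NA_character_,
    tissue = if ("TISSUE_ID" %in% names(obs) && nrow(obs)) obs$TISSUE_ID[1] else NA_character_,
    n_samples = nrow(obs),
    n_informative = sum(informative),
    n_called = sum(imb),
    consistency = consistency,
    median_deviation = stats::median(dev, na.rm = TRUE),
    sufficient = nrow(obs) >= min_samples,
    all_imbalanced = sum(informative) > 0 && all(imb[informative])
  )
}

#' LD-stratified control for allelic-imbalance calls
#'
#' Systematic count-level bias (e.g. preferential amplification) affects
#' every site in a region, while true cis-regulatory imbalance tracks the
#' haplotype: it should appear at co-located sites in strong LD with the
#' marker (r2 > 0.9) but not at co-located sites in weak LD (r2 < 0.1).
#' A partner summary is "imbalance-enriched" when its imbalanced fraction
#' `n_called / n_informative` reaches `theta`.
#'
#' @param target Summary row ([summarize_variant_tissue()]) for the marker;
#'   must be `sufficient`.
#' @param strong_partners,weak_partners Tibbles of summaries for co-located
#'   sites in strong and weak LD with the marker.
#' @param theta Enrichment threshold on the imbalanced fraction
#'   (default 0.5).
#' @return `"true_aei"`, `"suspected_bias"` or `"inconclusive"`.
#' @export
ld_stratified_control <- function(target, strong_partners, weak_partners,
                                  theta = 0.5) {
  if (!isTRUE(target$sufficient[1])) {
    stop("target summary must be sufficient (n_samples >= min_samples)")
  }
  enriched <- function(s) {
    s <- tibble::as_tibble(s)
    if (nrow(s) == 0) return(logical(0))
    frac <- ifelse(s$n_informative > 0, s$n_called / s$n_informative, 0)
    frac >= theta
  }
  strong <- enriched(strong_partners)
  weak <- enriched(weak_partners)
  if (length(strong) == 0 || length(weak) == 0) return("inconclusive")
  strong_major <- mean(strong) > 0.5
  weak_major <- mean(weak) > 0.5
  if (weak_major) return("suspected_bias")
  if (strong_major) return("true_aei")
  "inconclusive"
}
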