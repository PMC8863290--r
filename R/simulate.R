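#' Simulate a founder-mosaic haplotype panel
#'
#' Generates phased chromosomes organised in LD blocks. Each block carries
#' `k` derived founder haplotypes in addition to the ancestral all-reference
#' haplotype; every chromosome independently copies one of these `k + 1`
#' classes per block. Class draws are independent across blocks, so
#' within-block LD is high (few haplotype classes) while cross-block LD is
#' at chance level. With `k = 1` a block has exactly two haplotype classes
#' and every polymorphic pair within it is in perfect LD (r2 = 1).
#'
#' Founder alleles at each variant are resampled (up to `max_retries`) until
#' the empirical minor-allele frequency falls inside `maf_range`; an
#' unsatisfiable constraint raises an error naming the variant.
#'
#' @param n_samples Number of diploid samples (>= 2); 2 * n_samples
#'   chromosomes are emitted.
#' @param block_spec List of `c(n_variants, n_founders)` pairs, one per
#'   block.
#' @param maf_range Admissible minor-allele frequency interval, within
#'   (0, 0.5].
#' @param seed Integer seed; a fixed seed yields byte-identical panels.
#' @param chrom Chromosome label for emitted variants.
#' @param start_pos Position of the first variant (1-based).
#' @param spacing_bp Spacing between adjacent variants within a block.
#' @param block_gap_bp Gap between the last variant of a block and the first
#'   of the next.
#' @param max_retries Per-variant founder-allele resampling budget.
#' @return A [haplotype_panel()] whose variant table carries a `block`
#'   column with the generating block index.
#' @export
simulate_haplotypes <- function(n_samples, block_spec,
                                maf_range = c(0.05, 0.5), seed = 1L,
                                chrom = "chr1", start_pos = 1e6L,
                                spacing_bp = 2000L, block_gap_bp = 500000L,
                                max_retries = 200L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (length(block_spec) == 0) stop("block_spec must be non-empty")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  set.seed(seed)
  n_chrom <- 2L * n_samples
  cols <- list()
  blocks <- integer(0)
  pos <- integer(0)
  cur <- as.integer(start_pos)
  v_idx <- 0L
  for (b in seq_along(block_spec)) {
    len <- as.integer(block_spec[[b]][1])
    k <- as.integer(block_spec[[b]][2])
    if (len < 1L || k < 1L) stop("each block needs >= 1 variant and founder")
    # class 0 = ancestral haplotype; classes 1..k = derived founders
    class_of <- sample.int(k + 1L, n_chrom, replace = TRUE) - 1L
    class_n <- tabulate(class_of + 1L, nbins = k + 1L)
    for (v in seq_len(len)) {
      v_idx <- v_idx + 1L
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        founder_allele <- stats::rbinom(k, 1L, 0.5)
        freq <- sum(class_n[-1L] * founder_allele) / n_chrom
        maf <- min(freq, 1 - freq)
        if (freq > 0 && freq < 1 && maf >= maf_range[1] && maf <= maf_range[2]) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not satisfy maf_range [%g, %g] for variant v%04d after %d retries",
          maf_range[1], maf_range[2], v_idx, max_retries
        ))
      }
      allele_by_class <- c(0L, founder_allele)
      cols[[v_idx]] <- allele_by_class[class_of + 1L]
      blocks[v_idx] <- b
      pos[v_idx] <- cur
      cur <- cur + as.integer(spacing_bp)
    }
    cur <- cur + as.integer(block_gap_bp)
  }
  h <- do.call(cbind, cols)
  variants <- tibble::tibble(
    variant_id = sprintf("v%04d", seq_len(v_idx)),
    chrom = chrom,
    pos = pos,
    ref = "A",
    alt = "G",
    block = blocks
  )
  haplotype_panel(h, variants)
}

#' Simulate tissue expression with planted additive cis effects
#'
#' For each target gene, the expected expression of a sample with dosage
#' \eqn{g \in \{0,1,2\}} at causal variant \eqn{c} is
#' \eqn{\mu (1 + \sum_c \delta_c (g_c - 1))} plus Gaussian noise, i.e.
#' genotype-class means \eqn{\mu(1-\delta), \mu, \mu(1+\delta)} for a single
#' causal variant — an additive allelic effect expressed as a fraction of
#' the median expression level. Genes without a causal specification are
#' noise around \eqn{\mu}.
#'
#' @param dosages Sample-by-variant dosage matrix (see [panel_dosages()]).
#' @param causal_spec Named list: for each target gene id, a list with
#'   `variants` (variant ids), `delta` (fractional effect per variant,
#'   recycled, each >= 0) and optional `mu` (median expression, default
#'   `mu`).
#' @param genes Character vector of gene ids to emit; defaults to the names
#'   of `causal_spec`.
#' @param mu Baseline median expression for genes without their own `mu`.
#' @param noise_sd Gaussian residual standard deviation (> 0).
#' @param seed Integer seed.
#' @return Numeric matrix samples x genes.
#' @export
simulate_expression <- function(dosages, causal_spec, genes = names(causal_spec),
                                mu = 10, noise_sd = 1, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(seed)
  n <- nrow(dosages)
  if (is.null(genes)) stop("no genes requested")
  out <- matrix(0, n, length(genes), dimnames = list(rownames(dosages), genes))
  for (g in genes) {
    spec <- causal_spec[[g]]
    gmu <- if (!is.null(spec$mu)) spec$mu else mu
    mean_g <- rep(gmu, n)
    if (!is.null(spec) && length(spec$variants)) {
      delta <- rep(spec$delta, length.out = length(spec$variants))
      if (any(delta < 0)) stop("delta must be >= 0")
      missing <- setdiff(spec$variants, colnames(dosages))
      if (length(missing)) {
        stop("causal variant absent from genotypes: ",
             paste(missing, collapse = ", "))
      }
      for (kk in seq_along(spec$variants)) {
        gvec <- dosages[, spec$variants[kk]]
        mean_g <- mean_g + gmu * delta[kk] * (gvec - 1)
      }
    }
    out[, g] <- mean_g + stats::rnorm(n, 0, noise_sd)
  }
  out
}

#' Simulate allele-specific read counts at heterozygous sites
#'
#' Read depth is negative-binomial; the reference-allele count is binomial
#' with success probability
#' \eqn{p = \rho x / (\rho x + (1-\rho)(1-x))} where \eqn{x = a/(1+a)} is
#' the expression share of the reference-haplotype allele under allelic
#' fold-change \eqn{a}, and \eqn{\rho} is the multiplicative reference
#' (mapping) bias. The emitted `NULL_RATIO` is the value of \eqn{p} at
#' \eqn{a = 1}, i.e. \eqn{\rho}: bias alone produces zero expected deviation
#' of `REF_RATIO` from `NULL_RATIO`.
#'
#' @param n_het Number of heterozygous samples to emit.
#' @param afc Allelic fold-change `a > 0` (reference over alternate
#'   haplotype expression).
#' @param rho Reference bias in (0, 1).
#' @param depth_mean,depth_dispersion Negative-binomial read-depth
#'   parameters (mean and `size`); depth 0 rows are emitted but flagged
#'   `uninformative`.
#' @param null_rho Value of the bias used to compute the emitted
#'   `NULL_RATIO`; defaults to `rho`. Setting it away from `rho` emulates a
#'   mis-calibrated null (unabsorbed count-level bias).
#' @param variant_id,tissue_id,sample_prefix Identifiers for the emitted
#'   rows.
#' @param seed Integer seed.
#' @return Tibble with columns `SAMPLE_ID`, `TISSUE_ID`, `VARIANT_ID`,
#'   `REF_COUNT`, `ALT_COUNT`, `REF_RATIO`, `NULL_RATIO`, `uninformative`.
#' @export
simulate_ase <- function(n_het, afc = 1, rho = 0.5,
                         depth_mean = 50, depth_dispersion = 5,
                         null_rho = rho,
                         variant_id = "rs0", tissue_id = "TISSUE",
                         sample_prefix = "S", seed = 1L) {
  if (afc <= 0) stop("allelic fold-change must be positive")
  if (rho <= 0 || rho >= 1) stop("reference bias rho must lie in (0, 1)")
  set.seed(seed)
  depth <- stats::rnbinom(n_het, mu = depth_mean, size = depth_dispersion)
  x <- afc / (1 + afc)
  p <- rho * x / (rho * x + (1 - rho) * (1 - x))
  ref <- stats::rbinom(n_het, depth, p)
  tibble::tibble(
    SAMPLE_ID = paste0(sample_prefix, seq_len(n_het)),
    TISSUE_ID = tissue_id,
    VARIANT_ID = variant_id,
    REF_COUNT = ref,
    ALT_COUNT = depth - ref,
    REF_RATIO = ifelse(depth > 0, ref / depth, NA_real_),
    NULL_RATIO = null_rho,
    uninformative = depth == 0L
  )
}
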