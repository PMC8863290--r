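#' Construct a phased haplotype panel
#'
#' A haplotype panel holds phased chromosomes (two rows per diploid sample)
#' over biallelic variants coded 0 (reference) / 1 (alternate). It is the
#' substrate for all linkage-disequilibrium computations.
#'
#' @param haplotypes Integer matrix in \{0,1\}; rows are chromosomes (an even
#'   number), columns are variants. No missing values are allowed.
#' @param variants Data frame with one row per column of `haplotypes`,
#'   containing at least `variant_id`; `chrom`, `pos`, `ref`, `alt` are
#'   carried when present.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, variants) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) {
    stop("haplotype panel must have an even number of chromosome rows")
  }
  if (anyNA(haplotypes)) stop("haplotype panel must not contain missing calls")
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype alleles must be coded 0/1")
  }
  variants <- tibble::as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    stop("`variants` must contain a variant_id column")
  }
  if (nrow(variants) != ncol(haplotypes)) {
    stop("variant table and haplotype matrix disagree on variant count")
  }
  colnames(haplotypes) <- variants$variant_id
  structure(
    list(haplotypes = haplotypes, variants = variants),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d samples (%d chromosomes) x %d variants\n",
    nrow(x$haplotypes) / 2L, nrow(x$haplotypes), ncol(x$haplotypes)
  ))
  invisible(x)
}

#' Collapse a phased panel to per-sample dosages
#'
#' @param panel A [haplotype_panel()].
#' @return Integer matrix of alternate-allele dosages (0/1/2), one row per
#'   sample, columns named by variant id.
#' @export
panel_dosages <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$haplotypes
  odd <- seq(1L, nrow(h), by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(d) <- paste0("S", seq_along(odd))
  d
}

resolve_variant_index <- function(panel, i) {
  if (is.character(i)) {
    idx <- match(i, panel$variants$variant_id)
    if (anyNA(idx)) stop("variant not present in panel: ", i[is.na(idx)][1])
    return(idx)
  }
  as.integer(i)
}

two_locus_freqs <- function(a, b) {
  p_ab <- mean(a == 1L & b == 1L)
  p_a <- mean(a == 1L)
  p_b <- mean(b == 1L)
  list(p_ab = p_ab, p_a = p_a, p_b = p_b, d = p_ab - p_a * p_b)
}

#' Squared allelic correlation from phased haplotypes
#'
#' With haplotype frequency \eqn{p_{AB}} and allele frequencies
#' \eqn{p_A, p_B}: \eqn{D = p_{AB} - p_A p_B} and
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}.
#'
#' @param panel A [haplotype_panel()].
#' @param i,j Variant ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
r2_phased <- function(panel, i, j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  i <- resolve_variant_index(panel, i)
  j <- resolve_variant_index(panel, j)
  a <- panel$haplotypes[, i]
  b <- panel$haplotypes[, j]
  f <- two_locus_freqs(a, b)
  den <- f$p_a * (1 - f$p_a) * f$p_b * (1 - f$p_b)
  if (den == 0) {
    stop("r2 undefined: monomorphic variant among ",
         panel$variants$variant_id[i], ", ", panel$variants$variant_id[j])
  }
  min(1, f$d^2 / den)
}

#' Normalized linkage-disequilibrium coefficient D'
#'
#' \eqn{D' = |D| / D_{max}} where \eqn{D_{max} = \min(p_A p_b, p_a p_B)} for
#' \eqn{D > 0} and \eqn{\min(p_A p_B, p_a p_b)} for \eqn{D < 0}.
#'
#' @inheritParams r2_phased
#' @return D' in `[0, 1]`.
#' @export
d_prime <- function(panel, i, j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  i <- resolve_variant_index(panel, i)
  j <- resolve_variant_index(panel, j)
  a <- panel$haplotypes[, i]
  b <- panel$haplotypes[, j]
  f <- two_locus_freqs(a, b)
  p_a <- f$p_a; p_b <- f$p_b
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("D' undefined: monomorphic variant among ",
         panel$variants$variant_id[i], ", ", panel$variants$variant_id[j])
  }
  if (f$d == 0) return(0)
  dmax <- if (f$d > 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  min(1, abs(f$d) / dmax)
}

#' Unphased r-squared from genotype dosages
#'
#' `method = "em"` estimates the four haplotype frequencies by
#' expectation-maximization over the double-heterozygote phase ambiguity and
#' plugs them into the phased formula; `method = "composite"` is the squared
#' Pearson correlation of dosages. Missing dosages are pairwise-deleted; an
#' informative-sample floor guards against tiny overlaps.
#'
#' @param g1,g2 Numeric vectors of alternate-allele dosages in \{0,1,2\},
#'   `NA` allowed.
#' @param method `"em"` (default) or `"composite"`.
#' @param min_informative Minimum number of complete pairs (default 20).
#' @param max_iter,tol EM controls.
#' @return r-squared in `[0, 1]`. For the EM method the result carries an
#'   attribute `ambiguous = TRUE` when every informative pair is a double
#'   heterozygote (the likelihood is symmetric and the returned solution is a
#'   boundary choice).
#' @export
r2_unphased <- function(g1, g2, method = c("em", "composite"),
                        min_informative = 20L, max_iter = 1000L, tol = 1e-12) {
  method <- match.arg(method)
  if (length(unique(g1[!is.na(g1)])) < 2L ||
      length(unique(g2[!is.na(g2)])) < 2L) {
    stop("r2 undefined: variant with a single dosage class")
  }
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < min_informative) {
    stop("fewer than ", min_informative, " informative sample pairs (", n, ")")
  }
  if (method == "composite") {
    return(stats::cor(g1, g2)^2)
  }
  em_haplotype_freqs(g1, g2, max_iter = max_iter, tol = tol)
}

# EM over the 3x3 genotype table; haplotypes 11, 10, 01, 00 (allele at locus
# 1, allele at locus 2). Only the (1,1) genotype cell has ambiguous phase.
em_haplotype_freqs <- function(g1, g2, max_iter = 1000L, tol = 1e-12) {
  n <- length(g1)
  cnt <- matrix(0, 3, 3)
  for (k in seq_len(n)) cnt[g1[k] + 1L, g2[k] + 1L] <- cnt[g1[k] + 1L, g2[k] + 1L] + 1
  n_chrom <- 2 * n
  # fixed haplotype counts contributed by unambiguous genotypes
  fixed <- c(h11 = 0, h10 = 0, h01 = 0, h00 = 0)
  add <- function(fixed, hap, times) { fixed[hap] <- fixed[hap] + times; fixed }
  for (a in 0:2) for (b in 0:2) {
    m <- cnt[a + 1L, b + 1L]
    if (m == 0 || (a == 1L && b == 1L)) next
    # every genotype pair except the double het resolves to a unique
    # haplotype pair; h counts (11, 10, 01, 00) per individual
    h <- c(0, 0, 0, 0)
    if (a == 0L) { h[3] <- b; h[4] <- 2 - b }
    else if (a == 2L) { h[1] <- b; h[2] <- 2 - b }
    else { # a == 1, b != 1
      if (b == 0L) { h <- c(0, 1, 0, 1) }
      else { h <- c(1, 0, 1, 0) } # b == 2
    }
    fixed <- fixed + m * h
  }
  dh <- cnt[2, 2] # double heterozygotes: either 11/00 or 10/01
  p <- rep(0.25, 4)
  if (dh == 0) {
    p <- (fixed) / n_chrom
  } else {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      num <- p[1] * p[4]
      den <- num + p[2] * p[3]
      w <- if (den > 0) num / den else 0.5
      new_p <- (fixed + dh * c(w, 1 - w, 1 - w, w)) / n_chrom
      if (max(abs(new_p - p)) < tol) { p <- new_p; converged <- TRUE; break }
      p <- new_p
    }
    if (!converged) {
      stop("EM did not converge after ", max_iter, " iterations")
    }
  }
  p_a <- p[1] + p[2]
  p_b <- p[1] + p[3]
  den <- p_a * (1 - p_a) * p_b * (1 - p_b)
  if (den <= 0) stop("r2 undefined after EM: boundary allele frequency")
  d <- p[1] - p_a * p_b
  out <- min(1, unname(d^2 / den))
  all_dh <- sum(cnt) == dh
  if (all_dh) attr(out, "ambiguous") <- TRUE
  out
}

#' Pairwise LD matrix for a panel
#'
#' @param panel A [haplotype_panel()].
#' @param dprime Also compute the D' matrix (default `TRUE`).
#' @return An `ld_matrix`: list with `variant_id`, symmetric `r2` and
#'   optionally `dprime` matrices with unit diagonal.
#' @export
ld_matrix <- function(panel, dprime = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- ncol(panel$haplotypes)
  ids <- panel$variants$variant_id
  r2 <- diag(1, m)
  dp <- if (dprime) diag(1, m) else NULL
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      r2[i, j] <- r2[j, i] <- r2_phased(panel, i, j)
      if (dprime) dp[i, j] <- dp[j, i] <- d_prime(panel, i, j)
    }
  }
  dimnames(r2) <- list(ids, ids)
  if (dprime) dimnames(dp) <- list(ids, ids)
  structure(list(variant_id = ids, r2 = r2, dprime = dp), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants (r2%s)\n", length(x$variant_id),
              if (is.null(x$dprime)) "" else " + D'"))
  invisible(x)
}

#' Hierarchical LD clustering of variants
#'
#' Average-linkage hierarchical clustering on distance `1 - r2`, the ordering
#' used to render LD heatmaps of tissue-specific eQTLs.
#'
#' @param ld An [ld_matrix()].
#' @param cut_height Distance at which the dendrogram is cut into clusters
#'   (default 0.5, i.e. mean within-cluster r2 above 0.5).
#' @return List with `order` (leaf ordering of variant ids), `cluster`
#'   (named integer membership vector) and the `hclust` object.
#' @export
ld_cluster <- function(ld, cut_height = 0.5) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (length(ld$variant_id) < 2L) {
    stop("LD clustering needs at least 2 variants")
  }
  d <- stats::as.dist(1 - ld$r2)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  list(order = ld$variant_id[hc$order], cluster = cl, hclust = hc)
}

#' Write an LD matrix as TSV
#'
#' Square matrix with a variant-id header row and first column.
#'
#' @param ld An [ld_matrix()].
#' @param path Output file.
#' @param which `"r2"` or `"dprime"`.
#' @return `path`, invisibly.
#' @export
write_ld_tsv <- function(ld, path, which = c("r2", "dprime")) {
  which <- match.arg(which)
  m <- ld[[which]]
  if (is.null(m)) stop("requested component not present in ld_matrix")
  df <- data.frame(variant_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix from TSV
#'
#' @param path File written by [write_ld_tsv()].
#' @return An `ld_matrix` with the `r2` slot populated.
#' @export
read_ld_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  structure(list(variant_id = ids, r2 = m, dprime = NULL), class = "ld_matrix")
}
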