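#' Write a haplotype panel as VCF
#'
#' VCF v4.2 with biallelic SNVs and per-sample GT fields; phased (`|`) by
#' default, or unphased dosage-style genotypes (`/`).
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file (plain text).
#' @param phased Emit phased genotypes (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, phased = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$haplotypes
  v <- panel$variants
  n_samp <- nrow(h) / 2L
  sep <- if (phased) "|" else "/"
  odd <- seq(1L, nrow(h), by = 2L)
  a1 <- h[odd, , drop = FALSE]
  a2 <- h[odd + 1L, , drop = FALSE]
  if (!phased) { # order alleles so unphased genotypes are canonical
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    a1 <- lo; a2 <- hi
  }
  gt <- matrix(paste0(a1, sep, a2), nrow = n_samp)
  samples <- paste0("S", seq_len(n_samp))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=relociate",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ref <- if ("ref" %in% names(v)) v$ref else "A"
  alt <- if ("alt" %in% names(v)) v$alt else "G"
  body <- paste(v$chrom, v$pos, v$variant_id, ref, alt, ".", "PASS", ".",
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased haplotype panel from VCF
#'
#' Parses GT fields via `vcfR`; every record must be phased (`|`) and
#' biallelic with no missing calls.
#'
#' @param path VCF file.
#' @return A [haplotype_panel()].
#' @export
read_haplotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes found; a haplotype panel requires phased GT")
  }
  if (anyNA(gt) || any(gt == ".")) stop("missing genotype calls in VCF")
  left <- substr(gt, 1, 1)
  right <- substr(gt, 3, 3)
  n_var <- nrow(gt)
  n_samp <- ncol(gt)
  h <- matrix(0L, nrow = 2L * n_samp, ncol = n_var)
  h[seq(1L, 2L * n_samp, by = 2L), ] <- t(matrix(as.integer(left), n_var))
  h[seq(2L, 2L * n_samp, by = 2L), ] <- t(matrix(as.integer(right), n_var))
  fix <- vcfR::getFIX(vcf)
  variants <- tibble::tibble(
    variant_id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  haplotype_panel(h, variants)
}

#' Write transcript models as GTF
#'
#' Emits gene, transcript and exon features with `gene_id`, `transcript_id`
#' and `transcript_biotype` attributes. Each transcript is written with two
#' terminal exons so that the span between them is intronic.
#'
#' @param transcripts Tibble with `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  tdf <- tibble::as_tibble(transcripts)
  lines <- character(0)
  attr_str <- function(gene, tx = NULL, biotype = NULL) {
    s <- sprintf('gene_id "%s";', gene)
    if (!is.null(tx)) s <- paste0(s, sprintf(' transcript_id "%s";', tx))
    if (!is.null(biotype)) {
      s <- paste0(s, sprintf(' transcript_biotype "%s";', biotype))
    }
    s
  }
  for (g in unique(tdf$gene_id)) {
    sub <- tdf[tdf$gene_id == g, , drop = FALSE]
    lines <- c(lines, paste(
      sub$chrom[1], "relociate", "gene", min(sub$start), max(sub$end),
      ".", sub$strand[1], ".", attr_str(g), sep = "\t"
    ))
    for (k in seq_len(nrow(sub))) {
      r <- sub[k, ]
      lines <- c(lines, paste(
        r$chrom, "relociate", "transcript", r$start, r$end, ".",
        r$strand, ".", attr_str(g, r$transcript_id, r$biotype), sep = "\t"
      ))
      exon_len <- max(1L, min(1000L, as.integer((r$end - r$start) %/% 4)))
      exons <- rbind(
        c(r$start, r$start + exon_len),
        c(r$end - exon_len, r$end)
      )
      for (e in seq_len(nrow(exons))) {
        lines <- c(lines, paste(
          r$chrom, "relociate", "exon", exons[e, 1], exons[e, 2], ".",
          r$strand, ".", attr_str(g, r$transcript_id, r$biotype), sep = "\t"
        ))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Imports via `rtracklayer` and keeps transcript features; accepts both the
#' `transcript_biotype` and `transcript_type` attribute dialects. Feature
#' types other than transcript are skipped with a message.
#'
#' @param path GTF file.
#' @return Tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype` (1-based inclusive coordinates).
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  is_tx <- df$type == "transcript"
  skipped <- setdiff(unique(as.character(df$type)), "transcript")
  if (length(skipped)) {
    message("skipping non-transcript feature types: ",
            paste(skipped, collapse = ", "))
  }
  df <- df[is_tx, , drop = FALSE]
  biotype <- if ("transcript_biotype" %in% names(df)) {
    df$transcript_biotype
  } else if ("transcript_type" %in% names(df)) {
    df$transcript_type
  } else {
    stop("GTF carries neither transcript_biotype nor transcript_type")
  }
  tibble::tibble(
    transcript_id = df$transcript_id,
    gene_id = df$gene_id,
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = df$start,
    end = df$end,
    biotype = biotype
  )
}

#' Read a GTEx-dialect QTL table
#'
#' Expects columns `variant_id`, `rs_id`, `gene_id`, `tissue`, `slope`,
#' `pval_nominal`, `qtl_type`.
#'
#' @param path TSV file.
#' @return Tibble of QTL records.
#' @export
read_qtl_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  needed <- c("variant_id", "gene_id", "tissue", "slope", "pval_nominal")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("QTL table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Read an allele-specific expression table
#'
#' Expects the GTEx ASE matrix columns `SAMPLE_ID`, `TISSUE_ID`,
#' `VARIANT_ID`, `REF_COUNT`, `ALT_COUNT`, `REF_RATIO`, `NULL_RATIO`.
#'
#' @param path TSV file.
#' @return Tibble of ASE observations.
#' @export
read_ase_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  needed <- c("SAMPLE_ID", "TISSUE_ID", "VARIANT_ID", "REF_COUNT",
              "ALT_COUNT", "NULL_RATIO")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("ASE table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a GWAS hit table
#'
#' Expects columns `locus`, `rs_id`, `chrom`, `pos`, `effect_allele`, `OR`,
#' `annotated_genes` (semicolon-separated).
#'
#' @param path TSV file.
#' @return Tibble of GWAS hits.
#' @export
read_gwas_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  needed <- c("locus", "rs_id", "annotated_genes")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("GWAS table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}
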