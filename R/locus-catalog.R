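#' Simulate a GWAS locus catalog with known tier structure
#'
#' Builds a miniature genome of GWAS loci whose evidence layout forces a
#' known tier label, together with the QTL tables and transcript models the
#' re-prioritization pipeline consumes, and a planted-truth record for
#' round-trip testing. One locus is emitted per requested tier label:
#'
#' * **Tier 1** — GWAS gene supported by eQTL, sQTL and position; emitted
#'   with two marker SNPs sharing the evidence (a multi-SNP locus).
#' * **Tier 2A** — all GWAS genes supported, one extra gene introduced.
#' * **Tier 2B** — some GWAS genes supported, plus a new gene.
#' * **Tier 2C** — only new genes; GWAS annotation unsupported.
#' * **Tier 3** — no QTL match and no overlapping transcript.
#'
#' @param tiers Character vector of tier labels from
#'   `c("1", "2A", "2B", "2C", "3")`, one locus per entry (repeats
#'   allowed). Empty vector gives an empty, structurally valid catalog.
#' @param seed Integer seed (fixed seed gives identical catalogs).
#' @return List of class `locus_catalog` with tibbles `gwas`, `qtl`,
#'   `transcripts` and `truth`.
#' @export
simulate_locus_catalog <- function(tiers = c("1", "2A", "2B", "2C", "3"),
                                   seed = 1L) {
  tiers <- as.character(tiers)
  bad <- setdiff(tiers, c("1", "2A", "2B", "2C", "3"))
  if (length(bad)) stop("unknown tier label: ", paste(bad, collapse = ", "))
  set.seed(seed)
  gwas <- list(); qtl <- list(); tx <- list(); truth <- list()
  region_span <- 2e6
  for (li in seq_along(tiers)) {
    tier <- tiers[li]
    locus <- sprintf("L%02d", li)
    base <- 1e6 + (li - 1) * region_span
    # three gene slots per locus region, 50 kb each, 100 kb apart
    gene_ids <- paste0("GENE", li, "_", c("A", "B", "C"))
    gene_start <- base + c(0, 150000, 300000)
    gene_end <- gene_start + 50000
    snp_pos <- gene_start[1] + 25000  # inside GENE_A span (intronic)
    rs <- sprintf("rs%d%03d", 100000 + li, 1L)
    gwas_genes <- gene_ids[1]
    evid <- list()  # rows: rs_id, gene, tissue, type
    used_genes <- gene_ids[1]
    if (tier == "1") {
      rs2 <- sprintf("rs%d%03d", 100000 + li, 2L)
      evid <- list(
        c(rs, gene_ids[1], "Liver", "eQTL"),
        c(rs, gene_ids[1], "Whole Blood", "eQTL"),
        c(rs, gene_ids[1], "Lung", "sQTL"),
        c(rs2, gene_ids[1], "Whole Blood", "eQTL")
      )
      snps <- tibble::tibble(rs_id = c(rs, rs2),
                             pos = c(snp_pos, snp_pos + 4000))
    } else if (tier == "2A") {
      evid <- list(
        c(rs, gene_ids[1], "Liver", "eQTL"),
        c(rs, gene_ids[2], "Liver", "eQTL")
      )
      used_genes <- gene_ids[1:2]
      snps <- tibble::tibble(rs_id = rs, pos = snp_pos)
    } else if (tier == "2B") {
      gwas_genes <- gene_ids[1:2]
      evid <- list(
        c(rs, gene_ids[1], "Liver", "eQTL"),
        c(rs, gene_ids[3], "Artery - Aorta", "sQTL")
      )
      used_genes <- gene_ids
      snps <- tibble::tibble(rs_id = rs, pos = snp_pos)
    } else if (tier == "2C") {
      # marker sits between genes; evidence implicates only GENE_B
      snp_pos <- gene_end[1] + 50000
      evid <- list(c(rs, gene_ids[2], "Liver", "eQTL"))
      used_genes <- gene_ids[1:2]
      snps <- tibble::tibble(rs_id = rs, pos = snp_pos)
    } else { # tier 3: intergenic marker, no QTL
      snp_pos <- gene_end[3] + 200000
      gwas_genes <- gene_ids[1:2]
      snps <- tibble::tibble(rs_id = rs, pos = snp_pos)
    }
    gwas[[li]] <- tibble::tibble(
      locus = locus,
      rs_id = snps$rs_id,
      chrom = "chr1",
      pos = as.integer(snps$pos),
      effect_allele = "G",
      OR = round(stats::runif(nrow(snps), 1.03, 1.25), 2),
      annotated_genes = paste(gwas_genes, collapse = ";")
    )
    if (length(evid)) {
      ev <- do.call(rbind, evid)
      pos_of <- snps$pos[match(ev[, 1], snps$rs_id)]
      qtl[[li]] <- tibble::tibble(
        variant_id = sprintf("chr1_%d_A_G_b38", as.integer(pos_of)),
        rs_id = ev[, 1],
        gene_id = ev[, 2],
        tissue = ev[, 3],
        slope = round(stats::rnorm(nrow(ev), 0, 0.4), 3),
        pval_nominal = signif(10^stats::runif(nrow(ev), -20, -8), 3),
        qtl_type = ev[, 4]
      )
    }
    # two transcripts per gene: one coding, one non-coding
    tx[[li]] <- tibble::tibble(
      transcript_id = paste0(rep(gene_ids, each = 2), ".t", 1:2),
      gene_id = rep(gene_ids, each = 2),
      chrom = "chr1",
      strand = rep(c("+", "-", "+"), each = 2)[seq_len(2 * length(gene_ids))],
      start = rep(as.integer(gene_start), each = 2),
      end = rep(as.integer(gene_end), each = 2) - rep(c(0L, 5000L), 3),
      biotype = rep(c("protein_coding", "lincRNA"), 3)
    )
    # ground truth: evidence genes = QTL genes union positionally overlapped
    qtl_genes <- if (length(evid)) unique(do.call(rbind, evid)[, 2]) else character(0)
    overlap <- gene_ids[snps$pos[1] >= gene_start & snps$pos[1] <= gene_end]
    truth[[li]] <- tibble::tibble(
      locus = locus,
      true_tier = tier,
      gwas_genes = paste(gwas_genes, collapse = ";"),
      evidence_genes = paste(sort(unique(c(qtl_genes, overlap))), collapse = ";"),
      snps = paste(snps$rs_id, collapse = ";")
    )
  }
  bind_or_empty <- function(lst, proto) {
    if (length(lst)) dplyr::bind_rows(lst) else proto
  }
  out <- list(
    gwas = bind_or_empty(gwas, tibble::tibble(
      locus = character(), rs_id = character(), chrom = character(),
      pos = integer(), effect_allele = character(), OR = double(),
      annotated_genes = character()
    )),
    qtl = bind_or_empty(qtl, tibble::tibble(
      variant_id = character(), rs_id = character(), gene_id = character(),
      tissue = character(), slope = double(), pval_nominal = double(),
      qtl_type = character()
    )),
    transcripts = bind_or_empty(tx, tibble::tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      biotype = character()
    )),
    truth = bind_or_empty(truth, tibble::tibble(
      locus = character(), true_tier = character(), gwas_genes = character(),
      evidence_genes = character(), snps = character()
    ))
  )
  class(out) <- "locus_catalog"
  out
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("<locus_catalog> %d loci, %d QTL records, %d transcripts\n",
              nrow(x$truth), nrow(x$qtl), nrow(x$transcripts)))
  invisible(x)
}

#' Write a locus catalog to disk
#'
#' Emits `gwas.tsv`, `eqtl.tsv`, `sqtl.tsv`, `genes.gtf` and `truth.json`
#' under `outdir`. Output is byte-identical for identical catalogs.
#'
#' @param catalog A [simulate_locus_catalog()] result.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_locus_catalog <- function(catalog, outdir) {
  stopifnot(inherits(catalog, "locus_catalog"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(catalog$gwas, "gwas.tsv")
  w(catalog$qtl[catalog$qtl$qtl_type == "eQTL", , drop = FALSE], "eqtl.tsv")
  w(catalog$qtl[catalog$qtl$qtl_type == "sQTL", , drop = FALSE], "sqtl.tsv")
  write_gtf(catalog$transcripts, file.path(outdir, "genes.gtf"))
  jsonlite::write_json(catalog$truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(outdir)
}
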