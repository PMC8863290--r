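#' Tier-1 coronary-artery-disease GWAS loci with their regulatory support
#'
#' A transcription of the published evidence for the seven CAD GWAS loci
#' whose GTEx QTL and positional support points exclusively at the
#' GWAS-annotated gene(s): per marker SNP, the annotated gene set, the
#' tissues in which the SNP is a significant eQTL or sQTL for a gene, and
#' the gene whose transcript span (intron included) contains the SNP.
#' Locus 32 carries two marker SNPs (rs11203042 and rs1412444, both
#' assigned to LIPA); locus 08 is annotated with both ABCG8 and ABCG5,
#' of which only ABCG8 has QTL or positional support.
#'
#' @return List with tibbles `gwas` (locus, rs_id, annotated_genes),
#'   `qtl` (rs_id, gene_id, tissue, qtl_type, plus placeholder
#'   variant_id/slope/pval_nominal fields for interface compatibility) and
#'   `positional` (rs_id, gene_id for intronic overlap).
#' @export
cad_tier1_catalog <- function() {
  gwas <- tibble::tribble(
    ~locus, ~rs_id, ~annotated_genes,
    "08", "rs6544713", "ABCG8;ABCG5",
    "16", "rs6903956", "ADTRP",
    "32", "rs11203042", "LIPA",
    "32", "rs1412444", "LIPA",
    "38", "rs9319428", "FLT1",
    "42", "rs17514846", "FURIN;FES",
    "54", "rs7212798", "BCAS3",
    "57", "rs11830157", "KSR2"
  )

  q <- function(rs, gene, type, tissues) {
    tibble::tibble(rs_id = rs, gene_id = gene, tissue = tissues,
                   qtl_type = type)
  }
  qtl <- dplyr::bind_rows(
    q("rs6544713", "ABCG8", "eQTL", "Colon - Transverse"),
    q("rs6903956", "ADTRP", "sQTL", "Testis"),
    q("rs11203042", "LIPA", "eQTL", c(
      "Adipose - Subcutaneous", "Adipose - Visceral", "Colon - Transverse",
      "Heart - Atrial Appendage", "Lung", "Pancreas", "Skin - Sun Exposed",
      "Spleen", "Thyroid", "Whole Blood"
    )),
    q("rs11203042", "LIPA", "sQTL", c(
      "Adipose - Subcutaneous", "Cells - Fibroblasts", "Lung"
    )),
    q("rs1412444", "LIPA", "eQTL", c(
      "Adipose - Subcutaneous", "Adipose - Visceral", "Adrenal Gland",
      "Artery - Aorta", "Brain - Cerebellum", "Colon - Sigmoid",
      "Colon - Transverse", "Heart - Atrial Appendage",
      "Heart - Left Ventricle", "Lung", "Muscle - Skeletal",
      "Nerve - Tibial", "Pancreas", "Skin - Not Sun Exposed",
      "Skin - Sun Exposed", "Spleen", "Stomach", "Thyroid", "Whole Blood"
    )),
    q("rs1412444", "LIPA", "sQTL", c(
      "Adipose - Subcutaneous", "Adipose - Visceral", "Adrenal Gland",
      "Artery - Aorta", "Artery - Tibial", "Brain - Spinal Cord",
      "Breast - Mammary", "Cells - Fibroblasts", "Cells - Lymphocytes",
      "Lung", "Nerve - Tibial", "Pancreas", "Skin - Sun Exposed",
      "Small Intestine", "Spleen", "Stomach", "Whole Blood"
    )),
    q("rs9319428", "FLT1", "eQTL", "Nerve - Tibial"),
    q("rs17514846", "FES", "eQTL", c(
      "Adipose - Subcutaneous", "Adipose - Visceral", "Adrenal Gland",
      "Artery - Aorta", "Artery - Tibial", "Cells - Fibroblasts",
      "Colon - Transverse", "Esophagus - Muscularis",
      "Heart - Atrial Appendage", "Lung", "Nerve - Tibial", "Pancreas",
      "Pituitary", "Prostate", "Skin - Not Sun Exposed",
      "Skin - Sun Exposed", "Stomach", "Thyroid", "Whole Blood"
    )),
    q("rs17514846", "FES", "sQTL", c(
      "Adipose - Subcutaneous", "Adipose - Visceral", "Artery - Aorta",
      "Artery - Tibial", "Breast - Mammary", "Cells - Fibroblasts",
      "Colon - Sigmoid", "Esophagus - Gastroesophageal Junction",
      "Esophagus - Muscularis", "Heart - Atrial Appendage",
      "Heart - Left Ventricle", "Lung", "Minor Salivary Gland",
      "Nerve - Tibial", "Prostate", "Skin - Not Sun Exposed",
      "Skin - Sun Exposed", "Small Intestine", "Spleen", "Thyroid",
      "Whole Blood"
    )),
    q("rs17514846", "FURIN", "eQTL", c(
      "Artery - Aorta", "Artery - Tibial", "Esophagus - Muscularis"
    ))
  )
  qtl$variant_id <- paste0(qtl$rs_id, "_vid")
  qtl$slope <- NA_real_
  qtl$pval_nominal <- NA_real_

  positional <- tibble::tribble(
    ~rs_id, ~gene_id,
    "rs6544713", "ABCG8",
    "rs6903956", "ADTRP",
    "rs11203042", "LIPA",
    "rs1412444", "LIPA",
    "rs9319428", "FLT1",
    "rs17514846", "FURIN",
    "rs7212798", "BCAS3",
    "rs11830157", "KSR2"
  )
  list(gwas = gwas, qtl = qtl, positional = positional)
}

#' Tier classification of the bundled Tier-1 worked example
#'
#' Runs exact QTL matching, evidence union over each locus's markers and
#' [assign_tier()] on [cad_tier1_catalog()].
#'
#' @return Tibble of per-locus tier assignments (one row per distinct
#'   locus).
#' @export
cad_tier1_assignments <- function() {
  cat <- cad_tier1_catalog()
  out <- list()
  for (loc in unique(cat$gwas$locus)) {
    sub <- cat$gwas[cat$gwas$locus == loc, , drop = FALSE]
    g <- unique(unlist(strsplit(sub$annotated_genes, ";", fixed = TRUE)))
    rec <- match_qtls(sub, cat$qtl)
    pos_genes <- cat$positional$gene_id[cat$positional$rs_id %in% sub$rs_id]
    ev <- build_evidence(loc, rec, unique(pos_genes))
    out[[loc]] <- assign_tier(g, ev$gene_id, locus = loc)
  }
  dplyr::bind_rows(out)
}
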