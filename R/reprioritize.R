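#' Normalized variant identity
#'
#' Builds the `chr{N}_{pos}_{ref}_{alt}_b38` identity string used for exact
#' QTL matching.
#'
#' @param chrom,pos,ref,alt Vectors of coordinates and alleles.
#' @return Character vector of identities.
#' @export
variant_identity <- function(chrom, pos, ref, alt) {
  sprintf("%s_%d_%s_%s_b38", chrom, as.integer(pos), ref, alt)
}

#' Exact-match QTL lookup for a locus's marker variants
#'
#' Returns only QTL records whose variant identity equals a locus variant
#' exactly — by rsID when available, otherwise by normalized
#' `chrom_pos_ref_alt` identity. No LD-based relaxation happens here; proxy
#' expansion is a separate, explicit step ([expand_markers()]).
#'
#' @param locus_variants Tibble with `rs_id` and/or `chrom`, `pos`, `ref`,
#'   `alt` per marker variant.
#' @param qtl Tibble of QTL records (`variant_id`, `rs_id`, `gene_id`,
#'   `tissue`, `slope`, `pval_nominal`, `qtl_type`).
#' @return Tibble of matching QTL records with a `matched_rs` column naming
#'   the locus variant each record matched.
#' @export
match_qtls <- function(locus_variants, qtl) {
  lv <- tibble::as_tibble(locus_variants)
  qtl <- tibble::as_tibble(qtl)
  out <- list()
  for (k in seq_len(nrow(lv))) {
    rs <- if ("rs_id" %in% names(lv)) lv$rs_id[k] else NA_character_
    if (!is.na(rs) && nzchar(rs)) {
      hit <- !is.na(qtl$rs_id) & qtl$rs_id == rs
    } else if (all(c("chrom", "pos", "ref", "alt") %in% names(lv)) &&
               !is.na(lv$pos[k])) {
      vid <- variant_identity(lv$chrom[k], lv$pos[k], lv$ref[k], lv$alt[k])
      hit <- qtl$variant_id == vid
      rs <- vid
    } else {
      stop("unresolvable variant identity at locus row ", k,
           ": no rsID and no coordinates")
    }
    if (any(hit)) {
      m <- qtl[hit, , drop = FALSE]
      m$matched_rs <- rs
      out[[length(out) + 1L]] <- m
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    dplyr::mutate(qtl[0, , drop = FALSE], matched_rs = character(0))
  }
}

#' Aggregate per-locus gene evidence
#'
#' Unions evidence over all marker variants of a locus. Each implicated
#' gene is annotated with its eQTL tissues, sQTL tissues and a positional
#' flag; the `added_by` bookkeeping attributes a gene to the first source
#' that implicates it in the order eQTL, then sQTL, then position, with
#' multi-source genes labelled `combination`.
#'
#' @param locus Locus label.
#' @param qtl_records Matched QTL records for this locus (from
#'   [match_qtls()]).
#' @param positional_genes Character vector of genes overlapped by any of
#'   the locus's variants (from [positional_candidate_genes()]).
#' @return An evidence table: tibble with `locus`, `gene_id`,
#'   `eqtl_tissues`, `sqtl_tissues` (semicolon-joined), `positional`,
#'   `added_by`, `n_sources`.
#' @export
build_evidence <- function(locus, qtl_records, positional_genes = character(0)) {
  qtl_records <- tibble::as_tibble(qtl_records)
  genes <- sort(unique(c(qtl_records$gene_id, positional_genes)))
  if (length(genes) == 0) {
    return(tibble::tibble(
      locus = character(0), gene_id = character(0),
      eqtl_tissues = character(0), sqtl_tissues = character(0),
      positional = logical(0), added_by = character(0), n_sources = integer(0)
    ))
  }
  rows <- lapply(genes, function(g) {
    e <- qtl_records[qtl_records$gene_id == g &
                       qtl_records$qtl_type == "eQTL", , drop = FALSE]
    s <- qtl_records[qtl_records$gene_id == g &
                       qtl_records$qtl_type == "sQTL", , drop = FALSE]
    pos_flag <- g %in% positional_genes
    sources <- c(eQTL = nrow(e) > 0, sQTL = nrow(s) > 0, position = pos_flag)
    n_src <- sum(sources)
    added <- if (n_src > 1L) "combination" else names(sources)[sources]
    tibble::tibble(
      locus = locus, gene_id = g,
      eqtl_tissues = paste(sort(unique(e$tissue)), collapse = ";"),
      sqtl_tissues = paste(sort(unique(s$tissue)), collapse = ";"),
      positional = pos_flag,
      added_by = added,
      n_sources = n_src
    )
  })
  dplyr::bind_rows(rows)
}

#' Tier classification of a GWAS locus
#'
#' Compares the GWAS-annotated gene set `G` with the evidence gene set `Q`
#' (genes supported by eQTL, sQTL or transcript overlap):
#'
#' * `Q` empty — **Tier 3**: annotation neither supported nor negated.
#' * `Q` non-empty and a subset of `G` — **Tier 1**: evidence supports
#'   GWAS genes only.
#' * otherwise (new genes present): `G` a subset of `Q` — **Tier 2A** (all
#'   GWAS genes supported); some overlap — **Tier 2B**; no overlap —
#'   **Tier 2C**. An empty `G` with non-empty `Q` is the degenerate
#'   all-new-genes case and is labelled 2C.
#'
#' @param gwas_genes Character vector `G` of GWAS-annotated genes.
#' @param evidence_genes Character vector `Q` of evidence-supported genes.
#' @param locus Optional locus label carried into the result.
#' @return Tibble with `locus`, `tier`, `supported_genes`, `new_genes`.
#' @export
assign_tier <- function(gwas_genes, evidence_genes, locus = NA_character_) {
  g <- unique(gwas_genes[!is.na(gwas_genes) & nzchar(gwas_genes)])
  q <- unique(evidence_genes[!is.na(evidence_genes) & nzchar(evidence_genes)])
  supported <- intersect(g, q)
  new_genes <- setdiff(q, g)
  tier <- if (length(q) == 0) {
    "3"
  } else if (length(new_genes) == 0) {
    "1"
  } else if (length(g) > 0 && all(g %in% q)) {
    "2A"
  } else if (length(supported) > 0) {
    "2B"
  } else {
    "2C"
  }
  tibble::tibble(
    locus = locus,
    tier = tier,
    supported_genes = paste(sort(supported), collapse = ";"),
    new_genes = paste(sort(new_genes), collapse = ";")
  )
}

#' Proxy-marker expansion for unannotated loci
#'
#' Finds panel variants within a window around the query that are in strong
#' LD with it (`r2 > r2_min`, strict), the expansion used to rescue loci
#' whose GWAS marker has no QTL or positional annotation. The query itself
#' is always returned.
#'
#' @param variant Variant id present in `panel`.
#' @param panel A [haplotype_panel()].
#' @param window Total window width in bp centred on the query (default
#'   1 Mb, i.e. +/- 500 kb).
#' @param r2_min Strict lower r2 bound for proxies (default 0.8).
#' @return Character vector of variant ids (query first).
#' @export
expand_markers <- function(variant, panel, window = 1e6, r2_min = 0.8) {
  stopifnot(inherits(panel, "haplotype_panel"))
  idx <- match(variant, panel$variants$variant_id)
  if (is.na(idx)) stop("variant not present in panel: ", variant)
  qpos <- panel$variants$pos[idx]
  half <- window / 2
  cand <- which(
    panel$variants$chrom == panel$variants$chrom[idx] &
      abs(panel$variants$pos - qpos) <= half &
      seq_len(nrow(panel$variants)) != idx
  )
  keep <- cand[vapply(cand, function(j) {
    r2 <- tryCatch(r2_phased(panel, idx, j), error = function(e) NA_real_)
    !is.na(r2) && r2 > r2_min
  }, logical(1))]
  c(variant, panel$variants$variant_id[keep])
}

#' Classify every locus of a catalog
#'
#' End-to-end convenience: exact QTL matching, positional overlap, evidence
#' union and tier assignment per locus.
#'
#' @param gwas GWAS hit table (`locus`, `rs_id`, `chrom`, `pos`,
#'   `annotated_genes` semicolon-separated).
#' @param qtl QTL record table.
#' @param transcripts Transcript models for positional evidence (may be
#'   `NULL` to skip).
#' @return List with `assignments` (one row per locus) and `evidence`
#'   (gene-level evidence rows over all loci).
#' @export
reprioritize_loci <- function(gwas, qtl, transcripts = NULL) {
  gwas <- tibble::as_tibble(gwas)
  assignments <- list(); evidence <- list()
  for (loc in unique(gwas$locus)) {
    sub <- gwas[gwas$locus == loc, , drop = FALSE]
    g <- unique(unlist(strsplit(sub$annotated_genes, ";", fixed = TRUE)))
    rec <- match_qtls(sub, qtl)
    pos_genes <- character(0)
    if (!is.null(transcripts) && all(c("chrom", "pos") %in% names(sub))) {
      pos_genes <- unique(unlist(lapply(seq_len(nrow(sub)), function(k) {
        positional_candidate_genes(sub$chrom[k], sub$pos[k], transcripts)
      })))
    }
    ev <- build_evidence(loc, rec, pos_genes)
    evidence[[loc]] <- ev
    assignments[[loc]] <- assign_tier(g, ev$gene_id, locus = loc)
  }
  list(
    assignments = dplyr::bind_rows(assignments),
    evidence = dplyr::bind_rows(evidence)
  )
}

#' Tally tier assignments and gene-addition sources
#'
#' @param assignments Tibble from [reprioritize_loci()] (or rows from
#'   [assign_tier()]).
#' @param evidence Optional evidence table; when given, newly added genes
#'   (absent from the GWAS annotation) are tallied by their `added_by`
#'   source, with multi-source genes under `combination`.
#' @return List with `tier_counts` (named vector over 1/2A/2B/2C/3) and,
#'   when `evidence` is supplied, `added_by_source`.
#' @export
summarize_tiers <- function(assignments, evidence = NULL) {
  lv <- c("1", "2A", "2B", "2C", "3")
  counts <- table(factor(assignments$tier, levels = lv))
  out <- list(tier_counts = stats::setNames(as.integer(counts), lv))
  if (!is.null(evidence) && nrow(evidence) > 0) {
    new_map <- strsplit(assignments$new_genes, ";", fixed = TRUE)
    names(new_map) <- assignments$locus
    ev <- evidence
    is_new <- mapply(function(loc, gene) gene %in% new_map[[loc]],
                     ev$locus, ev$gene_id)
    src <- factor(ev$added_by[is_new],
                  levels = c("eQTL", "sQTL", "position", "combination"))
    out$added_by_source <- stats::setNames(
      as.integer(table(src)), levels(src)
    )
  }
  out
}
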