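# Controlled biotype vocabularies used to call a transcript coding or
# non-coding. Stored in normalized form (lower case, underscores); the
# classifier is total on the union and rejects anything else.
.coding_biotypes <- c(
  "igc_gene", "igd_gene", "ig_gene", "igj_gene", "iglv_gene", "igm_gene",
  "igv_gene", "igz_gene", "nonsense_mediated_decay", "nontranslating_cds",
  "non_stop_decay", "polymorphic_pseudogene", "trc_gene", "trd_gene",
  "trj_gene", "protein_coding", "tec"
)

.noncoding_biotypes <- c(
  "disrupted_domain", "igc_pseudogene", "igj_pseudogene", "ig_pseudogene",
  "igv_pseudogene", "processed_pseudogene", "transcribed_processed_pseudogene",
  "transcribed_unitary_pseudogene", "transcribed_unprocessed_pseudogene",
  "translated_processed_pseudogene", "trj_pseudogene",
  "unprocessed_pseudogene", "unitary_pseudogene", "3prime_overlapping_ncrna",
  "ambiguous_orf", "antisense", "antisense_rna", "lincrna", "ncrna_host",
  "processed_transcript", "sense_intronic", "sense_overlapping", "lncrna",
  "retained_intron", "mirna", "mirna_pseudogene", "miscrna",
  "miscrna_pseudogene", "mt_rrna", "mt_trna", "rrna", "scrna", "snlrna",
  "snorna", "snrna", "trna", "trna_pseudogene", "rrna_pseudogene"
)

normalize_biotype <- function(biotype) {
  gsub("[ -]+", "_", tolower(trimws(biotype)))
}

#' Classify a transcript biotype as coding or non-coding
#'
#' Biotypes are matched, after normalization of case and space/underscore
#' variation, against the controlled protein-coding and non-coding
#' vocabularies (Ensembl/BioMart designations such as `protein_coding`,
#' `nonsense_mediated_decay` and `polymorphic_pseudogene` on the coding
#' side; pseudogenes, `lincRNA`, `antisense`, small RNAs and the like on the
#' non-coding side). A biotype in neither list is an error — there is no
#' silent default.
#'
#' @param biotype Character vector of biotype strings.
#' @return Character vector in `c("coding", "noncoding")`.
#' @export
classify_transcript_biotype <- function(biotype) {
  if (length(biotype) == 0 || any(!nzchar(trimws(biotype)))) {
    stop("biotype must be a non-empty string")
  }
  norm <- normalize_biotype(biotype)
  out <- ifelse(norm %in% .coding_biotypes, "coding",
                ifelse(norm %in% .noncoding_biotypes, "noncoding", NA))
  if (anyNA(out)) {
    stop("unknown transcript biotype: ",
         paste(unique(biotype[is.na(out)]), collapse = ", "))
  }
  out
}

#' Coding status of a gene from its transcript biotypes
#'
#' A gene is non-coding only if every one of its transcripts is non-coding;
#' a single coding transcript makes the gene coding.
#'
#' @param biotypes Character vector of the gene's transcript biotypes
#'   (at least one).
#' @return `"coding"` or `"noncoding"`.
#' @export
gene_coding_status <- function(biotypes) {
  if (length(biotypes) == 0) stop("gene must have at least one transcript")
  cls <- classify_transcript_biotype(biotypes)
  if (all(cls == "noncoding")) "noncoding" else "coding"
}

#' Gene-level summary of transcript models
#'
#' @param transcripts Transcript tibble as from [read_transcript_models()].
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `start`, `end`
#'   (span over transcripts), `n_transcripts`, `coding_status`.
#' @export
gene_models <- function(transcripts) {
  transcripts <- tibble::as_tibble(transcripts)
  dplyr::summarise(
    dplyr::group_by(transcripts, .data$gene_id),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    n_transcripts = dplyr::n(),
    coding_status = gene_coding_status(.data$biotype),
    .groups = "drop"
  )
}

#' Positional candidate genes for a variant
#'
#' Returns every gene with at least one transcript whose span (introns
#' included) covers the variant position, regardless of strand — so
#' antisense-overlapping genes are returned too. Interval ends are
#' inclusive: a variant at the first or last base of a transcript is inside.
#'
#' @param chrom Chromosome of the variant.
#' @param pos 1-based position of the variant.
#' @param transcripts Transcript tibble (`transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, ...).
#' @return Character vector of gene ids (possibly empty), sorted.
#' @export
positional_candidate_genes <- function(chrom, pos, transcripts) {
  transcripts <- tibble::as_tibble(transcripts)
  hit <- transcripts$chrom == chrom &
    transcripts$start <= pos & pos <= transcripts$end
  sort(unique(transcripts$gene_id[hit]))
}
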