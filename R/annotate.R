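# Site annotation: genomic-feature classification, synonymous/nonsynonymous
# codon effect, and assembly of the fixed 17-column annotation table.

# Feature precedence, highest first. A site in a coding exon reports as
# exonic even when it also lies within the splice window (exonic wins the
# tie); upstream and downstream share a rank, with upstream chosen on the
# rare tie of a site in both flanks of different transcripts.
FEATURE_LEVELS <- c("exonic", "splicing", "ncRNA", "utr5", "utr3",
                    "intronic", "upstream", "downstream", "intergenic")

#' The 17 annotation columns, in output order
#'
#' @return character vector of column names.
#' @export
table_columns <- function() {
  c("Chr", "Pos", "In DNA", "In RNA", "Gene", "Evidence level", "Strand",
    "Source", "PubMed ID", "Alu", "Data reference", "ENSG", "ENST", "ENSE",
    "Genomic feature", "Synonymous or nonsynonymous", "Noncoding RNA")
}

#' Classify the genomic feature at one or more positions
#'
#' Each position is tested against every transcript and resolved to a single
#' label by fixed precedence: exonic (in a coding exon / CDS), splicing
#' (within 2 bp of an exon-intron junction, unless the site is itself in a
#' CDS), ncRNA (in an exon of a transcript without coding annotation), 5'UTR,
#' 3'UTR, intronic, upstream / downstream (the 1-kb flank 5' of the TSS / 3'
#' of the transcription end, strand-aware), intergenic. The ncRNA flag is
#' reported separately: it is TRUE whenever any transcript overlapping the
#' position is non-coding, whatever the primary label.
#'
#' @param chrom chromosome label (scalar).
#' @param pos integer vector of 1-based positions.
#' @param models a \code{transcript_models} object.
#' @return data frame with one row per position: \code{pos},
#'   \code{primary_feature}, \code{gene_names}, \code{ensg}, \code{enst},
#'   \code{ense} (comma-joined, lexically sorted), \code{ncrna_flag}.
#' @export
classify_genomic_feature <- function(chrom, pos, models) {
  idx <- models$index
  tx <- models$tx
  n <- length(pos)
  if (!chrom %in% tx$chrom && n > 0 && nrow(tx) > 0) {
    warning(sprintf("chromosome '%s' has no annotated transcripts", chrom))
  }
  q <- GenomicRanges::GRanges(rep(chrom, n), IRanges::IRanges(pos, pos))

  hit_any <- function(gr) {
    out <- logical(n)
    h <- ov_hits(q, gr)
    out[unique(S4Vectors::queryHits(h))] <- TRUE
    out
  }
  in_cds <- hit_any(idx$cds)
  in_splice <- hit_any(idx$splice)
  in_nc_exon <- hit_any(idx$nc_exon)
  in_utr5 <- hit_any(idx$utr5)
  in_utr3 <- hit_any(idx$utr3)
  in_span <- hit_any(idx$span)
  in_up <- hit_any(idx$upstream)
  in_down <- hit_any(idx$downstream)

  feature <- rep("intergenic", n)
  feature[in_down] <- "downstream"
  feature[in_up] <- "upstream"
  feature[in_span] <- "intronic"
  feature[in_utr3] <- "utr3"
  feature[in_utr5] <- "utr5"
  feature[in_nc_exon] <- "ncRNA"
  feature[in_splice] <- "splicing"
  feature[in_cds] <- "exonic"

  # Transcripts informing the identifier columns: those containing the
  # position, or (for flank-only sites) those whose flank contains it.
  span_h <- ov_hits(q, idx$span)
  up_h <- ov_hits(q, idx$upstream)
  down_h <- ov_hits(q, idx$downstream)
  exon_h <- ov_hits(q, idx$exon)

  tx_sets <- vector("list", n)
  add_hits <- function(sets, h, gr) {
    qh <- S4Vectors::queryHits(h)
    ti <- S4Vectors::mcols(gr)$tx_i[S4Vectors::subjectHits(h)]
    for (k in seq_along(qh)) sets[[qh[k]]] <- c(sets[[qh[k]]], ti[k])
    sets
  }
  tx_sets <- add_hits(tx_sets, span_h, idx$span)
  flank_sets <- vector("list", n)
  flank_sets <- add_hits(flank_sets, up_h, idx$upstream)
  flank_sets <- add_hits(flank_sets, down_h, idx$downstream)

  ense_sets <- vector("list", n)
  qh <- S4Vectors::queryHits(exon_h)
  eid <- S4Vectors::mcols(idx$exon)$exon_id[S4Vectors::subjectHits(exon_h)]
  for (k in seq_along(qh)) ense_sets[[qh[k]]] <- c(ense_sets[[qh[k]]], eid[k])

  res <- data.frame(pos = pos, primary_feature = feature,
                    gene_names = "", ensg = "", enst = "", ense = "",
                    ncrna_flag = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ti <- unique(tx_sets[[i]])
    if (length(ti) == 0 && feature[i] %in% c("upstream", "downstream")) {
      ti <- unique(flank_sets[[i]])
    }
    if (length(ti) > 0) {
      res$gene_names[i] <- join_csv(sort(unique(tx$gene_name[ti])))
      res$ensg[i] <- join_csv(sort(unique(tx$gene_id[ti])))
      res$enst[i] <- join_csv(sort(unique(tx$transcript_id[ti])))
    }
    res$ense[i] <- join_csv(sort(unique(ense_sets[[i]])))
    span_ti <- unique(tx_sets[[i]])
    res$ncrna_flag[i] <- length(span_ti) > 0 && any(!tx$coding[span_ti])
  }
  res
}

#' Coding effect of a single-base substitution within one transcript
#'
#' Locates the position within the spliced CDS of the transcript, rebuilds
#' the reference codon from the genome (reverse-complementing on the minus
#' strand), substitutes the edited base, and translates both codons under
#' the standard nuclear genetic code. The input bases are given on the plus
#' (genomic) strand, as in a VCF.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param dna_base,rna_base plus-strand reference and edited base.
#' @param model single-transcript model from \code{\link{transcript_model}}.
#' @param genome genome from \code{\link{read_fasta}}.
#' @return list with \code{status} ("synonymous", "nonsynonymous" or
#'   "not_applicable"), \code{ref_codon}, \code{alt_codon}, \code{ref_aa},
#'   \code{alt_aa}, \code{codon_position} (1-3; NA when not applicable).
#' @export
annotate_coding_effect <- function(chrom, pos, dna_base, rna_base, model,
                                   genome) {
  na_effect <- list(status = "not_applicable", ref_codon = NA_character_,
                    alt_codon = NA_character_, ref_aa = NA_character_,
                    alt_aa = NA_character_, codon_position = NA_integer_)
  cds <- model$cds
  if (nrow(cds) == 0 || chrom != model$tx$chrom) return(na_effect)
  strand <- model$tx$strand

  # Spliced CDS coordinates in transcription order.
  coords <- unlist(lapply(seq_len(nrow(cds)),
                          function(i) cds$start[i]:cds$end[i]))
  if (strand == "-") coords <- rev(coords)
  if (length(coords) %% 3L != 0L) {
    warning(sprintf("CDS length of %s not divisible by 3; coding effect not computed",
                    model$tx$transcript_id))
    return(na_effect)
  }
  i <- match(pos, coords)
  if (is.na(i)) return(na_effect)

  codon_idx <- (i - 1L) %/% 3L
  codon_pos <- (i - 1L) %% 3L + 1L
  codon_coords <- coords[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  plus_bases <- genome_base(genome, chrom, codon_coords)
  ref_codon_bases <- if (strand == "+") plus_bases else
    complement_base(plus_bases)

  genome_ref <- genome_base(genome, chrom, pos)
  if (genome_ref != toupper(dna_base)) {
    warning(sprintf("reference base at %s:%d is %s, not %s; using genome base",
                    chrom, pos, genome_ref, dna_base))
  }
  edited <- if (strand == "+") toupper(rna_base) else
    complement_base(rna_base)
  alt_codon_bases <- ref_codon_bases
  alt_codon_bases[codon_pos] <- edited

  ref_codon <- paste(ref_codon_bases, collapse = "")
  alt_codon <- paste(alt_codon_bases, collapse = "")
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  list(status = if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous",
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, codon_position = codon_pos)
}

# Coding effect for a site against all transcripts whose CDS contains it;
# transcripts are tried in lexical transcript_id order and the first
# applicable result is reported (deterministic across iteration orders).
coding_effect_at <- function(models, genome, chrom, pos, dna_base, rna_base) {
  cds <- models$cds
  hit_tx <- unique(cds$transcript_id[cds$seqname == chrom &
                                       cds$start <= pos & cds$end >= pos])
  for (id in sort(hit_tx)) {
    eff <- suppressWarnings(
      annotate_coding_effect(chrom, pos, dna_base, rna_base,
                             transcript_model(models, id), genome))
    if (eff$status != "not_applicable") return(eff$status)
  }
  ""
}

#' Annotate variant records against the knowledgebase and gene models
#'
#' Produces the 17-column annotation table: one row per input variant found
#' in the knowledgebase (evidence level, strand, tissue sources, PubMed ids,
#' Alu name and data references taken from the matched entry), with genomic
#' feature, coding effect and ncRNA flag computed from the gene models and
#' genome. With \code{keep_novel = TRUE}, variants absent from the
#' knowledgebase are retained with empty evidence columns; their Alu column
#' is then computed directly from \code{repeats}.
#'
#' @param vcf_records data frame from \code{\link{read_vcf}}.
#' @param kb knowledgebase from \code{\link{integrate_resources}} or
#'   \code{\link{read_kb}}.
#' @param models transcript models.
#' @param genome genome sequences.
#' @param repeats repeat intervals (used only for novel sites), or NULL.
#' @param keep_novel keep variants not present in the knowledgebase.
#' @return data frame with the columns of \code{\link{table_columns}}.
#' @export
annotate_sites <- function(vcf_records, kb, models, genome, repeats = NULL,
                           keep_novel = FALSE) {
  v <- vcf_records
  rows <- vector("list", nrow(v))
  kb_key <- site_key(kb$chrom, kb$pos, kb$dna_base, kb$rna_base)

  for (i in seq_len(nrow(v))) {
    key <- site_key(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    j <- match(key, kb_key)
    if (is.na(j) && !keep_novel) next

    feat <- classify_genomic_feature(v$chrom[i], v$pos[i], models)
    effect <- if (feat$primary_feature == "exonic") {
      coding_effect_at(models, genome, v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    } else ""

    if (!is.na(j)) {
      evidence <- kb$evidence_level[j]
      strand <- kb$strand[j]
      source <- kb$tissue_sources[j]
      pubmed <- kb$pubmed_ids[j]
      alu <- kb$alu_name[j]
      dataref <- kb$data_references[j]
    } else {
      evidence <- ""; strand <- ""; source <- ""; pubmed <- ""; dataref <- ""
      alu <- alu_name_at(v$chrom[i], v$pos[i], repeats)
    }
    row <- data.frame(
      v$chrom[i], v$pos[i], v$ref[i], v$alt[i], feat$gene_names, evidence,
      strand, source, pubmed, alu, dataref, feat$ensg, feat$enst, feat$ense,
      feat$primary_feature, effect,
      ifelse(feat$ncrna_flag, "yes", "no"),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    names(row) <- table_columns()
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_annotation_df()
  rownames(out) <- NULL
  out
}

empty_annotation_df <- function() {
  out <- as.data.frame(matrix(character(0), nrow = 0,
                              ncol = length(table_columns())),
                       stringsAsFactors = FALSE)
  names(out) <- table_columns()
  out$Pos <- integer(0)
  out
}

#' Write / read the annotation table as CSV
#'
#' The CSV carries the exact 17-column header.
#'
#' @param rows annotation data frame from \code{\link{annotate_sites}}.
#' @param path file path.
#' @export
write_annotation_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  extra <- setdiff(table_columns(), colnames(df))
  if (length(extra) > 0) {
    format_error(sprintf("annotation CSV missing column(s): %s",
                         paste(extra, collapse = ", ")), path)
  }
  for (col in setdiff(colnames(df), "Pos")) df[[col]][is.na(df[[col]])] <- ""
  df$Pos <- as.integer(df$Pos)
  df
}
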