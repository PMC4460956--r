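# Shared fixtures and independent brute-force oracles. The oracles apply
# the published definitions literally, position by position, with none of
# the package's interval-index machinery.

# ---- literal genomic-feature classifier -------------------------------------
# tx_layout: the transcripts table of generate_locus() (exon/CDS coordinate
# lists as comma-joined strings), or a data frame built by hand in the same
# shape.
int_list <- function(s) if (nzchar(s)) as.integer(strsplit(s, ",")[[1]]) else integer(0)

oracle_tx_feature <- function(p, t) {
  ex_s <- int_list(t$exon_starts); ex_e <- int_list(t$exon_ends)
  cds_s <- int_list(t$cds_starts); cds_e <- int_list(t$cds_ends)
  in_cds <- any(cds_s <= p & p <= cds_e)
  if (in_cds) return("exonic")
  # splice: within 2 bp of an internal exon/intron junction, either side
  if (length(ex_s) > 1) {
    for (k in seq_len(length(ex_s) - 1)) {
      donor <- ex_e[k]; acceptor <- ex_s[k + 1]
      if ((p >= donor - 1 && p <= donor + 2) ||
          (p >= acceptor - 2 && p <= acceptor + 1)) return("splicing")
    }
  }
  in_exon <- any(ex_s <= p & p <= ex_e)
  if (in_exon && !t$coding) return("ncRNA")
  if (in_exon && t$coding) {
    cds_lo <- min(cds_s); cds_hi <- max(cds_e)
    if (p < cds_lo) return(if (t$strand == "+") "utr5" else "utr3")
    if (p > cds_hi) return(if (t$strand == "+") "utr3" else "utr5")
  }
  if (p >= t$start && p <= t$end) return("intronic")
  tss <- if (t$strand == "+") t$start else t$end
  tes <- if (t$strand == "+") t$end else t$start
  if (t$strand == "+") {
    if (p >= tss - 1000 && p <= tss - 1) return("upstream")
    if (p >= tes + 1 && p <= tes + 1000) return("downstream")
  } else {
    if (p >= tss + 1 && p <= tss + 1000) return("upstream")
    if (p >= tes - 1000 && p <= tes - 1) return("downstream")
  }
  NA_character_
}

ORACLE_PRECEDENCE <- c("exonic", "splicing", "ncRNA", "utr5", "utr3",
                       "intronic", "upstream", "downstream")

oracle_classify <- function(p, tx_layout) {
  labels <- vapply(seq_len(nrow(tx_layout)), function(i)
    oracle_tx_feature(p, tx_layout[i, , drop = FALSE]), character(1))
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return("intergenic")
  ORACLE_PRECEDENCE[min(match(labels, ORACLE_PRECEDENCE))]
}

# ---- translate-and-compare codon oracle -------------------------------------
oracle_codon_status <- function(ref_codon, codon_pos, alt_base) {
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_base
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
}

ALL_CODONS <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T"), paste0)),
                              c("A", "C", "G", "T"), paste0))

# ---- small hand-built fixtures ----------------------------------------------
# A plus-strand coding transcript with a chosen middle codon, for targeted
# codon-effect cases: CDS = ATG | codon | TAA starting at position 11.
codon_fixture <- function(codon) {
  seq <- paste0("GGGGGGGGGG", "ATG", codon, "TAA", "GGGGGGGGGG")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "1"
  gtf <- data.frame(
    seqname = "1", feature = c("exon", "CDS"), start = c(1L, 11L),
    end = c(nchar(seq), 19L), strand = "+", frame = NA_integer_,
    gene_id = "ENSG1", transcript_id = "ENST1", exon_id = c("ENSE1", NA),
    gene_name = "G1", biotype = "protein_coding", stringsAsFactors = FALSE)
  models <- build_transcript_models(gtf)
  list(genome = genome, models = models,
       model = transcript_model(models, "ENST1"))
}

# The minus-strand mirror of codon_fixture: same sense-strand CDS, written
# reverse-complemented into the genome with the transcript on "-".
codon_fixture_minus <- function(codon) {
  sense <- paste0("ATG", codon, "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  seq <- paste0("GGGGGGGGGG", rc, "GGGGGGGGGG")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "1"
  gtf <- data.frame(
    seqname = "1", feature = c("exon", "CDS"), start = c(1L, 11L),
    end = c(nchar(seq), 19L), strand = "-", frame = NA_integer_,
    gene_id = "ENSG1", transcript_id = "ENST1", exon_id = c("ENSE1", NA),
    gene_name = "G1", biotype = "protein_coding", stringsAsFactors = FALSE)
  models <- build_transcript_models(gtf)
  list(genome = genome, models = models,
       model = transcript_model(models, "ENST1"))
}

# Write a small VCF from vectors; returns the path.
write_test_vcf <- function(path, chrom, pos, ref, alt, id = ".") {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste(chrom, pos, id, ref, alt, ".", "PASS", ".",
                     sep = "\t")),
             path)
  path
}

# Write a resource TSV with the documented header.
write_test_resource <- function(path, chrom, pos, in_dna, in_rna,
                                strand = "+", source = "brain",
                                pubmed = "12345678") {
  df <- data.frame(chrom = chrom, pos = pos, in_dna = in_dna,
                   in_rna = in_rna, strand = strand, source = source,
                   pubmed = pubmed, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Default-registry resource record data frame built in code.
make_resource_records <- function(resource_id, chrom, pos, dna, rna,
                                  strand = "+", tissue = "brain",
                                  pubmed = "11111111") {
  data.frame(resource_id = resource_id, chrom = chrom, pos = pos,
             dna_base = dna, rna_base = rna, strand = strand,
             tissue_sources = tissue, pubmed_ids = pubmed,
             stringsAsFactors = FALSE)
}
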