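make_two_exon_gtf <- function(strand = "+") {
  a <- function(id, e = NA) list(gene_id = "ENSG1", transcript_id = "ENST1",
                                 exon_id = e)
  data.frame(
    seqname = "1",
    feature = c("exon", "exon", "CDS", "CDS"),
    start = c(1001L, 2001L, 1101L, 2001L),
    end = c(1400L, 2300L, 1400L, 2200L),
    strand = strand, frame = NA_integer_,
    gene_id = "ENSG1", transcript_id = "ENST1",
    exon_id = c("ENSE1", "ENSE2", NA, NA),
    gene_name = "G1", biotype = "protein_coding", stringsAsFactors = FALSE)
}

test_that("transcript models capture exons, CDS and strand-aware TSS", {
  m <- build_transcript_models(make_two_exon_gtf("+"))
  expect_equal(nrow(m$tx), 1)
  expect_equal(nrow(m$exons), 2)
  expect_equal(nrow(m$cds), 2)
  expect_true(m$tx$coding)
  expect_equal(m$tx$tss, 1001L)
  expect_equal(m$tx$tes, 2300L)

  minus <- build_transcript_models(make_two_exon_gtf("-"))
  expect_equal(minus$tx$tss, 2300L)   # 5'-most transcribed base on minus
  expect_equal(minus$tx$tes, 1001L)

  nc <- make_two_exon_gtf("+")
  nc <- nc[nc$feature == "exon", ]
  nc$biotype <- "lincRNA"
  mnc <- build_transcript_models(nc)
  expect_false(mnc$tx$coding)

  expect_warning(build_transcript_models(within(nc, transcript_id <- NA)),
                 "without transcript_id")
})

test_that("point queries find overlapping transcripts but not intron exons", {
  m <- build_transcript_models(make_two_exon_gtf("+"))
  expect_equal(transcripts_at(m, "1", 1700)$transcript_id, "ENST1")  # intron
  expect_equal(nrow(transcripts_at(m, "1", 500)), 0)
  feat <- classify_genomic_feature("1", 1700, m)
  expect_equal(feat$primary_feature, "intronic")
  expect_equal(feat$ense, "")                   # no exon at an intron point
  in_exon <- classify_genomic_feature("1", 1050, m)
  expect_equal(in_exon$ense, "ENSE1")
})

test_that("splice window is exactly 2 bp around exon/intron junctions", {
  m <- build_transcript_models(make_two_exon_gtf("+"))
  # exon1 is UTR from 1001-1100, CDS 1101-1400; junction after 1400
  cls <- function(p) classify_genomic_feature("1", p, m)$primary_feature
  expect_equal(cls(1401), "splicing")  # 1 bp into the intron
  expect_equal(cls(1402), "splicing")  # 2 bp into the intron
  expect_equal(cls(1403), "intronic")  # 3 bp into the intron
  expect_equal(cls(1999), "splicing")  # 2 bp before the acceptor
  expect_equal(cls(2000), "splicing")
  expect_equal(cls(1400), "exonic")    # exonic-coding wins at the boundary
  expect_equal(cls(2001), "exonic")
})

test_that("flanks are exactly 1 kb and strand-aware; UTR sides follow strand", {
  m <- build_transcript_models(make_two_exon_gtf("+"))
  cls <- function(p, mm = m) classify_genomic_feature("1", p, mm)$primary_feature
  expect_equal(cls(1), "upstream")      # tss - 1000
  expect_equal(cls(1000), "upstream")
  expect_equal(cls(2301), "downstream")
  expect_equal(cls(3300), "downstream") # tes + 1000
  expect_equal(cls(3301), "intergenic")
  expect_equal(cls(1050), "utr5")       # exon1 before the CDS on plus strand
  expect_equal(cls(2250), "utr3")

  minus <- build_transcript_models(make_two_exon_gtf("-"))
  expect_equal(cls(2301, minus), "upstream")
  expect_equal(cls(3301, minus), "intergenic")
  expect_equal(cls(1, minus), "downstream")
  expect_equal(cls(1050, minus), "utr3")  # same exon region flips on minus
})

test_that("noncoding transcripts classify as ncRNA and set the flag", {
  nc <- make_two_exon_gtf("+")
  nc <- nc[nc$feature == "exon", ]
  nc$biotype <- "lincRNA"
  m <- build_transcript_models(nc)
  feat <- classify_genomic_feature("1", 1050, m)
  expect_equal(feat$primary_feature, "ncRNA")
  expect_true(feat$ncrna_flag)
  intron <- classify_genomic_feature("1", 1700, m)
  expect_equal(intron$primary_feature, "intronic")
  expect_true(intron$ncrna_flag)
})

test_that("unknown chromosomes classify intergenic with a warning", {
  m <- build_transcript_models(make_two_exon_gtf("+"))
  expect_warning(feat <- classify_genomic_feature("99", 100, m),
                 "no annotated transcripts")
  expect_equal(feat$primary_feature, "intergenic")
})

test_that("classifier equals the literal brute-force oracle at every locus position", {
  locus <- generate_locus(101, n_transcripts = 5, coding_fraction = 0.6)
  models <- build_transcript_models(locus$gtf)
  chrom_len <- length(locus$genome[[1]])
  positions <- seq_len(chrom_len)
  got <- classify_genomic_feature("1", positions, models)$primary_feature
  want <- vapply(positions, oracle_classify, character(1),
                 tx_layout = locus$transcripts)
  expect_gte(chrom_len, 5000)
  expect_equal(got, want)
})

test_that("feature precedence is invariant to transcript order", {
  locus <- generate_locus(17, n_transcripts = 4)
  gtf <- locus$gtf
  shuffled <- gtf[rev(seq_len(nrow(gtf))), ]
  m1 <- build_transcript_models(gtf)
  m2 <- build_transcript_models(shuffled)
  pos <- seq(1, length(locus$genome[[1]]), by = 17)
  f1 <- classify_genomic_feature("1", pos, m1)
  f2 <- classify_genomic_feature("1", pos, m2)
  expect_equal(f1, f2)
})

test_that("coding effect matches the hand case CTT>CTC (Leu>Leu, synonymous)", {
  fx <- codon_fixture("CTT")
  # CDS = ATG CTT TAA at 11..19; codon position 3 of codon 2 is pos 16
  eff <- annotate_coding_effect("1", 16, "T", "C", fx$model, fx$genome)
  expect_equal(eff$status, "synonymous")
  expect_equal(eff$ref_codon, "CTT")
  expect_equal(eff$alt_codon, "CTC")
  expect_equal(eff$ref_aa, "L")
  expect_equal(eff$codon_position, 3L)
})

test_that("all 576 codon substitutions agree with the translate-and-compare oracle", {
  for (codon in ALL_CODONS) {
    fx <- codon_fixture(codon)
    for (cp in 1:3) {
      pos <- 13L + cp  # codon occupies genome 14..16
      ref <- substr(codon, cp, cp)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        eff <- annotate_coding_effect("1", pos, ref, alt, fx$model, fx$genome)
        expect_equal(eff$status, oracle_codon_status(codon, cp, alt),
                     label = sprintf("%s pos%d >%s", codon, cp, alt))
      }
    }
  }
})

test_that("coding effect is strand-consistent", {
  set.seed(3)
  for (codon in sample(setdiff(ALL_CODONS, "NNN"), 12)) {
    plus <- codon_fixture(codon)
    minus <- codon_fixture_minus(codon)
    for (cp in 1:3) {
      ref_sense <- substr(codon, cp, cp)
      for (alt_sense in setdiff(c("A", "C", "G", "T"), ref_sense)) {
        p_eff <- annotate_coding_effect("1", 13L + cp, ref_sense, alt_sense,
                                        plus$model, plus$genome)
        # genome position of sense base cp on the minus-strand fixture:
        # CDS runs 19..11 in transcription order
        g_pos <- 19L - (3L + cp) + 1L
        m_eff <- annotate_coding_effect("1", g_pos,
                                        complement_base(ref_sense),
                                        complement_base(alt_sense),
                                        minus$model, minus$genome)
        expect_equal(m_eff$ref_aa, p_eff$ref_aa)
        expect_equal(m_eff$alt_aa, p_eff$alt_aa)
        expect_equal(m_eff$status, p_eff$status)
      }
    }
  }
})

test_that("coding effect handles non-CDS sites, mismatches and broken frames", {
  fx <- codon_fixture("AAA")
  expect_equal(annotate_coding_effect("1", 5, "G", "A", fx$model,
                                      fx$genome)$status, "not_applicable")
  expect_warning(
    eff <- annotate_coding_effect("1", 15, "C", "G", fx$model, fx$genome),
    "reference base")          # genome has A at 15, caller claimed C
  expect_equal(eff$ref_codon, "AAA")

  # CDS length not divisible by 3: effect refused with a warning
  gtf <- data.frame(seqname = "1", feature = c("exon", "CDS"),
                    start = c(1L, 11L), end = c(30L, 18L), strand = "+",
                    frame = NA_integer_, gene_id = "ENSG1",
                    transcript_id = "ENST1", exon_id = c("ENSE1", NA),
                    gene_name = "G1", biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  broken <- build_transcript_models(gtf)
  expect_warning(
    eff <- annotate_coding_effect("1", 12, "T", "C",
                                  transcript_model(broken, "ENST1"),
                                  fx$genome),
    "divisible by 3")
  expect_equal(eff$status, "not_applicable")
})

test_that("annotate_sites emits the 17-column table and respects keep_novel", {
  fx <- codon_fixture("CTT")
  repeats <- data.frame(chrom = "1", start = 10L, end = 20L, name = "AluSx",
                        family = "SINE/Alu", stringsAsFactors = FALSE)
  kb <- integrate_resources(
    list(make_resource_records("DARNED", "1", 16, "T", "C"),
         make_resource_records("RADAR", "1", 16, "T", "C")),
    repeats)
  vcf <- data.frame(chrom = "1", pos = c(16L, 5L), id = ".",
                    ref = c("T", "G"), alt = c("C", "A"), qual = 50,
                    filter = "PASS", info = ".", stringsAsFactors = FALSE)

  rows <- annotate_sites(vcf, kb, fx$models, fx$genome)
  expect_equal(colnames(rows), table_columns())
  expect_equal(nrow(rows), 1)   # only the knowledgebase-known site
  expect_equal(rows[["Evidence level"]], "C")  # DARNED+RADAR+Alu
  expect_equal(rows[["Alu"]], "AluSx")
  expect_equal(rows[["Genomic feature"]], "exonic")
  expect_equal(rows[["Synonymous or nonsynonymous"]], "synonymous")
  expect_equal(rows[["ENST"]], "ENST1")

  all_rows <- annotate_sites(vcf, kb, fx$models, fx$genome, repeats,
                             keep_novel = TRUE)
  expect_equal(nrow(all_rows), 2)
  novel <- all_rows[all_rows$Pos == 5, ]
  expect_equal(novel[["Evidence level"]], "")
  expect_equal(novel[["Alu"]], "")   # repeat does not cover position 5

  empty <- annotate_sites(vcf[0, ], kb, fx$models, fx$genome)
  expect_equal(nrow(empty), 0)
  expect_equal(colnames(empty), table_columns())
})

test_that("annotation CSV round-trips with the exact header", {
  fx <- codon_fixture("CTT")
  kb <- integrate_resources(make_resource_records("DARNED", "1", 16, "T", "C"))
  vcf <- data.frame(chrom = "1", pos = 16L, id = ".", ref = "T", alt = "C",
                    qual = 50, filter = "PASS", info = ".",
                    stringsAsFactors = FALSE)
  rows <- annotate_sites(vcf, kb, fx$models, fx$genome)
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(rows, f)
  expect_equal(read_annotation_csv(f), rows)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", header), table_columns())
})
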