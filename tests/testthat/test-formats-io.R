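test_that("read_vcf parses records, splits multiallelics and skips non-SNVs", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.",
    "chr1\t200\trs1\tC\tG,T\t.\t.\tDP=3",
    "chr2\t30\t.\tT\tA\t10\tq10\t."), f)
  v <- read_vcf(f)
  expect_equal(nrow(v), 4)                       # one ALT split into two rows
  expect_equal(v$chrom, c("1", "1", "1", "2"))   # chr prefix stripped
  expect_equal(v$pos[2:3], c(200L, 200L))
  expect_equal(v$alt[2:3], c("G", "T"))
  expect_true(all(v$ref != v$alt))

  g <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t10\t.\tAT\tA\t.\t.\t.",
    "1\t20\t.\tG\t<DEL>\t.\t.\t.",
    "1\t40\t.\tC\tA\t.\t.\t."), g)
  expect_warning(w <- read_vcf(g), "skipped")
  expect_equal(nrow(w), 1)
  expect_equal(w$pos, 40L)
})

test_that("read_vcf handles degenerate and malformed files", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), f)
  expect_equal(nrow(read_vcf(f)), 0)

  g <- withr::local_tempfile(fileext = ".vcf")
  writeLines("1\t100\t.\tA\tG\t.\t.\t.", g)
  expect_error(read_vcf(g), "#CHROM", class = "editgrade_format_error")

  h <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\tabc\t.\tA\tG\t.\t.\t."), h)
  expect_error(read_vcf(h), "line 3", class = "editgrade_format_error")

  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")),
               class = "editgrade_format_error")
})

test_that("VCF write-read round trip is the identity", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tA\tG\t50\tPASS\t.",
               "2\t5\trs9\tC\tT\t.\tq10\tDP=7"), f)
  v1 <- read_vcf(f)
  g <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v1, g)
  v2 <- read_vcf(g)
  expect_equal(v1, v2)

  empty <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v1[0, ], empty)
  expect_equal(nrow(read_vcf(empty)), 0)
})

test_that("read_gtf parses records and attributes, rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "ENSG1"; transcript_id "ENST1"; gene_name "G1"; gene_biotype "protein_coding";'
  ex_attrs <- function(e) sprintf(
    'gene_id "ENSG1"; transcript_id "ENST1"; exon_id "%s"; gene_name "G1"; gene_biotype "protein_coding";', e)
  writeLines(c(
    "# a comment",
    paste("1", "src", "gene", 100, 900, ".", "+", ".", attrs, sep = "\t"),
    paste("1", "src", "transcript", 100, 900, ".", "+", ".", attrs, sep = "\t"),
    paste("1", "src", "exon", 100, 300, ".", "+", ".", ex_attrs("ENSE1"), sep = "\t"),
    paste("1", "src", "exon", 600, 900, ".", "+", ".", ex_attrs("ENSE2"), sep = "\t"),
    paste("1", "src", "CDS", 150, 300, ".", "+", "0", attrs, sep = "\t"),
    paste("1", "src", "CDS", 600, 800, ".", "+", "2", attrs, sep = "\t")), f)
  g <- read_gtf(f)
  expect_equal(nrow(g), 6)
  expect_equal(sum(g$feature == "exon"), 2)
  expect_equal(g$exon_id[g$feature == "exon"], c("ENSE1", "ENSE2"))
  expect_true(all(g$gene_id == "ENSG1"))
  expect_true(all(g$biotype == "protein_coding"))

  empty <- withr::local_tempfile(fileext = ".gtf")
  file.create(empty)
  expect_equal(nrow(read_gtf(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("1", "src", "exon", 500, 100, ".", "+", ".", attrs,
                   sep = "\t"), bad)
  expect_error(read_gtf(bad), "start > end", class = "editgrade_format_error")

  short <- withr::local_tempfile(fileext = ".gtf")
  writeLines("1\tsrc\texon\t100", short)
  expect_error(read_gtf(short), "9", class = "editgrade_format_error")
})

test_that("repeat intervals normalize to 0-based half-open from both dialects", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t120\tAluSx\tSINE/Alu",
               "chr1\t200\t260\tL1MA4\tLINE/L1"), bed)
  r <- read_repeat_intervals(bed)
  expect_equal(r$start[1], 99L)
  expect_equal(r$end[1], 120L)
  # 1-based p overlaps iff start < p <= end: brute-force check
  covered <- vapply(90:130, function(p) r$start[1] < p & p <= r$end[1],
                    logical(1))
  expect_equal((90:130)[covered], 100:120)

  # RepeatMasker .out (1-based closed begin/end in columns 6-7)
  out <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query        matching  repeat        position in repeat",
    "score  div. del. ins.  sequence  begin    end   (left)    repeat    class/family  begin  end (left)  ID",
    "",
    "  463  1.3  0.6  1.7  chr1      100      120  (1000) +   AluSx     SINE/Alu      1      21    (291)  1"),
    out)
  rm <- read_repeat_intervals(out)
  expect_equal(rm$start, 99L)   # same interval as the BED row above
  expect_equal(rm$end, 120L)
  expect_equal(rm$name, "AluSx")

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_repeat_intervals(empty)), 0)

  degenerate <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t50\tAluY", degenerate)
  expect_error(read_repeat_intervals(degenerate), "start >= end",
               class = "editgrade_format_error")

  junk <- withr::local_tempfile()
  writeLines("not a repeat file at all", junk)
  expect_error(read_repeat_intervals(junk), "dialect",
               class = "editgrade_format_error")
})

test_that("read_fasta upper-cases, keys by first header token and indexes 1-based", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "TTAA"), f)
  g <- read_fasta(f)
  expect_equal(names(g), c("1", "2"))
  expect_equal(as.character(g[["1"]]), "ACGT")
  expect_equal(genome_base(g, "1", 3), "G")
  expect_equal(genome_base(g, "2", c(1, 4)), c("T", "A"))
  expect_error(genome_base(g, "1", 5), "outside")
  expect_error(genome_base(g, "3", 1), "not in genome")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AAAA", ">chr1 again", "CCCC"), dup)
  expect_error(read_fasta(dup), "duplicate", class = "editgrade_format_error")
})

test_that("resource tables read with id tagging, base normalization and row rejection", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_test_resource(f, chrom = rep("1", 5), pos = c(10, 20, 30, 40, 50),
                      in_dna = c("A", "a", "T", "C", "G"),
                      in_rna = c("G", "g", "C", "T", "A"))
  r <- read_resource_table(f, "DARNED")
  expect_equal(nrow(r), 5)
  expect_true(all(r$resource_id == "DARNED"))
  expect_equal(r$dna_base[2], "A")   # lower-case input upper-cased
  expect_equal(r$rna_base[2], "G")

  same <- withr::local_tempfile(fileext = ".tsv")
  write_test_resource(same, "1", c(10, 20), c("A", "C"), c("A", "T"))
  expect_warning(s <- read_resource_table(same, "RADAR"), "rejected")
  expect_equal(nrow(s), 1)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tin_dna\tin_rna\tstrand\tsource\tpubmed", empty)
  expect_equal(nrow(read_resource_table(empty, "LI")), 0)

  badhdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tposition\tref\talt", badhdr)
  expect_error(read_resource_table(badhdr, "LI"), "missing column",
               class = "editgrade_format_error")
})
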