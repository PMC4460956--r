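# Readers and writers for the standard formats the toolkit touches.
#
# Coordinate conventions: VCF and GTF are 1-based; BED and RepeatMasker .out
# are converted to 0-based half-open intervals at read time. Everything that
# refers to a single site (variants, editing-site resources, knowledgebase
# entries) is 1-based.

#' Read single-nucleotide variants from a VCF file
#'
#' Parses the site-level fields of a VCF v4.x file into a data frame with one
#' row per (position, alternative allele) pair. Multiallelic records are split
#' into one row per ALT. Records whose REF or ALT is not a single A/C/G/T base
#' (indels, symbolic alleles such as \code{<DEL>}) are skipped with a warning:
#' RNA editing is a single-nucleotide phenomenon, so only substitutions are
#' retained.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param chrom_style chromosome-label policy passed to
#'   \code{\link{normalize_chrom}}.
#' @return data frame with columns \code{chrom}, \code{pos} (1-based integer),
#'   \code{id}, \code{ref}, \code{alt}, \code{qual}, \code{filter},
#'   \code{info}.
#' @export
read_vcf <- function(path, chrom_style = "strip") {
  if (!file.exists(path)) format_error("VCF file does not exist", path)
  lines <- readLines(path, warn = FALSE)
  header_idx <- grep("^#CHROM\t", lines)
  if (length(header_idx) == 0) {
    format_error("not a VCF: no #CHROM header line", path)
  }
  header_idx <- header_idx[1]
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) return(empty_vcf_df())

  pos_raw <- fix[, "POS"]
  pos <- suppressWarnings(as.integer(pos_raw))
  bad <- which(is.na(pos) | as.character(pos) != pos_raw | pos < 1)
  if (length(bad) > 0) {
    format_error(sprintf("invalid POS %s at line %d", pos_raw[bad[1]],
                         header_idx + bad[1]), path)
  }

  df <- data.frame(
    chrom  = normalize_chrom(fix[, "CHROM"], chrom_style),
    pos    = pos,
    id     = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref    = toupper(fix[, "REF"]),
    alt    = toupper(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"])),
    qual   = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    info   = ifelse(is.na(fix[, "INFO"]), ".", fix[, "INFO"]),
    stringsAsFactors = FALSE
  )

  # Split multiallelic ALT ("G,C") into one row per allele.
  alt_list <- strsplit(df$alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  n_alt[n_alt == 0] <- 1L
  alt_list[lengths(alt_list) == 0] <- list("")
  df <- df[rep(seq_len(nrow(df)), n_alt), , drop = FALSE]
  df$alt <- unlist(alt_list, use.names = FALSE)

  keep <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  if (any(!keep)) {
    warning(sprintf("%d non-SNV or degenerate record(s) skipped in %s",
                    sum(!keep), basename(path)))
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_vcf_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), qual = numeric(0),
             filter = character(0), info = character(0),
             stringsAsFactors = FALSE)
}

#' Write variant records to a minimal VCF file
#'
#' Emits a VCF v4.2 header followed by one line per record, in the given
#' order. Inverse of \code{\link{read_vcf}} for the site-level fields.
#'
#' @param records data frame as returned by \code{\link{read_vcf}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  qual <- ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE))
  body <- if (nrow(records) > 0) {
    paste(records$chrom, records$pos, records$id, records$ref, records$alt,
          qual, records$filter, records$info, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF and flattens the attribute string into
#' columns. Comment lines are skipped; every data line must have nine
#' tab-separated fields.
#'
#' @param path path to a GTF file.
#' @param chrom_style chromosome-label policy (see
#'   \code{\link{normalize_chrom}}).
#' @return data frame with columns \code{seqname}, \code{feature},
#'   \code{start}, \code{end} (1-based closed), \code{strand}, \code{frame},
#'   \code{gene_id}, \code{transcript_id}, \code{exon_id}, \code{gene_name},
#'   \code{biotype}.
#' @export
read_gtf <- function(path, chrom_style = "strip") {
  if (!file.exists(path)) format_error("GTF file does not exist", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(data_lines) == 0) return(empty_gtf_df())
  nfields <- lengths(strsplit(data_lines, "\t", fixed = TRUE))
  if (any(nfields != 9)) {
    format_error(sprintf("GTF line with %d fields (expected 9)",
                         nfields[which(nfields != 9)[1]]), path)
  }
  start_f <- as.integer(vapply(strsplit(data_lines, "\t", fixed = TRUE),
                               `[`, character(1), 4))
  end_f <- as.integer(vapply(strsplit(data_lines, "\t", fixed = TRUE),
                             `[`, character(1), 5))
  if (any(is.na(start_f)) || any(is.na(end_f)) || any(start_f > end_f)) {
    format_error("GTF record with non-numeric coordinates or start > end", path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name, alt = NULL) {
    if (name %in% colnames(mc)) as.character(mc[[name]])
    else if (!is.null(alt) && alt %in% colnames(mc)) as.character(mc[[alt]])
    else rep(NA_character_, length(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    format_error("GTF record without +/- strand", path)
  }
  data.frame(
    seqname = normalize_chrom(as.character(GenomicRanges::seqnames(gr)),
                              chrom_style),
    feature = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    frame = if ("phase" %in% colnames(mc)) as.integer(mc$phase)
            else rep(NA_integer_, length(gr)),
    gene_id = get_attr("gene_id"),
    transcript_id = get_attr("transcript_id"),
    exon_id = get_attr("exon_id"),
    gene_name = get_attr("gene_name"),
    biotype = get_attr("gene_biotype", "transcript_biotype"),
    stringsAsFactors = FALSE
  )
}

empty_gtf_df <- function() {
  data.frame(seqname = character(0), feature = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), gene_id = character(0),
             transcript_id = character(0), exon_id = character(0),
             gene_name = character(0), biotype = character(0),
             stringsAsFactors = FALSE)
}

#' Read repeat annotations (BED or RepeatMasker .out)
#'
#' Auto-detects BED (tab-separated, 0-based half-open) versus RepeatMasker
#' \code{.out} tables (whitespace-separated, 1-based closed) by column
#' signature and normalizes both to 0-based half-open intervals. A 1-based
#' position \code{p} overlaps an interval iff \code{start < p <= end}.
#'
#' @param path path to the repeat file.
#' @param chrom_style chromosome-label policy.
#' @return data frame with columns \code{chrom}, \code{start} (0-based
#'   inclusive), \code{end} (0-based exclusive), \code{name}, \code{family}.
#' @export
read_repeat_intervals <- function(path, chrom_style = "strip") {
  if (!file.exists(path)) format_error("repeat file does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) return(empty_repeat_df())

  is_int <- function(x) grepl("^[0-9]+$", x)
  tab_fields <- strsplit(lines, "\t", fixed = TRUE)
  ws_fields <- strsplit(trimws(lines), "[[:space:]]+")

  looks_bed <- all(lengths(tab_fields) >= 3) &&
    all(vapply(tab_fields, function(f) is_int(f[2]) && is_int(f[3]), logical(1)))
  # RepeatMasker .out: two header lines, then >= 14 whitespace columns with
  # integer begin/end in columns 6 and 7.
  rm_body <- ws_fields[vapply(ws_fields, function(f)
    length(f) >= 14 && is_int(f[6]) && is_int(f[7]), logical(1))]
  looks_rm <- length(rm_body) > 0 && length(rm_body) >= length(lines) - 3

  if (looks_bed) {
    df <- data.frame(
      chrom = normalize_chrom(vapply(tab_fields, `[`, character(1), 1),
                              chrom_style),
      start = as.integer(vapply(tab_fields, `[`, character(1), 2)),
      end = as.integer(vapply(tab_fields, `[`, character(1), 3)),
      name = vapply(tab_fields, function(f)
        if (length(f) >= 4) f[4] else ".", character(1)),
      family = vapply(tab_fields, function(f)
        if (length(f) >= 5) f[5] else ".", character(1)),
      stringsAsFactors = FALSE
    )
  } else if (looks_rm) {
    df <- data.frame(
      chrom = normalize_chrom(vapply(rm_body, `[`, character(1), 5),
                              chrom_style),
      start = as.integer(vapply(rm_body, `[`, character(1), 6)) - 1L,
      end = as.integer(vapply(rm_body, `[`, character(1), 7)),
      name = vapply(rm_body, `[`, character(1), 10),
      family = vapply(rm_body, `[`, character(1), 11),
      stringsAsFactors = FALSE
    )
  } else {
    format_error("cannot detect repeat-file dialect (neither BED nor RepeatMasker .out)",
                 path)
  }
  if (any(df$start >= df$end)) {
    format_error("repeat interval with start >= end", path)
  }
  df
}

empty_repeat_df <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), family = character(0),
             stringsAsFactors = FALSE)
}

#' Read a reference genome from FASTA
#'
#' Sequences are keyed by the first whitespace-delimited token of each header
#' and upper-cased on load.
#'
#' @param path path to a FASTA file.
#' @param chrom_style chromosome-label policy.
#' @return a \code{Biostrings::DNAStringSet}, one entry per chromosome.
#' @export
read_fasta <- function(path, chrom_style = "strip") {
  if (!file.exists(path)) format_error("FASTA file does not exist", path)
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- normalize_chrom(sub("\\s.*$", "", names(seqs)), chrom_style)
  if (anyDuplicated(nms)) {
    format_error(sprintf("duplicate FASTA header '%s'", nms[duplicated(nms)][1]),
                 path)
  }
  names(seqs) <- nms
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Fetch reference bases at 1-based positions
#'
#' @param genome a \code{DNAStringSet} from \code{\link{read_fasta}}.
#' @param chrom chromosome label (scalar).
#' @param pos integer vector of 1-based positions.
#' @return character vector of upper-case bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not in genome", chrom))
  }
  s <- genome[[chrom]]
  if (any(pos < 1 | pos > length(s))) {
    stop(sprintf("position outside chromosome '%s' (length %d)", chrom,
                 length(s)))
  }
  vapply(pos, function(p) as.character(Biostrings::subseq(s, p, p)),
         character(1))
}

#' Read an RNA-editing-site resource table
#'
#' Resource tables are tab-separated with the header
#' \code{chrom pos in_dna in_rna strand source pubmed}; \code{source} and
#' \code{pubmed} may hold comma-separated lists. Rows whose DNA and RNA base
#' agree are rejected with a warning (no editing event). The schema mirrors
#' the site-level content of public editing databases (DARNED, RADAR and
#' publication-derived site lists).
#'
#' @param path path to the TSV file.
#' @param resource_id identifier the rows are tagged with (e.g. "DARNED").
#' @param chrom_style chromosome-label policy.
#' @return data frame with columns \code{resource_id}, \code{chrom},
#'   \code{pos}, \code{dna_base}, \code{rna_base}, \code{strand} (+/-/""),
#'   \code{tissue_sources}, \code{pubmed_ids} (comma-joined lists).
#' @export
read_resource_table <- function(path, resource_id, chrom_style = "strip") {
  if (!file.exists(path)) format_error("resource table does not exist", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("chrom", "pos", "in_dna", "in_rna", "strand", "source", "pubmed")
  if (!all(required %in% colnames(df))) {
    format_error(sprintf("resource table missing column(s): %s",
                         paste(setdiff(required, colnames(df)), collapse = ", ")),
                 path)
  }
  if (nrow(df) == 0) return(empty_resource_df())
  out <- data.frame(
    resource_id = resource_id,
    chrom = normalize_chrom(df$chrom, chrom_style),
    pos = as.integer(df$pos),
    dna_base = toupper(df$in_dna),
    rna_base = toupper(df$in_rna),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, ""),
    tissue_sources = df$source,
    pubmed_ids = df$pubmed,
    stringsAsFactors = FALSE
  )
  bad <- out$dna_base == out$rna_base |
    !out$dna_base %in% BASES | !out$rna_base %in% BASES
  if (any(bad)) {
    warning(sprintf("%d row(s) with invalid or identical bases rejected in %s",
                    sum(bad), basename(path)))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_resource_df <- function() {
  data.frame(resource_id = character(0), chrom = character(0),
             pos = integer(0), dna_base = character(0),
             rna_base = character(0), strand = character(0),
             tissue_sources = character(0), pubmed_ids = character(0),
             stringsAsFactors = FALSE)
}
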