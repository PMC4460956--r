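# Transcript models built from GTF records: the per-transcript exon/CDS
# structure plus the derived interval indexes (UTRs, splice-junction windows,
# 1-kb flanks) used for point classification.

SPLICE_WINDOW <- 2L   # bp on either side of an exon/intron junction
FLANK_SIZE <- 1000L   # upstream/downstream flank, bp

#' Build transcript models from GTF records
#'
#' Groups GTF exon and CDS features by \code{transcript_id} into one model
#' per transcript. A transcript with no CDS feature is treated as non-coding.
#' 5'/3' UTRs are derived as the exonic regions outside the CDS extent
#' (strand-aware), so explicit UTR features are not required. The
#' transcription start site (TSS) is the 5'-most transcribed base
#' (\code{min(start)} on plus, \code{max(end)} on minus strand).
#'
#' @param gtf_records data frame from \code{\link{read_gtf}}.
#' @return object of class \code{transcript_models} with elements \code{tx}
#'   (one row per transcript), \code{exons} and \code{cds} data frames, and
#'   internal interval indexes.
#' @export
build_transcript_models <- function(gtf_records) {
  g <- gtf_records
  ex <- g[g$feature == "exon", , drop = FALSE]
  no_tx <- is.na(ex$transcript_id) | !nzchar(ex$transcript_id)
  if (any(no_tx)) {
    warning(sprintf("%d exon record(s) without transcript_id skipped",
                    sum(no_tx)))
    ex <- ex[!no_tx, , drop = FALSE]
  }
  cds <- g[g$feature == "CDS" & !is.na(g$transcript_id), , drop = FALSE]

  tx_ids <- unique(ex$transcript_id)
  tx <- do.call(rbind, lapply(tx_ids, function(id) {
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop(sprintf("overlapping exons in transcript %s", id))
    }
    strand <- e$strand[1]
    cc <- cds[cds$transcript_id == id, , drop = FALSE]
    cds_len <- if (nrow(cc)) sum(cc$end - cc$start + 1L) else 0L
    data.frame(
      transcript_id = id,
      gene_id = if (!is.na(e$gene_id[1])) e$gene_id[1] else "",
      gene_name = if (!is.na(e$gene_name[1])) e$gene_name[1] else "",
      chrom = e$seqname[1],
      strand = strand,
      start = min(e$start), end = max(e$end),
      tss = if (strand == "+") min(e$start) else max(e$end),
      tes = if (strand == "+") max(e$end) else min(e$start),
      biotype = if (!is.na(e$biotype[1])) e$biotype[1] else "",
      coding = nrow(cc) > 0,
      cds_frame_ok = cds_len %% 3L == 0L,
      n_exons = nrow(e),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(tx)) tx <- empty_tx_df()
  rownames(tx) <- NULL

  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  models <- list(tx = tx,
                 exons = ex[, c("transcript_id", "exon_id", "seqname",
                                "start", "end", "strand"), drop = FALSE],
                 cds = cds[, c("transcript_id", "seqname", "start", "end",
                               "frame"), drop = FALSE])
  models$index <- build_model_index(models)
  class(models) <- "transcript_models"
  models
}

empty_tx_df <- function() {
  data.frame(transcript_id = character(0), gene_id = character(0),
             gene_name = character(0), chrom = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             tss = integer(0), tes = integer(0), biotype = character(0),
             coding = logical(0), cds_frame_ok = logical(0),
             n_exons = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcript(s) (%d coding) on %d chromosome(s)\n",
              nrow(x$tx), sum(x$tx$coding), length(unique(x$tx$chrom))))
  invisible(x)
}

granges_or_empty <- function(chrom, start, end, tx_i) {
  keep <- start <= end
  GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(start[keep], end[keep]),
                         tx_i = tx_i[keep])
}

empty_tx_gr <- function() {
  g <- GenomicRanges::GRanges()
  S4Vectors::mcols(g)$tx_i <- integer(0)
  g
}

# findOverlaps with seqlevel-mismatch warnings silenced: query positions on
# chromosomes absent from the annotation are a normal, handled case.
ov_hits <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}

# Precomputed interval sets, each carrying the row index of its transcript:
# spans, exons, CDS, noncoding-transcript exons, derived UTRs, splice-junction
# windows, and the two 1-kb flanks.
build_model_index <- function(models) {
  tx <- models$tx
  ex <- models$exons
  cds <- models$cds
  ex_tx_i <- match(ex$transcript_id, tx$transcript_id)
  cds_tx_i <- match(cds$transcript_id, tx$transcript_id)

  span_gr <- granges_or_empty(tx$chrom, tx$start, tx$end, seq_len(nrow(tx)))
  exon_gr <- granges_or_empty(ex$seqname, ex$start, ex$end, ex_tx_i)
  if (length(exon_gr)) S4Vectors::mcols(exon_gr)$exon_id <- ex$exon_id[ex$start <= ex$end]
  cds_gr <- granges_or_empty(cds$seqname, cds$start, cds$end, cds_tx_i)
  nc_exon_gr <- exon_gr[!tx$coding[S4Vectors::mcols(exon_gr)$tx_i]]

  # UTRs: exonic minus the CDS genomic extent, split by side of the CDS.
  utr5 <- list(); utr3 <- list()
  for (i in which(tx$coding)) {
    id <- tx$transcript_id[i]
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    cc <- cds[cds$transcript_id == id, , drop = FALSE]
    cds_lo <- min(cc$start); cds_hi <- max(cc$end)
    er <- IRanges::IRanges(e$start, e$end)
    left <- IRanges::restrict(er, end = cds_lo - 1L)
    right <- IRanges::restrict(er, start = cds_hi + 1L)
    left <- left[IRanges::width(left) > 0]
    right <- right[IRanges::width(right) > 0]
    if (tx$strand[i] == "+") { u5 <- left; u3 <- right }
    else { u5 <- right; u3 <- left }
    if (length(u5)) utr5[[length(utr5) + 1L]] <-
      GenomicRanges::GRanges(tx$chrom[i], u5, tx_i = i)
    if (length(u3)) utr3[[length(utr3) + 1L]] <-
      GenomicRanges::GRanges(tx$chrom[i], u3, tx_i = i)
  }
  utr5_gr <- if (length(utr5)) suppressWarnings(do.call(c, utr5)) else empty_tx_gr()
  utr3_gr <- if (length(utr3)) suppressWarnings(do.call(c, utr3)) else empty_tx_gr()

  # Splice windows: SPLICE_WINDOW bp either side of each internal junction.
  sw <- list()
  for (i in seq_len(nrow(tx))) {
    if (tx$n_exons[i] < 2) next
    e <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    donors <- e$end[-nrow(e)]      # internal exon ends (genomic order)
    acceptors <- e$start[-1]       # internal exon starts
    st <- c(donors - SPLICE_WINDOW + 1L, acceptors - SPLICE_WINDOW)
    en <- c(donors + SPLICE_WINDOW, acceptors + SPLICE_WINDOW - 1L)
    sw[[length(sw) + 1L]] <- GenomicRanges::GRanges(
      tx$chrom[i], IRanges::IRanges(st, en), tx_i = i)
  }
  splice_gr <- if (length(sw)) suppressWarnings(do.call(c, sw)) else empty_tx_gr()

  up_start <- ifelse(tx$strand == "+", tx$tss - FLANK_SIZE, tx$tss + 1L)
  up_end <- ifelse(tx$strand == "+", tx$tss - 1L, tx$tss + FLANK_SIZE)
  down_start <- ifelse(tx$strand == "+", tx$tes + 1L, tx$tes - FLANK_SIZE)
  down_end <- ifelse(tx$strand == "+", tx$tes + FLANK_SIZE, tx$tes - 1L)
  up_gr <- granges_or_empty(tx$chrom, pmax(up_start, 1L), up_end,
                            seq_len(nrow(tx)))
  down_gr <- granges_or_empty(tx$chrom, pmax(down_start, 1L), down_end,
                              seq_len(nrow(tx)))

  list(span = span_gr, exon = exon_gr, cds = cds_gr, nc_exon = nc_exon_gr,
       utr5 = utr5_gr, utr3 = utr3_gr, splice = splice_gr,
       upstream = up_gr, downstream = down_gr)
}

#' Extract a single transcript model
#'
#' @param models a \code{transcript_models} object.
#' @param transcript_id the transcript to extract.
#' @return list with the transcript row, its exons and CDS segments.
#' @export
transcript_model <- function(models, transcript_id) {
  i <- match(transcript_id, models$tx$transcript_id)
  if (is.na(i)) stop(sprintf("unknown transcript '%s'", transcript_id))
  list(tx = models$tx[i, , drop = FALSE],
       exons = models$exons[models$exons$transcript_id == transcript_id, ,
                            drop = FALSE],
       cds = models$cds[models$cds$transcript_id == transcript_id, ,
                        drop = FALSE])
}

#' Transcripts overlapping a point
#'
#' @param models a \code{transcript_models} object.
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @return data frame of transcript rows whose span contains the position.
#' @export
transcripts_at <- function(models, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- ov_hits(q, models$index$span)
  i <- S4Vectors::mcols(models$index$span)$tx_i[S4Vectors::subjectHits(hits)]
  models$tx[sort(unique(i)), , drop = FALSE]
}
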