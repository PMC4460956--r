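# Integration of editing-site resources into a knowledgebase and the
# five-level evidence grade.
#
# Sites are merged on (chromosome, position, DNA base, RNA base). The
# evidence count of a site is the number of distinct resources reporting it,
# plus one when the site lies in an Alu repeat; counts 1..5+ map to class
# letters E, D, C, B, A. Alu context can raise the grade of an existing site
# but can never create one on its own.

#' Default resource registry
#'
#' The five editing-site resources eligible as evidence: the DARNED and RADAR
#' databases, ENCODE cell-line RNA-Seq sites, and the site lists of two
#' primary publications (here "BAHN" and "LI"). The Alu pseudo-resource is
#' handled separately and is not part of the registry.
#'
#' @param resources character vector of resource identifiers.
#' @return character vector usable as the \code{registry} argument elsewhere.
#' @export
default_registry <- function(resources = c("DARNED", "ENCODE", "RADAR",
                                           "BAHN", "LI")) {
  resources <- toupper(resources)
  if (anyDuplicated(resources)) stop("registry identifiers must be unique")
  if ("ALU" %in% resources) {
    stop("ALU is a pseudo-resource and cannot be registered as evidence")
  }
  resources
}

evidence_letters <- c("E", "D", "C", "B", "A")

#' Assign the evidence level of an integrated site
#'
#' The evidence count is the number of supporting resources plus one when the
#' site has Alu context. Counts map to class letters E (1), D (2), C (3),
#' B (4) and A (>= 5); a site supported by all five resources plus Alu
#' (count 6) still grades A, as the scheme has exactly five classes.
#'
#' @param memberships character vector of resource identifiers supporting the
#'   site (must be a nonempty subset of the registry).
#' @param alu logical; TRUE when the site lies in an Alu repeat.
#' @param registry resource registry from \code{\link{default_registry}}.
#' @return list with \code{evidence_count} (integer, uncapped) and
#'   \code{class_letter} ("A".."E").
#' @export
assign_evidence_level <- function(memberships, alu = FALSE,
                                  registry = default_registry()) {
  memberships <- unique(toupper(memberships))
  if (length(memberships) == 0) {
    stop("a site cannot exist on Alu evidence alone: empty resource memberships")
  }
  unknown <- setdiff(memberships, registry)
  if (length(unknown) > 0) {
    stop(sprintf("unregistered resource(s): %s", paste(unknown, collapse = ", ")))
  }
  count <- length(memberships) + as.integer(isTRUE(alu))
  list(evidence_count = count,
       class_letter = evidence_letters[min(count, 5L)])
}

#' Merge editing-site resources into an integrated knowledgebase
#'
#' Records sharing (chromosome, position, DNA base, RNA base) merge into one
#' site. Memberships, tissue sources, PubMed ids and data references are
#' unions; to make the result independent of input order, resources are
#' always processed in registry order and within a resource in file order.
#' Strand is taken by majority vote among resources reporting one, unknown
#' ("") on a tie. A site gains Alu context when its position overlaps a
#' repeat whose name starts with "Alu".
#'
#' @param resource_records a single data frame of resource records (from
#'   \code{\link{read_resource_table}}) or a list of such data frames.
#' @param repeats repeat intervals from \code{\link{read_repeat_intervals}},
#'   or NULL for no Alu context.
#' @param registry resource registry.
#' @return data frame of class \code{editing_kb}, sorted by (chrom, pos),
#'   with columns \code{chrom}, \code{pos}, \code{dna_base}, \code{rna_base},
#'   \code{strand}, \code{memberships}, \code{alu_name},
#'   \code{tissue_sources}, \code{pubmed_ids}, \code{data_references},
#'   \code{evidence_count}, \code{evidence_level}.
#' @export
integrate_resources <- function(resource_records, repeats = NULL,
                                registry = default_registry()) {
  if (is.data.frame(resource_records)) {
    rec <- resource_records
  } else {
    rec <- do.call(rbind, resource_records)
  }
  if (is.null(rec) || nrow(rec) == 0) {
    kb <- empty_kb_df()
    return(as_editing_kb(kb, registry))
  }
  unknown <- setdiff(unique(rec$resource_id), registry)
  if (length(unknown) > 0) {
    stop(sprintf("unregistered resource(s): %s", paste(unknown, collapse = ", ")))
  }
  # Canonical processing order: registry order, then file order.
  rec <- rec[order(match(rec$resource_id, registry)), , drop = FALSE]
  key <- site_key(rec$chrom, rec$pos, rec$dna_base, rec$rna_base)
  groups <- split(seq_len(nrow(rec)), factor(key, levels = unique(key)))

  merge_group <- function(idx) {
    g <- rec[idx, , drop = FALSE]
    votes <- g$strand[g$strand %in% c("+", "-")]
    strand <- ""
    if (length(votes) > 0) {
      tab <- table(votes)
      if (length(tab) == 1 || max(tab) > min(tab)) {
        strand <- names(tab)[which.max(tab)]
      }
    }
    data.frame(
      chrom = g$chrom[1], pos = g$pos[1],
      dna_base = g$dna_base[1], rna_base = g$rna_base[1],
      strand = strand,
      memberships = join_csv(g$resource_id),
      tissue_sources = join_csv(unlist(lapply(g$tissue_sources, split_csv))),
      pubmed_ids = join_csv(unlist(lapply(g$pubmed_ids, split_csv))),
      stringsAsFactors = FALSE
    )
  }
  kb <- do.call(rbind, lapply(groups, merge_group))
  rownames(kb) <- NULL
  kb$data_references <- kb$memberships
  kb$alu_name <- alu_name_at(kb$chrom, kb$pos, repeats)

  ev <- lapply(seq_len(nrow(kb)), function(i) {
    assign_evidence_level(split_csv(kb$memberships[i]),
                          alu = nzchar(kb$alu_name[i]), registry = registry)
  })
  kb$evidence_count <- vapply(ev, `[[`, integer(1), "evidence_count")
  kb$evidence_level <- vapply(ev, `[[`, character(1), "class_letter")
  kb <- kb[order(kb$chrom, kb$pos, kb$dna_base, kb$rna_base), , drop = FALSE]
  rownames(kb) <- NULL
  kb <- kb[, kb_columns(), drop = FALSE]
  as_editing_kb(kb, registry)
}

kb_columns <- function() {
  c("chrom", "pos", "dna_base", "rna_base", "strand", "memberships",
    "alu_name", "tissue_sources", "pubmed_ids", "data_references",
    "evidence_count", "evidence_level")
}

empty_kb_df <- function() {
  kb <- data.frame(chrom = character(0), pos = integer(0),
                   dna_base = character(0), rna_base = character(0),
                   strand = character(0), memberships = character(0),
                   alu_name = character(0), tissue_sources = character(0),
                   pubmed_ids = character(0), data_references = character(0),
                   evidence_count = integer(0), evidence_level = character(0),
                   stringsAsFactors = FALSE)
  kb
}

as_editing_kb <- function(kb, registry) {
  attr(kb, "registry") <- registry
  class(kb) <- c("editing_kb", "data.frame")
  kb
}

# Name of the first Alu repeat overlapping each 1-based position, "" when
# none. Repeats are 0-based half-open: p overlaps iff start < p <= end.
alu_name_at <- function(chrom, pos, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0) return(rep("", length(pos)))
  alu <- repeats[startsWith(repeats$name, "Alu"), , drop = FALSE]
  if (nrow(alu) == 0) return(rep("", length(pos)))
  alu <- alu[order(alu$chrom, alu$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(alu$chrom,
                               IRanges::IRanges(alu$start + 1L, alu$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, gr, select = "first")
  ifelse(is.na(hits), "", alu$name[hits])
}

#' Look up a site in the knowledgebase by exact key
#'
#' @param kb an \code{editing_kb}.
#' @param chrom,pos,dna_base,rna_base the site key.
#' @return the matching one-row data frame, or NULL when absent.
#' @export
query_known <- function(kb, chrom, pos, dna_base, rna_base) {
  hit <- kb$chrom == chrom & kb$pos == pos &
    kb$dna_base == toupper(dna_base) & kb$rna_base == toupper(rna_base)
  if (!any(hit)) return(NULL)
  out <- as.data.frame(kb)[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist / load a knowledgebase as sorted TSV
#'
#' @param kb an \code{editing_kb}.
#' @param path file path.
#' @return \code{write_kb}: the path invisibly; \code{read_kb}: the
#'   knowledgebase.
#' @export
write_kb <- function(kb, path) {
  utils::write.table(as.data.frame(kb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_kb
#' @param registry resource registry to attach on load.
#' @export
read_kb <- function(path, registry = default_registry()) {
  kb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(kb_columns() %in% colnames(kb))) {
    format_error("not a knowledgebase TSV: missing columns", path)
  }
  if (nrow(kb) == 0) return(as_editing_kb(empty_kb_df(), registry))
  kb$pos <- as.integer(kb$pos)
  kb$evidence_count <- as.integer(kb$evidence_count)
  for (col in c("strand", "alu_name", "tissue_sources", "pubmed_ids"))
    kb[[col]][is.na(kb[[col]])] <- ""
  as_editing_kb(kb[, kb_columns(), drop = FALSE], registry)
}
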