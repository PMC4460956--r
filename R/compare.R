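# Paired DNA/RNA comparison (RDD candidate discovery), multi-sample
# known-site comparison, and editing-type classification.

#' The twelve editing-type labels
#'
#' All ordered single-base substitutions X-to-Y with X != Y.
#'
#' @return character vector of length 12.
#' @export
edit_type_labels <- function() {
  grid <- expand.grid(to = BASES, from = BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  sort(paste0(grid$from, "-to-", grid$to))
}

#' Classify the editing type of a substitution
#'
#' Editing types are reported in transcript orientation: on the minus strand
#' both bases are complemented before labeling, so a genomic T>C change in a
#' minus-strand gene reports as A-to-G (the A-to-I signature). Unknown strand
#' is treated as plus.
#'
#' @param dna_base,rna_base plus-strand reference and edited base.
#' @param strand "+", "-" or "" / "unknown".
#' @return an editing-type label such as "A-to-G".
#' @export
classify_edit_type <- function(dna_base, rna_base, strand = "+") {
  dna_base <- toupper(dna_base); rna_base <- toupper(rna_base)
  if (!dna_base %in% BASES || !rna_base %in% BASES) {
    stop("bases must be single A/C/G/T")
  }
  if (dna_base == rna_base) stop("DNA and RNA base are identical: no edit")
  if (identical(strand, "-")) {
    dna_base <- complement_base(dna_base)
    rna_base <- complement_base(rna_base)
  }
  paste0(dna_base, "-to-", rna_base)
}

#' Detect RDD candidates from paired DNA and RNA variant calls
#'
#' An RNA variant is an RNA-DNA difference (RDD) candidate when no DNA
#' variant of the same individual exists at its position: a genomic variant
#' at the position explains the RNA mismatch as germline, whatever its
#' allele. Both inputs must come from the same individual.
#'
#' @param dna_records,rna_records data frames from \code{\link{read_vcf}}.
#' @return data frame sorted by (chrom, pos) with columns \code{chrom},
#'   \code{pos}, \code{dna_base}, \code{rna_base}, \code{edit_type},
#'   \code{dna_status} (always "absent_in_dna").
#' @export
compare_rdd <- function(dna_records, rna_records) {
  dna_pos <- unique(paste(dna_records$chrom, dna_records$pos))
  keep <- !(paste(rna_records$chrom, rna_records$pos) %in% dna_pos)
  r <- rna_records[keep, , drop = FALSE]
  r <- r[order(r$chrom, r$pos, r$alt), , drop = FALSE]
  out <- data.frame(
    chrom = r$chrom, pos = r$pos, dna_base = r$ref, rna_base = r$alt,
    edit_type = if (nrow(r)) mapply(classify_edit_type, r$ref, r$alt,
                                    USE.NAMES = FALSE) else character(0),
    dna_status = rep("absent_in_dna", nrow(r)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare known editing sites across samples
#'
#' Sites are matched by exact (chromosome, position, DNA base, RNA base)
#' key. For every unordered sample pair the intersection and both difference
#' sets are reported; a sample's unique sites are those present in no other
#' sample.
#'
#' @param samples named list (>= 2 entries) of data frames from
#'   \code{\link{read_vcf}}, one per sample.
#' @return object of class \code{sample_comparison}: list with
#'   \code{sample_names}, \code{sites} (named list of site-key data frames),
#'   \code{unique_sites}, \code{pairwise} (per pair: \code{intersection},
#'   \code{only_a}, \code{only_b}) and \code{counts} (pairwise intersection
#'   count matrix with per-sample totals on the diagonal).
#' @export
compare_known_sites <- function(samples) {
  if (length(samples) < 2) {
    stop("need at least two samples; for a single sample use annotation mode")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list")
  }
  key_df <- function(v) {
    df <- unique(data.frame(chrom = v$chrom, pos = v$pos, dna_base = v$ref,
                            rna_base = v$alt, stringsAsFactors = FALSE))
    df <- df[order(df$chrom, df$pos, df$rna_base), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  reset_rn <- function(df) { rownames(df) <- NULL; df }
  sites <- lapply(samples, key_df)
  keys <- lapply(sites, function(s)
    site_key(s$chrom, s$pos, s$dna_base, s$rna_base))
  nm <- names(samples)

  unique_sites <- lapply(seq_along(nm), function(i) {
    others <- unlist(keys[-i], use.names = FALSE)
    reset_rn(sites[[i]][!keys[[i]] %in% others, , drop = FALSE])
  })
  names(unique_sites) <- nm

  pairwise <- list()
  counts <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  diag(counts) <- vapply(keys, length, integer(1))
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq(i + 1, length(nm))) {
        inter <- keys[[i]] %in% keys[[j]]
        pair <- list(intersection = reset_rn(sites[[i]][inter, , drop = FALSE]),
                     only_a = reset_rn(sites[[i]][!inter, , drop = FALSE]),
                     only_b = reset_rn(sites[[j]][!keys[[j]] %in% keys[[i]], ,
                                                  drop = FALSE]))
        pairwise[[paste(nm[i], nm[j], sep = " vs ")]] <- pair
        counts[i, j] <- counts[j, i] <- sum(inter)
      }
    }
  }
  structure(list(sample_names = nm, sites = sites,
                 unique_sites = unique_sites, pairwise = pairwise,
                 counts = counts),
            class = "sample_comparison")
}

#' @export
print.sample_comparison <- function(x, ...) {
  cat(sprintf("sample_comparison across %d samples\n", length(x$sample_names)))
  print(x$counts)
  invisible(x)
}

#' Write comparison outputs
#'
#' Writes one CSV per sample pair (intersection and both differences, with a
#' leading "set" column) plus the pairwise intersection-count matrix as TSV.
#'
#' @param comparison a \code{sample_comparison}.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_comparison <- function(comparison, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pair_name in names(comparison$pairwise)) {
    p <- comparison$pairwise[[pair_name]]
    tag <- function(df, set) {
      if (nrow(df) == 0) return(NULL)
      cbind(data.frame(set = set, stringsAsFactors = FALSE), df)
    }
    rows <- do.call(rbind, Filter(Negate(is.null), list(
      tag(p$intersection, "intersection"),
      tag(p$only_a, paste0("only_", strsplit(pair_name, " vs ")[[1]][1])),
      tag(p$only_b, paste0("only_", strsplit(pair_name, " vs ")[[1]][2])))))
    if (is.null(rows)) {
      rows <- data.frame(set = character(0), chrom = character(0),
                         pos = integer(0), dna_base = character(0),
                         rna_base = character(0), stringsAsFactors = FALSE)
    }
    f <- file.path(out_dir, paste0(gsub(" ", "_", pair_name), ".csv"))
    utils::write.csv(rows, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  mat_path <- file.path(out_dir, "pairwise_counts.tsv")
  utils::write.table(comparison$counts, mat_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(paths, mat_path))
}
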