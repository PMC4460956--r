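# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Complement single nucleotide bases
#'
#' @param x character vector of bases (A/C/G/T, any case).
#' @return upper-case complemented bases.
#' @keywords internal
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCATGCA", toupper(x))
}

#' Normalize chromosome labels
#'
#' Ensembl-style annotation uses bare labels ("1", "X") while UCSC-derived
#' resources use a "chr" prefix. All readers funnel labels through this
#' function so that every in-memory table uses one convention.
#'
#' @param x character vector of chromosome labels.
#' @param style "strip" (default) removes a leading "chr", "add" prepends it,
#'   "asis" leaves labels untouched.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x, style = c("strip", "add", "asis")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "strip") {
    sub("^chr", "", x)
  } else if (style == "add") {
    ifelse(grepl("^chr", x), x, paste0("chr", x))
  } else {
    x
  }
}

# Canonical site key: chromosome / position / genomic base / RNA base.
site_key <- function(chrom, pos, dna_base, rna_base) {
  paste(chrom, pos, dna_base, rna_base, sep = ":")
}

# Run code under a fixed RNG seed without disturbing global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stop with a classed format error so callers can distinguish malformed
# input files from programming errors.
format_error <- function(msg, path = NULL) {
  if (!is.null(path)) msg <- sprintf("%s [file: %s]", msg, path)
  stop(errorCondition(msg, class = c("editgrade_format_error", "error")))
}

# Collapse a character vector into the comma-joined list form used in
# serialized tables; empty input becomes "".
join_csv <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  paste(unique(x), collapse = ",")
}

split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}
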