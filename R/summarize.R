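# Executive-summary tables and bar plots over annotated sites: counts by
# genomic feature, chromosome, editing type, evidence class, gene,
# synonymous/nonsynonymous status, ncRNA flag and sample.

SUMMARY_DIMENSIONS <- c("genomic_feature", "chromosome", "edit_type",
                        "evidence_class", "gene", "syn_nonsyn", "ncrna",
                        "sample")

# Cap for the gene dimension: genes beyond the top GENE_TOP are pooled as
# "other" to keep plots readable.
GENE_TOP <- 30L

#' Count annotated sites along one summary dimension
#'
#' Categories with zero count are omitted; ordering is deterministic (count
#' descending, then lexical). For \code{edit_type}, the label is derived from
#' the In DNA / In RNA / Strand columns; for \code{gene}, categories beyond
#' the 30 most frequent are pooled into "other". Rows whose category is
#' empty are counted under "(none)" so that counts always sum to the number
#' of input rows.
#'
#' @param rows annotation data frame (17 columns; for \code{dimension =
#'   "sample"} an additional \code{Sample} column is required).
#' @param dimension one of genomic_feature, chromosome, edit_type,
#'   evidence_class, gene, syn_nonsyn, ncrna, sample.
#' @return data frame of class \code{summary_table} with columns
#'   \code{category} and \code{count}, and the dimension as an attribute.
#' @export
summarize_rows <- function(rows, dimension) {
  if (!dimension %in% SUMMARY_DIMENSIONS) {
    stop(sprintf("unknown dimension '%s'; valid dimensions: %s", dimension,
                 paste(SUMMARY_DIMENSIONS, collapse = ", ")))
  }
  values <- switch(dimension,
    genomic_feature = rows[["Genomic feature"]],
    chromosome = as.character(rows[["Chr"]]),
    evidence_class = rows[["Evidence level"]],
    gene = rows[["Gene"]],
    syn_nonsyn = rows[["Synonymous or nonsynonymous"]],
    ncrna = rows[["Noncoding RNA"]],
    sample = {
      if (!"Sample" %in% colnames(rows)) {
        stop("dimension 'sample' needs a 'Sample' column")
      }
      rows[["Sample"]]
    },
    edit_type = {
      if (nrow(rows) == 0) character(0)
      else mapply(function(d, r, s) {
        classify_edit_type(d, r, if (s %in% c("+", "-")) s else "+")
      }, rows[["In DNA"]], rows[["In RNA"]], rows[["Strand"]],
      USE.NAMES = FALSE)
    })
  values <- as.character(values)
  values[is.na(values) | !nzchar(values)] <- "(none)"
  tab <- table(values)
  df <- data.frame(category = as.character(names(tab)),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  if (nrow(df) > 0) df <- df[order(-df$count, df$category), , drop = FALSE]
  if (dimension == "gene" && nrow(df) > GENE_TOP) {
    other <- sum(df$count[-seq_len(GENE_TOP)])
    df <- rbind(df[seq_len(GENE_TOP), , drop = FALSE],
                data.frame(category = "other", count = other,
                           stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  attr(df, "dimension") <- dimension
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Render summary tables to CSV and bar-plot images
#'
#' One \code{<dimension>_summary.csv} and one \code{<dimension>_summary.png}
#' per table. The CSV is the quantitative record; the image is a bar plot
#' rendered from the CSV contents.
#'
#' @param tables list of \code{summary_table} objects.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_summary <- function(tables, out_dir) {
  if (length(tables) == 0) return(invisible(character(0)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in tables) {
    dim_name <- attr(tab, "dimension")
    csv_path <- file.path(out_dir, paste0(dim_name, "_summary.csv"))
    utils::write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
    png_path <- file.path(out_dir, paste0(dim_name, "_summary.png"))
    df <- as.data.frame(tab)
    if (nrow(df) > 0) {
      df$category <- factor(df$category, levels = df$category)
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                            y = .data$count)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = dim_name, y = "RNA editing sites",
                      title = sprintf("Sites by %s", gsub("_", " ", dim_name))) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      suppressMessages(ggplot2::ggsave(png_path, p, width = 7, height = 4.5,
                                       dpi = 120))
      paths <- c(paths, png_path)
    }
    paths <- c(paths, csv_path)
  }
  invisible(paths)
}

#' Re-read a summary CSV
#'
#' @param path path to a \code{<dimension>_summary.csv}.
#' @return a \code{summary_table}.
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  attr(df, "dimension") <- sub("_summary\\.csv$", "", basename(path))
  class(df) <- c("summary_table", "data.frame")
  df
}
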