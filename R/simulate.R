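# Seeded synthetic-fixture generation: toy genomes with gene models,
# editing-site resource tables with a planned evidence-class mix, Alu repeat
# tracks, and paired DNA/RNA VCFs with planted germline variants and RDD
# sites. Every generator is a pure function of its seed and parameters, and
# each returns a ground-truth manifest fragment so downstream modules can be
# tested against construction-time expectations rather than re-derived ones.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# A CDS of n_codons: ATG start, non-stop internal codons, one stop.
random_cds_seq <- function(n_codons) {
  all_codons <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                BASES, paste0))
  internal <- setdiff(all_codons, STOP_CODONS)
  paste(c("ATG", sample(internal, n_codons - 2L, replace = TRUE),
          sample(STOP_CODONS, 1L)), collapse = "")
}

#' Generate a toy genomic locus with gene models
#'
#' Builds one chromosome of random sequence carrying non-overlapping
#' transcripts on both strands. Each transcript has 1-4 exons; a
#' \code{coding_fraction} of them receive a CDS whose spliced sequence is a
#' well-formed open reading frame (ATG start, no internal stop, length
#' divisible by 3) written into the genome, with short UTRs on both sides.
#' Transcripts are spaced so that their 1-kb flanks stay clear of each
#' other, keeping every feature class (exonic, splicing, UTRs, intronic,
#' flanks, intergenic) represented and unambiguous.
#'
#' @param seed integer RNG seed.
#' @param n_transcripts number of transcripts to place.
#' @param coding_fraction fraction of transcripts given a CDS (0..1).
#' @param chrom chromosome label.
#' @param out_dir when non-NULL, write \code{locus.fa} and \code{locus.gtf}
#'   there.
#' @return list with \code{genome} (DNAStringSet), \code{gtf} (data frame of
#'   GTF records), \code{transcripts} (layout table used as ground truth),
#'   and \code{paths} when files were written.
#' @export
generate_locus <- function(seed, n_transcripts = 6, coding_fraction = 2 / 3,
                           chrom = "1", out_dir = NULL) {
  if (coding_fraction < 0 || coding_fraction > 1) {
    stop("coding_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    n_coding <- round(n_transcripts * coding_fraction)
    is_coding <- rep(FALSE, n_transcripts)
    if (n_coding > 0) is_coding[seq_len(n_coding)] <- TRUE

    gtf <- list(); layout <- list()
    cursor <- 1500L  # leave an intergenic margin before the first flank
    exon_counter <- 0L
    cds_strings <- list()

    for (t in seq_len(n_transcripts)) {
      n_ex <- sample(1:4, 1)
      exon_len <- sample(120:400, n_ex, replace = TRUE)
      intron_len <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE)
                    else integer(0)
      strand <- sample(c("+", "-"), 1)
      tx_start <- cursor + sample(2100:2600, 1)  # > 2 * flank + margin
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      p <- tx_start
      for (e in seq_len(n_ex)) {
        ex_start[e] <- p
        ex_end[e] <- p + exon_len[e] - 1L
        p <- ex_end[e] + 1L + (if (e < n_ex) intron_len[e] else 0L)
      }
      cursor <- ex_end[n_ex]
      tid <- sprintf("ENST%08d", t)
      gid <- sprintf("ENSG%08d", t)
      gname <- sprintf("GENE%d", t)
      biotype <- if (is_coding[t]) "protein_coding" else "lincRNA"

      gtf[[length(gtf) + 1L]] <- data.frame(
        seqname = chrom, feature = "gene", start = ex_start[1],
        end = ex_end[n_ex], strand = strand, frame = NA_integer_,
        gene_id = gid, transcript_id = NA_character_,
        exon_id = NA_character_, gene_name = gname, biotype = biotype,
        stringsAsFactors = FALSE)
      gtf[[length(gtf) + 1L]] <- data.frame(
        seqname = chrom, feature = "transcript", start = ex_start[1],
        end = ex_end[n_ex], strand = strand, frame = NA_integer_,
        gene_id = gid, transcript_id = tid, exon_id = NA_character_,
        gene_name = gname, biotype = biotype, stringsAsFactors = FALSE)
      exon_ids <- character(n_ex)
      for (e in seq_len(n_ex)) {
        exon_counter <- exon_counter + 1L
        exon_ids[e] <- sprintf("ENSE%08d", exon_counter)
        gtf[[length(gtf) + 1L]] <- data.frame(
          seqname = chrom, feature = "exon", start = ex_start[e],
          end = ex_end[e], strand = strand, frame = NA_integer_,
          gene_id = gid, transcript_id = tid, exon_id = exon_ids[e],
          gene_name = gname, biotype = biotype, stringsAsFactors = FALSE)
      }

      cds_rows <- NULL
      if (is_coding[t]) {
        # CDS in transcript coordinates: UTRs of 20-60 bp on each end.
        total_exonic <- sum(exon_len)
        utr5_len <- sample(20:60, 1)
        utr3_len <- sample(20:60, 1)
        cds_len <- total_exonic - utr5_len - utr3_len
        cds_len <- cds_len - cds_len %% 3L
        stopifnot(cds_len >= 9L)
        # Transcript-order exon list (genomic order flipped on minus strand).
        ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
        # Map transcript offsets [utr5_len+1, utr5_len+cds_len] to genomic
        # per-exon CDS segments.
        off <- 0L
        cds_lo <- utr5_len + 1L; cds_hi <- utr5_len + cds_len
        seg <- list()
        for (e in ord) {
          len <- exon_len[e]
          s_t <- max(cds_lo, off + 1L); e_t <- min(cds_hi, off + len)
          if (s_t <= e_t) {
            if (strand == "+") {
              gs <- ex_start[e] + (s_t - off - 1L)
              ge <- ex_start[e] + (e_t - off - 1L)
            } else {
              ge <- ex_end[e] - (s_t - off - 1L)
              gs <- ex_end[e] - (e_t - off - 1L)
            }
            seg[[length(seg) + 1L]] <- c(gs, ge)
          }
          off <- off + len
        }
        cds_rows <- do.call(rbind, seg)
        for (s in seq_len(nrow(cds_rows))) {
          gtf[[length(gtf) + 1L]] <- data.frame(
            seqname = chrom, feature = "CDS", start = cds_rows[s, 1],
            end = cds_rows[s, 2], strand = strand, frame = NA_integer_,
            gene_id = gid, transcript_id = tid, exon_id = NA_character_,
            gene_name = gname, biotype = biotype, stringsAsFactors = FALSE)
        }
        cds_strings[[tid]] <- list(strand = strand, segments = cds_rows,
                                   n_codons = cds_len %/% 3L)
      }
      layout[[length(layout) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, gene_name = gname, chrom = chrom,
        strand = strand, start = ex_start[1], end = ex_end[n_ex],
        coding = is_coding[t],
        exon_starts = paste(ex_start, collapse = ","),
        exon_ends = paste(ex_end, collapse = ","),
        cds_starts = if (is_coding[t]) paste(cds_rows[, 1], collapse = ",")
                     else "",
        cds_ends = if (is_coding[t]) paste(cds_rows[, 2], collapse = ",")
                   else "",
        stringsAsFactors = FALSE)
    }
    chrom_len <- cursor + 2000L
    seq_chars <- strsplit(random_dna(chrom_len), "")[[1]]

    # Overwrite CDS positions with a clean open reading frame.
    for (tid in names(cds_strings)) {
      info <- cds_strings[[tid]]
      cds_seq <- random_cds_seq(info$n_codons)
      # genomic order first, then reverse whole list for minus-strand
      # transcription order
      segs <- info$segments[order(info$segments[, 1]), , drop = FALSE]
      coords <- unlist(lapply(seq_len(nrow(segs)), function(i)
        segs[i, 1]:segs[i, 2]))
      if (info$strand == "-") coords <- rev(coords)
      bases <- strsplit(cds_seq, "")[[1]]
      if (info$strand == "-") bases <- complement_base(bases)
      seq_chars[coords] <- bases
    }

    genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
    names(genome) <- chrom
    gtf_df <- do.call(rbind, gtf)
    layout_df <- do.call(rbind, layout)
    rownames(gtf_df) <- rownames(layout_df) <- NULL

    out <- list(genome = genome, gtf = gtf_df, transcripts = layout_df)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(out_dir, "locus.fa")
      Biostrings::writeXStringSet(genome, fa)
      gtf_path <- file.path(out_dir, "locus.gtf")
      write_gtf(gtf_df, gtf_path)
      out$paths <- c(fasta = fa, gtf = gtf_path)
    }
    out
  })
}

# Serialize GTF records (inverse of read_gtf for the fields we use).
write_gtf <- function(gtf_df, path) {
  attrs <- vapply(seq_len(nrow(gtf_df)), function(i) {
    r <- gtf_df[i, ]
    parts <- c(sprintf('gene_id "%s";', r$gene_id))
    if (!is.na(r$transcript_id)) {
      parts <- c(parts, sprintf('transcript_id "%s";', r$transcript_id))
    }
    if (!is.na(r$exon_id)) {
      parts <- c(parts, sprintf('exon_id "%s";', r$exon_id))
    }
    parts <- c(parts, sprintf('gene_name "%s";', r$gene_name),
               sprintf('gene_biotype "%s";', r$biotype))
    paste(parts, collapse = " ")
  }, character(1))
  lines <- paste(gtf_df$seqname, "toygen", gtf_df$feature, gtf_df$start,
                 gtf_df$end, ".", gtf_df$strand,
                 ifelse(is.na(gtf_df$frame), ".", gtf_df$frame),
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Evidence number required for each class letter.
CLASS_COUNT <- c(A = 5L, B = 4L, C = 3L, D = 2L, E = 1L)

#' Generate editing-site resource tables with a planned evidence-class mix
#'
#' For each requested site the generator draws a resource composition that
#' yields the target class: the evidence number equals the class's count
#' (A needs 5, ... E needs 1), contributed by distinct resources plus
#' optionally one Alu overlap. Class A sites keep Alu context whenever fewer
#' than five plain resources are used. Requested compositions that cannot be
#' realized (e.g. class A from fewer than four resources without Alu) raise
#' an error. Alu repeat intervals are written to cover exactly the
#' Alu-flagged sites, plus unrelated decoy repeats.
#'
#' @param seed integer RNG seed.
#' @param class_mix named integer vector, e.g. \code{c(A = 1, D = 3)}:
#'   number of sites to plant per evidence class.
#' @param genome genome the sites are placed on (reference bases are taken
#'   from it).
#' @param registry resource registry.
#' @param edit_bias fraction of sites planted as A-to-G / T-to-C
#'   (the A-to-I signature); remaining sites get a random substitution.
#' @param out_dir when non-NULL, write one \code{<resource>.tsv} per
#'   registry resource and \code{repeats.bed} there.
#' @return list with \code{records} (named list of resource data frames),
#'   \code{repeats}, \code{kb_truth} (per-site expected memberships,
#'   Alu name and class), and \code{paths} when files were written.
#' @export
generate_resources <- function(seed, class_mix = c(A = 1, B = 2, C = 3,
                                                   D = 4, E = 4),
                               genome, registry = default_registry(),
                               edit_bias = 0.7, out_dir = NULL) {
  bad <- CLASS_COUNT[names(class_mix)] > length(registry) + 1L
  if (any(is.na(CLASS_COUNT[names(class_mix)]))) {
    stop("class_mix names must be evidence classes A-E")
  }
  if (any(bad)) {
    stop("requested class needs more evidence than registry size + Alu allows")
  }
  with_seed(seed, {
    chrom <- names(genome)[1]
    chrom_len <- length(genome[[chrom]])
    n_sites <- sum(class_mix)
    # Well-spaced positions so an Alu interval never covers a second site.
    pos <- sort(sample(seq(100L, chrom_len - 100L, by = 60L), n_sites))
    classes <- rep(names(class_mix), class_mix)

    tissues <- c("brain", "liver", "breast", "cervix", "lymphoblastoid")
    sites <- list(); alu_rows <- list()
    for (i in seq_len(n_sites)) {
      ref <- genome_base(genome, chrom, pos[i])
      if (stats::runif(1) < edit_bias && ref %in% c("A", "T")) {
        alt <- if (ref == "A") "G" else "C"
        strand <- if (ref == "A") "+" else "-"
      } else {
        alt <- sample(setdiff(BASES, ref), 1)
        strand <- sample(c("+", "-"), 1)
      }
      need <- CLASS_COUNT[[classes[i]]]
      # Alu can stand in for one evidence unit when feasible.
      use_alu <- if (need > length(registry)) TRUE
                 else if (need == 1L) FALSE
                 else stats::runif(1) < 0.5
      n_res <- need - as.integer(use_alu)
      members <- sort(sample(registry, n_res))
      alu_name <- ""
      if (use_alu) {
        alu_name <- sample(c("AluSx", "AluY", "AluJb"), 1)
        alu_rows[[length(alu_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos[i] - sample(5:20, 1),
          end = pos[i] + sample(5:20, 1), name = alu_name,
          family = "SINE/Alu", stringsAsFactors = FALSE)
      }
      sites[[i]] <- data.frame(
        chrom = chrom, pos = pos[i], dna_base = ref, rna_base = alt,
        strand = strand,
        memberships = paste(members[order(match(members, registry))],
                            collapse = ","),
        alu_name = alu_name, class = classes[i],
        tissue = sample(tissues, 1),
        pubmed = sprintf("%08d", sample.int(4e7, 1) + 1e7),
        stringsAsFactors = FALSE)
    }
    kb_truth <- do.call(rbind, sites)
    rownames(kb_truth) <- NULL

    # Decoy repeats that cover no planted site.
    decoys <- data.frame(
      chrom = chrom,
      start = c(5L, chrom_len - 80L), end = c(45L, chrom_len - 30L),
      name = c("L1MA4", "MIRb"), family = c("LINE/L1", "SINE/MIR"),
      stringsAsFactors = FALSE)
    repeats <- rbind(do.call(rbind, alu_rows), decoys)
    repeats <- repeats[order(repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL

    records <- lapply(registry, function(res) {
      idx <- vapply(kb_truth$memberships, function(m)
        res %in% split_csv(m), logical(1))
      k <- kb_truth[idx, , drop = FALSE]
      data.frame(resource_id = res, chrom = k$chrom, pos = k$pos,
                 dna_base = k$dna_base, rna_base = k$rna_base,
                 strand = k$strand, tissue_sources = k$tissue,
                 pubmed_ids = k$pubmed, stringsAsFactors = FALSE)
    })
    names(records) <- registry

    out <- list(records = records, repeats = repeats, kb_truth = kb_truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c()
      for (res in registry) {
        p <- file.path(out_dir, paste0(tolower(res), ".tsv"))
        r <- records[[res]]
        tsv <- data.frame(chrom = r$chrom, pos = r$pos, in_dna = r$dna_base,
                          in_rna = r$rna_base, strand = r$strand,
                          source = r$tissue_sources, pubmed = r$pubmed_ids,
                          stringsAsFactors = FALSE)
        utils::write.table(tsv, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[res] <- p
      }
      bed <- file.path(out_dir, "repeats.bed")
      writeLines(paste(repeats$chrom, repeats$start, repeats$end,
                       repeats$name, repeats$family, sep = "\t"), bed)
      paths["repeats"] <- bed
      out$paths <- paths
    }
    out
  })
}

#' Generate paired DNA and RNA VCFs with planted germline and RDD sites
#'
#' The DNA VCF holds germline variants; the RNA VCF holds the same germline
#' variants plus planted RNA-DNA difference (RDD) sites, so the expected
#' output of \code{\link{compare_rdd}} is exactly the planted RDD set.
#' Planted RDD substitutions are biased toward the A-to-I signature
#' (A-to-G on plus, T-to-C on minus reads of the genomic strand).
#'
#' @param seed integer RNG seed.
#' @param genome genome to place variants on.
#' @param n_germline,n_rdd numbers of germline and RDD sites.
#' @param rdd_sites optional data frame (\code{chrom}, \code{pos},
#'   \code{dna_base}, \code{rna_base}) of predetermined RDD sites (e.g.
#'   knowledgebase sites); sampled from when provided.
#' @param edit_bias A-to-G / T-to-C fraction for de-novo RDD sites.
#' @param out_dir when non-NULL, write \code{dna.vcf} and \code{rna.vcf}.
#' @return list with \code{dna}, \code{rna} (VCF record data frames),
#'   \code{manifest} (\code{planted_germline}, \code{planted_rdd} with
#'   expected edit types), and \code{paths} when files were written.
#' @export
generate_paired_vcfs <- function(seed, genome, n_germline = 10, n_rdd = 7,
                                 rdd_sites = NULL, edit_bias = 0.7,
                                 out_dir = NULL) {
  with_seed(seed, {
    chrom <- names(genome)[1]
    chrom_len <- length(genome[[chrom]])
    taken <- if (!is.null(rdd_sites)) rdd_sites$pos else integer(0)

    if (!is.null(rdd_sites)) {
      if (n_rdd > nrow(rdd_sites)) {
        stop("n_rdd exceeds the number of provided rdd_sites")
      }
      pick <- sort(sample(nrow(rdd_sites), n_rdd))
      rdd <- rdd_sites[pick, c("chrom", "pos", "dna_base", "rna_base"),
                       drop = FALSE]
    } else {
      if (n_germline + n_rdd > (chrom_len - 200L) %/% 3L) {
        stop("n_germline + n_rdd exceeds available positions")
      }
      pos <- sample(setdiff(100:(chrom_len - 100), taken), n_rdd)
      ref <- genome_base(genome, chrom, pos)
      alt <- vapply(seq_along(pos), function(i) {
        if (stats::runif(1) < edit_bias && ref[i] %in% c("A", "T")) {
          if (ref[i] == "A") "G" else "C"
        } else sample(setdiff(BASES, ref[i]), 1)
      }, character(1))
      rdd <- data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                        dna_base = ref, rna_base = alt,
                        stringsAsFactors = FALSE)
    }
    rdd <- rdd[order(rdd$pos), , drop = FALSE]

    germ_pool <- setdiff(100:(chrom_len - 100), rdd$pos)
    germ_pos <- sort(sample(germ_pool, n_germline))
    germ_ref <- genome_base(genome, chrom, germ_pos)
    germ_alt <- vapply(germ_ref, function(r) sample(setdiff(BASES, r), 1),
                       character(1), USE.NAMES = FALSE)
    germline <- data.frame(chrom = rep(chrom, length(germ_pos)),
                           pos = germ_pos, dna_base = germ_ref,
                           rna_base = germ_alt, stringsAsFactors = FALSE)

    as_vcf <- function(df) {
      n <- nrow(df)
      data.frame(chrom = df$chrom, pos = df$pos, id = rep(".", n),
                 ref = df$dna_base, alt = df$rna_base, qual = rep(50, n),
                 filter = rep("PASS", n), info = rep(".", n),
                 stringsAsFactors = FALSE)
    }
    dna <- as_vcf(germline)
    rna <- as_vcf(rbind(germline, rdd))
    rna <- rna[order(rna$pos), , drop = FALSE]
    rownames(rna) <- NULL

    rdd$expected_edit_type <- vapply(seq_len(nrow(rdd)), function(i)
      classify_edit_type(rdd$dna_base[i], rdd$rna_base[i], "+"), character(1))

    out <- list(dna = dna, rna = rna,
                manifest = list(planted_germline = germline,
                                planted_rdd = rdd, seed = seed))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      dna_path <- file.path(out_dir, "dna.vcf")
      rna_path <- file.path(out_dir, "rna.vcf")
      write_vcf(dna, dna_path)
      write_vcf(rna, rna_path)
      out$paths <- c(dna = dna_path, rna = rna_path)
    }
    out
  })
}

#' Generate a complete fixture set with a ground-truth manifest
#'
#' Chains the locus, resource and paired-VCF generators: the genome and gene
#' models are built first, editing-site resources are planted on the genome,
#' and the RNA VCF's RDD sites are drawn from the planted knowledgebase
#' sites (so default-mode annotation finds them) on top of shared germline
#' variants. All files plus a YAML manifest are written to \code{out_dir}.
#'
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @param n_transcripts,coding_fraction locus parameters.
#' @param class_mix evidence-class mix for planted sites.
#' @param n_germline germline variant count.
#' @param n_rdd RDD count (drawn from planted knowledgebase sites).
#' @return list with the in-memory pieces (\code{locus}, \code{resources},
#'   \code{vcfs}), the combined \code{manifest}, and all file \code{paths}.
#' @export
simulate_fixture_set <- function(seed, out_dir, n_transcripts = 6,
                                 coding_fraction = 2 / 3,
                                 class_mix = c(A = 1, B = 2, C = 3, D = 4,
                                               E = 4),
                                 n_germline = 10, n_rdd = 7) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locus <- generate_locus(seed, n_transcripts = n_transcripts,
                          coding_fraction = coding_fraction,
                          out_dir = out_dir)
  resources <- generate_resources(seed + 1L, class_mix = class_mix,
                                  genome = locus$genome, out_dir = out_dir)
  vcfs <- generate_paired_vcfs(seed + 2L, genome = locus$genome,
                               n_germline = n_germline, n_rdd = n_rdd,
                               rdd_sites = resources$kb_truth,
                               out_dir = out_dir)
  manifest <- list(
    seed = seed,
    transcripts = df_to_rows(locus$transcripts),
    kb_truth = df_to_rows(resources$kb_truth),
    planted_germline = df_to_rows(vcfs$manifest$planted_germline),
    planted_rdd = df_to_rows(vcfs$manifest$planted_rdd)
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  list(locus = locus, resources = resources, vcfs = vcfs,
       manifest = manifest,
       paths = c(locus$paths, resources$paths, vcfs$paths,
                 manifest = manifest_path))
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}
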