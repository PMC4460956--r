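Package: editgrade
Title: Evidence-Graded Annotation and Comparison of RNA-Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds an evidence-graded knowledgebase of RNA-editing sites by
    merging editing-site resources keyed on chromosome, position and
    reference/alternative base, and grades each site on a five-level (A-E)
    evidence scale that counts supporting resources plus Alu-repeat context.
    Annotates RNA-DNA difference (RDD) sites with genomic features (exonic,
    splicing, ncRNA, UTRs, intronic, flanks, intergenic), synonymous or
    nonsynonymous codon effects, Alu overlap and Ensembl gene, transcript and
    exon identifiers, producing a fixed 17-column table. Compares paired DNA
    and RNA variant calls to nominate editing candidates, intersects known
    sites across samples, and summarizes annotated sites as tables and bar
    plots. A seeded generator produces toy genomes, gene models, resource
    tables, repeat tracks and paired VCFs with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ggplot2,
    yaml,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
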