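---
title: "Evidence-graded annotation of RNA-editing sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-graded annotation of RNA-editing sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editgrade)
```

## The problem

RNA editing rewrites single nucleotides of a transcript relative to its
genomic template; in humans the dominant form is A-to-I deamination by ADAR,
observed as A→G in sequencing data and concentrated in double-stranded RNA
formed by inverted Alu repeats. Site lists called directly from RNA-Seq are
contaminated by alignment artifacts and unrecognized genomic variation, so
a reported RNA-DNA difference (RDD) site is best treated as a hypothesis
whose credibility grows with the number of independent resources that have
reported it. `editgrade` operationalizes that idea: a knowledgebase merged
from editing-site resources, a five-level evidence grade per site, rule-based
genomic annotation, and paired-VCF / cross-sample comparison.

## The evidence model

Resources are registered in a `ResourceRegistry` (default: DARNED, ENCODE,
RADAR, and two publication-derived site lists labelled BAHN and LI; the
registry is configurable through `default_registry()` because the literature
is not perfectly consistent about which five lists constitute the canon).
Sites merge on the exact key *(chromosome, position, DNA base, RNA base)* —
strand is deliberately not part of the key, since resources disagree on
strand conventions more often than on coordinates. For a merged site

$$N = |M| + \mathbf{1}[\text{Alu}] , \qquad
\text{class} = \begin{cases} \text{A} & N \ge 5\\ \text{B} & N = 4\\
\text{C} & N = 3\\ \text{D} & N = 2\\ \text{E} & N = 1 \end{cases}$$

where $M$ is the set of member resources and the indicator is 1 when the
position falls inside a RepeatMasker repeat whose name starts with "Alu".
Two asymmetries are intentional:

* Alu adds one unit of evidence but cannot create a site ($M$ must be
  nonempty): repeat context corroborates, it does not report.
* A site supported by all five resources *and* Alu has $N = 6$; the class
  scale has exactly five levels, so $N \ge 5$ clamps to A.

Merged list fields (tissue sources, PubMed ids, data references) are unions.
To make integration provably order-independent, resources are always
processed in registry order; strand is decided by majority vote among
resources that report one, with ties recorded as unknown.

## Genomic-feature classification

Features follow the conventional annotation taxonomy, resolved by fixed
precedence when a position has several plausible labels:

exonic > splicing > ncRNA > 5'UTR > 3'UTR > intronic > upstream =
downstream > intergenic.

The definitions, stated precisely since they are the substance of the
classifier:

* **exonic** — the position overlaps a CDS segment of a coding transcript.
* **splicing** — within 2 bp of an internal exon/intron junction, on either
  side: for a donor exon end $E$ the window is $\{E-1, E, E+1, E+2\}$, for
  an acceptor exon start $S$ it is $\{S-2, S-1, S, S+1\}$. A position that
  is also in a CDS reports exonic (the tie-break is deterministic and
  favors the coding call).
* **ncRNA** — in an exon of a transcript with no CDS annotation. A
  transcript is non-coding iff it has no CDS feature; the biotype attribute
  is carried along but not trusted, which keeps the rule robust across GTF
  dialects. Intronic positions of non-coding transcripts classify
  *intronic*: with a single-label scheme, one of ncRNA/intronic has to win,
  and the exon/intron distinction is the more informative one. The
  separate ncRNA *flag* (column 17) is true whenever any transcript
  overlapping the position is non-coding, so no information is lost.
* **5'UTR / 3'UTR** — exonic positions of a coding transcript outside the
  CDS genomic extent, sided by strand. UTRs are derived from exon and CDS
  features, so GTFs without explicit UTR records are fully supported.
* **intronic** — within the transcript span but in no exon.
* **upstream / downstream** — within the 1-kb (1000 bp) flank 5' of the
  transcription start site / 3' of the transcription end, strand-aware.
  Exactly 1000 bp away is in the flank; 1001 bp is intergenic. The two
  flank labels share a precedence rank; the rare site lying in both flanks
  of different transcripts resolves to upstream, for determinism.
* **intergenic** — everything else, including positions on chromosomes with
  no annotation (flagged with a warning).

A site overlapping several transcripts takes the highest-precedence label;
the gene, ENSG, ENST and ENSE columns carry comma-joined, lexically sorted
lists of all contributing identifiers, so shuffling transcript input order
cannot change any output byte. The test suite checks the classifier against
an independent brute-force implementation of these definitions at *every*
position of a generated multi-gene locus (~19 kb), including the window and
flank boundaries.

## Coding effect

For a site inside a CDS, the spliced CDS coordinate list is assembled in
transcription order (reverse-complemented on the minus strand), the
containing codon is rebuilt from the reference genome, the edited base is
substituted (complemented first for minus-strand transcripts, since VCF
bases are plus-strand), and both codons are translated under the standard
nuclear genetic code: identical amino acids → synonymous, otherwise
nonsynonymous. Degenerate situations return `not_applicable` with a
warning rather than a guess: positions outside any CDS, and transcripts
whose annotated CDS length is not divisible by 3. When the genome base
disagrees with the claimed reference base, the genome wins and the mismatch
is logged — the reference sequence is the more trustworthy witness. When
several coding transcripts contain the site, transcripts are evaluated in
lexical id order and the first applicable status is reported, a
deterministic choice in place of an arbitrary one. Correctness is tested
exhaustively: all 64 codons × 3 positions × 3 alternative bases against an
independent translate-and-compare oracle, plus plus/minus strand symmetry.

## Comparison semantics

**RDD compare.** An RNA variant is a candidate iff *no* DNA variant exists
at its position. Exclusion is by position, not by matching alternative
allele: a heterozygous genomic variant explains an RNA mismatch regardless
of how the allele was written. The method consumes already-called VCFs and
applies no coverage or quality thresholds by default (a minimum-QUAL hook
exists in the readers' output for callers who want one); filtering belongs
to the variant caller.

**Known-site compare.** Samples are compared by the exact site key, so the
same position edited to different bases counts as different sites —
mirroring the integration key. For each unordered pair the intersection and
both differences are reported; a sample's unique sites are those present in
no other sample. The identities $|A \cap B| + |A \setminus B| = |A|$ are
enforced by property tests on random fixtures.

**Editing types.** The 12 ordered substitutions X-to-Y are reported in
transcript orientation: both bases are complemented for minus-strand sites,
so genomic T>C under a minus-strand gene reports as A-to-G. Unknown strand
is treated as plus — the conservative choice that never invents a
complementation.

## The synthetic-fixture generator

The generator is first-class, tested code, and defines the conditions under
which the package's guarantees are demonstrated:

* **Locus** (`generate_locus`): one chromosome of 15–25 kb (six transcripts
  by default, spaced > 2 kb so 1-kb flanks stay unambiguous), 1–4 exons per
  transcript on both strands, two thirds coding. Coding transcripts get
  20–60 bp UTRs and a CDS written into the genome as a well-formed ORF
  (ATG, no internal stop, terminal stop, length divisible by 3) so that
  codon-effect annotation operates on realistic sequence.
* **Resources** (`generate_resources`): a requested class mix (default one
  A, two B, three C, four D, four E sites — a small pyramid echoing the
  shape of real integrated collections, where two-resource sites dominate)
  is realized by sampling, per site, a resource subset and optional Alu
  interval whose total equals the class's evidence number. 70% of planted
  sites carry the A-to-G / T-to-C signature, reflecting A-to-I
  predominance; the proportion is configurable.
* **Paired VCFs** (`generate_paired_vcfs`): germline variants appear in
  both files, RDD sites only in the RNA file; in the bundled
  `simulate_fixture_set` the RDD sites are drawn from the planted
  knowledgebase sites so that default-mode annotation finds them. Ten
  germline and seven RDD sites per fixture keep each of the 100 acceptance
  replicates fast while leaving room for collisions to occur if the logic
  were wrong.

All generators are pure functions of an explicit integer seed (global RNG
state is saved and restored), which is what makes the end-to-end
byte-identity test meaningful.

What the fixtures do *not* emulate — and therefore what passing tests do
not show about real data: read-level evidence (coverage, strand bias,
alignment artifacts), multi-chromosome genomes, overlapping genes,
alternative transcripts of one gene, real resource-export formats (the
resource TSV schema here is a documented normalization; adapters for real
DARNED/RADAR dumps are an extension point), and genome-build liftover.
The package grades and annotates sites; it does not validate the variant
calls it is given.

## Numerical and serialization choices

All internal site coordinates are 1-based; BED and RepeatMasker input is
converted once, at read time (a 1-based position p overlaps a 0-based
half-open interval iff start < p ≤ end). Chromosome labels are normalized
by stripping the "chr" prefix by default, configurable in every reader,
because Ensembl gene models and UCSC-derived repeat tracks disagree.
Multiallelic VCF records are split into one record per alternative allele;
indels and symbolic alleles are excluded at ingestion with a logged count —
editing is single-nucleotide by definition. Summary tables order categories
by count descending then lexically, and plots are rendered from the CSVs,
never from live state, so every quantitative claim in the outputs is
testable from text files. Problem sizes in the test suite (a ~19 kb
exhaustive sweep, 576 codon cases, 100 RDD replicates) were chosen as the
smallest scales at which the corresponding property is exercised
exhaustively rather than by spot checks.

## Known limitations

Evidence grading is a count, not a probability: resources are weighted
equally, and correlated resources (RADAR incorporates earlier site lists)
inflate counts. One annotation row per site means a site in a coding exon
of one transcript and the UTR of another reports only the higher-precedence
feature, with the full transcript list in the id columns. The coding-effect
caller reports the first applicable transcript rather than all of them.
Editing *levels* (the fraction of edited reads) are out of scope, as the
package consumes variant calls, not alignments.
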