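---
title: "Comparing transcriptomes at isoform resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transcriptomes at isoform resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Two samples can express largely the same *genes* while expressing largely
different *isoforms* of those genes. The canonical illustration is the
comparison of the two MAQC reference RNAs — HBRR (pooled human brain) and
UHRR (ten mixed cell lines): roughly two thirds of expressed genes are
shared, but under a third of expressed isoforms are identical, and a
substantial set of genes produces a protein-coding isoform in one sample
and a long noncoding RNA (lncRNA) in the other. `isocompare` implements
that comparison as a reusable pipeline: expressed-set filtering,
coding-potential classification, gene- vs isoform-level overlap,
bifunctional-gene and category-switch detection, splice-structure
classification of novel lncRNAs, conservation summaries, and a
disease-association screen for lncRNAs via microarray probes.

# Data model and conventions

All coordinates are **0-based half-open** internally; conversion to and
from 1-based closed (GTF) happens only in `read_annotation()` and the
writers. A `transcript_model` is an ordered exon chain on one chromosome
and strand; exons must be disjoint with at least one intronic base
between them, and unstranded records are rejected because splice-site
semantics need strand.

Isoform identity across samples is, by default, **full exon-chain
equality** including terminal ends (`exon_chain_key()`): with a fixed
annotation set this matches identity-by-annotated-transcript, and it is
robust to transcript-ID drift between runs. Whether the original
comparison intersected by shared IDs or by structure is not knowable from
the published account, so both modes are provided
(`identity = "transcript_id"`); with one shared annotation they coincide,
which the tests verify on toy sets. No terminal-trim tolerance is applied
by default — assembled inputs with ragged ends should be normalized
upstream.

BED12 has no gene field. The package writes names as
`gene_id|transcript_id` and the reader recovers gene grouping from that
convention; names without `|` make each transcript its own gene.
Chromosome-name dialects are kept as-is; `normalize_chrom()` can force
either style when inputs disagree.

# Expression and the expressed set

RPKM is the quotient `1e9 * C / (N * L)` for `C` exonic reads, `N` total
mapped reads and `L` spliced bases. A transcript is *expressed* at
**RPKM >= 0.1, inclusive** — a transcript at exactly 0.1 is kept — and a
gene is *expressed* when at least one of its isoforms passes (the
published account does not define "expressed gene"; this definition is
the one consistent with its per-gene isoform tables). Expression may be
supplied precomputed (the usual case: an upstream quantifier produced
it) or as counts plus library size; supplying both inconsistently beyond
1e-6 relative error is an error rather than a silent preference.

# Coding classification

Coding-potential scores are consumed, not computed (the upstream scorer
is a CPC-style classifier; re-implementing its SVM is out of scope). The
sign convention is: score `> 0` means coding, with 0 counted noncoding
(matching how such scorers label their own output); the cutoff is
exposed for sensitivity analysis. A noncoding transcript is a **long
ncRNA only when strictly longer than 200 nt** — a 200-nt transcript is a
short ncRNA. Short noncoding transcripts are tallied but not analyzed
further.

A gene is **bifunctional** when its expressed isoforms include at least
one protein-coding transcript *and at least one long ncRNA*. A short
noncoding isoform does not confer bifunctionality: the category tracks
genes that produce both a protein and a long regulatory RNA, and the
reference analysis ties its bifunctional counts to lncRNA production.

# Two-sample comparison

`comparison_summary()` partitions genes and isoforms into common /
A-only / B-only, with exclusive parts reported as percentages of their
own sample's totals, rounded **half-up to two decimals** for parity with
published tables. Genes present in both samples count as common by
gene_id alone, even with zero overlapping isoforms — that two-level
discrepancy is the phenomenon of interest. Derived sets:

* `identical_isoform_set_genes()` — common genes whose expressed isoform
  key-sets are exactly equal in both samples;
* `category_switch_genes()` — common genes with a lncRNA (or a coding
  isoform) in exactly one sample; note a gene can legitimately sit in
  one lncRNA set and one coding set at once;
* `bifunctional_union()` — the union of per-sample bifunctional genes.

# Splice-structure classes

A novel transcript is classified against *all* annotated isoforms of its
gene by a fixed-precedence decision tree: identical chain, else intron
retention (an exon fully contains an annotated intron, both splice sites
strictly inside), else novel boundary/exon (an internal boundary absent
from the gene's annotated boundary set, or an exon overlapping no
annotated exon), else exon skipping. Three choices deserve notes:

* **Precedence** retention > novel > skipping: an engulfed intron is the
  most structurally specific signal; the order is configurable for
  sensitivity analysis, and classification is invariant to the order of
  annotated isoforms because annotated boundaries and introns are
  unioned first.
* **Internal boundaries only**: sequencing-derived 5'/3' termini are
  unreliable, so a transcript differing from annotation only at its
  first start or last end is never called novel (it falls through to
  exon skipping, the residual class).
* "Contains introns" is ambiguous between true intron retention and
  unspliced fragments; the package implements retention (both splice
  sites strictly inside one exon). An unspliced fragment spanning a full
  intron satisfies the same test, so the class is a superset of both
  readings.

# Conservation

Conservation is evaluated over **exonic (spliced) bases only** — the
objects of interest are transcripts, and per-transcript ratios are what
the screen consumes. Two statistics per transcript and clade
(46 vertebrates, 33 placental mammals, 10 primates, or any labels):

* `base_conserved_fraction()` — the fraction of exonic bases whose
  per-base score is **>= 0.9**; bases missing from the track score 0
  (score dumps omit uncovered bases), with a flag to drop them from the
  denominator instead;
* `element_overlap_ratio()` — the fraction of exonic bases covered by
  predicted conserved elements, by interval arithmetic; "contains a
  conserved element" means at least one overlapped base.

No numeric "highly conserved transcript" cutoff is imposed: the
published account never states one, so the base-fraction statistic is
exposed and the cutoff left to the user.

# Disease screen

* **Probe matching** is exact and unique: a probe is reported only when
  its sequence occurs at exactly one position across the whole target
  transcript set, counting every occurrence position (two hits within
  one transcript are as disqualifying as one hit in each of two). Only
  the sense spliced sequence is searched by default — the stricter
  reading of aligning probes *onto* transcripts — with a
  both-orientations flag for arrays of uncertain probe orientation.
  Uniqueness is relative to the supplied transcript set, not the genome.
  A pre-filter to probes without gene symbols is available, since such
  probes are the ones free to represent unannotated transcripts.
* **Differential expression**: the reference analysis names no method,
  so the package uses the conventional assumption-light default — Welch
  two-sample t on `log2(x + 1)`, Benjamini–Hochberg q-values, flagged at
  q < 0.05. Rows constant across all samples get p = 1 by convention; a
  clean two-group separation with zero within-group variance is p = 0.
* **Correlation screen**: Pearson r for every ncRNA-probe x gene-probe
  pair, two-sided p from the t transform with n - 2 df; hits need
  `|r| >= 0.4` (inclusive — r exactly 0.4 qualifies) and `p < 0.05`
  (exclusive). The absolute value is used because a negative regulator
  is as relevant as a positive one; the published threshold is printed
  unsigned. Zero-variance rows are skipped and logged.

# The synthetic-data generator

Every pipeline input can be generated with recorded ground truth, which
is what the test suite and the acceptance script run on.

* `generate_gene_catalog()` packs non-overlapping gene loci onto toy
  chromosomes; each gene has a master exon chain, further isoforms are
  distinct exon subsets (so isoforms share exon sequence, as real
  isoforms do — the probe multi-match and splice-variant machinery rely
  on this), and an option plants short (<= 200 nt) single-exon isoforms.
* `generate_paired_transcriptomes()` plants gene- and isoform-level
  overlap, per-transcript coding labels, and optional feature groups.
  Because derived categories are **coupled** (a common gene with coding
  + lncRNA in A only is simultaneously bifunctional-in-A and
  lncRNA-in-A-only), planted groups are disjoint gene sets with fully
  determined label profiles, and the ground truth records the exact
  realized expectation for every downstream set. Planted counts equal
  realized counts when one feature class is planted at a time. RPKMs are
  log-normal (median ~5) clamped at the threshold, with records pinned
  at exactly 0.1 and sub-threshold decoys just below it, so the
  inclusive boundary is always exercised. Tables carry RPKM only,
  mirroring the upstream-quantifier entry point.
* Splice variants are explicit edits of a gene's master chain (merge two
  exons / extend an exon partway into its intron / drop an internal
  exon), each provably unambiguous under the classifier's precedence;
  edits colliding with an annotated chain are re-drawn.
* `generate_conservation_tracks()` chooses genes by greedy packing of
  their isoform counts so the covered transcripts number exactly
  `round(frac * n)`, then lays one element per merged exon region of
  each chosen gene — every isoform of a chosen gene is covered, no other
  transcript is, and the planted fraction is recovered exactly.
* `generate_disease_matrices()` uses a log-normal background
  (`2^L - 1`, so the DE test's `log2(x + 1)` recovers `L` exactly) with
  planted case-side shifts in background-SD units, and returns
  correlated probe pairs as bivariate-normal rows on the log scale so
  the planted correlation is exact in expectation.

What the generator does **not** emulate: read-level noise and mapping
ambiguity (expression enters as RPKM, so quantifier uncertainty is
outside the model), paralog cross-mapping, incomplete or wrong
annotation, heavy-tailed microarray noise, or batch structure. Green
tests therefore certify the *combinatorial and statistical machinery* —
partitions, decision trees, interval arithmetic, test calibration — not
robustness to upstream measurement error.

# Numerical choices and problem sizes

Percentages are rounded half away from zero to two decimals.
Count/RPKM consistency tolerance is 1e-6 relative. The default study
conditions of the generator: shared-gene fraction 0.49 of the catalog
(matching the union-level share of common genes in the reference
comparison), shared-isoform probability 0.3, coding fraction 0.96
(noncoding transcripts are a few percent of expressed sets), exon
lengths 80–300 nt, introns 60–400 nt.

The test suite runs on catalogs of tens to low hundreds of genes;
enumeration checks use all exon chains of up to three exons on a
toy locus; DE calibration uses 500 null and 200 shifted simulations of
100 probes x 20 samples; correlation recovery uses 200 draws of five
pairs at n = 40. These sizes make every check exact or tightly
concentrated while keeping the whole suite fast.

# Known limitations

* Exon-chain identity is exact; assembled transcripts with imprecise
  termini will under-count common isoforms unless normalized first.
* The splice classifier assigns one class per transcript; a transcript
  both skipping an exon and retaining an intron reports retention only.
* The exact-and-unique probe rule is evaluated against the supplied
  transcript set; genome-wide cross-hybridization is not modeled.
* `run_pipeline()` orchestrates single files per input; no
  workflow-engine integration or plotting is provided — outputs are
  TSV/JSON tables by design.
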