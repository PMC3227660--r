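#' Published MAQC brain vs cell-line summary counts
#'
#' Summary tables from the reference comparison of the two MAQC reference
#' RNA samples — HBRR (human brain) and UHRR (10 mixed cell lines) —
#' sequenced by RNA-Seq and compared at the isoform level: exon-count and
#' isoforms-per-gene distributions of the expressed sets (at the 0.1 RPKM
#' inclusive threshold), expressed-set totals, gene/isoform overlap
#' counts, bifunctional-gene counts and the splice-class counts of
#' bifunctional-gene long ncRNAs. These serve as worked-example inputs:
#' the package's summary arithmetic applied to them reproduces the
#' reported shares and percentages.
#'
#' @return Named list of data frames: `exon_counts`, `isoforms_per_gene`,
#'   `totals`, `overlap`, `bifunctional`, `splice_classes`.
#' @examples
#' cnt <- maqc_summary_counts()
#' pct_multi_exon(stats::setNames(cnt$exon_counts$brain,
#'                                cnt$exon_counts$exons))
#' @export
maqc_summary_counts <- function() {
  dir <- system.file("extdata", "maqc", package = "isocompare",
                     mustWork = TRUE)
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  list(exon_counts = rd("exon_count_table.tsv"),
       isoforms_per_gene = rd("isoforms_per_gene_table.tsv"),
       totals = rd("expressed_totals.tsv"),
       overlap = rd("overlap_counts.tsv"),
       bifunctional = rd("bifunctional_counts.tsv"),
       splice_classes = rd("splice_class_counts.tsv"))
}

#' Overlap percentages from plain counts
#'
#' The sample-exclusive percentages used in two-sample overlap reports,
#' computed from totals alone: `100 * (n_a - n_common) / n_a` and the
#' analogue for B, rounded half-up to two decimals. [set_overlap()] uses
#' the same arithmetic on realized sets; this counts-level interface
#' serves worked examples where only the totals are published.
#'
#' @param n_a,n_b Expressed totals in samples A and B.
#' @param n_common Number shared between the samples.
#' @return Named numeric vector `pct_a_only`, `pct_b_only`.
#' @examples
#' overlap_percentages(16818, 18431, 11654)  # 30.71, 36.77
#' @export
overlap_percentages <- function(n_a, n_b, n_common) {
  stopifnot(n_common <= n_a, n_common <= n_b, n_a >= 1, n_b >= 1)
  c(pct_a_only = round_half_up(100 * (n_a - n_common) / n_a, 2),
    pct_b_only = round_half_up(100 * (n_b - n_common) / n_b, 2))
}
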