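#!/usr/bin/env Rscript
# Worked examples over the published MAQC brain vs cell-line summary
# counts shipped with the package: the summary arithmetic reproduces the
# reported shares, means and percentages.

suppressPackageStartupMessages(library(isocompare))

cat("== 07 published-table worked examples ==\n")
cnt <- maqc_summary_counts()

ex <- cnt$exon_counts
cat(sprintf("multi-exon transcripts: brain %.2f%%, cell lines %.2f%%\n",
            pct_multi_exon(setNames(ex$brain, ex$exons)),
            pct_multi_exon(setNames(ex$cell_lines, ex$exons))))
iso <- cnt$isoforms_per_gene
cat(sprintf("one-isoform genes: brain %.2f%%, cell lines %.2f%%\n",
            pct_single_isoform(setNames(iso$brain, iso$isoforms)),
            pct_single_isoform(setNames(iso$cell_lines, iso$isoforms))))
tot <- cnt$totals
cat(sprintf("mean isoforms/gene: brain %.2f, cell lines %.2f\n",
            mean_isoforms_per_gene(tot$brain[tot$item == "transcripts"],
                                   tot$brain[tot$item == "genes"]),
            mean_isoforms_per_gene(tot$cell_lines[tot$item == "transcripts"],
                                   tot$cell_lines[tot$item == "genes"])))
for (lv in c("gene", "isoform")) {
  ov <- cnt$overlap[cnt$overlap$level == lv, ]
  p <- overlap_percentages(ov$brain, ov$cell_lines, ov$common)
  cat(sprintf("%s level: brain-only %.2f%%, cell-line-only %.2f%%\n",
              lv, p["pct_a_only"], p["pct_b_only"]))
}
bif <- cnt$bifunctional[cnt$bifunctional$item == "bifunctional_genes", ]
u <- bifunctional_union(paste0("g", seq_len(bif$brain)),
                        c(paste0("g", seq_len(bif$common)),
                          paste0("h", seq_len(bif$cell_lines -
                                                bif$common))))
cat(sprintf("bifunctional genes: %d brain + %d cell lines (%d shared) -> union %d\n",
            bif$brain, bif$cell_lines, bif$common, u$n_union))
cat(sprintf("bifunctional-gene long ncRNAs by splice class: brain %s = %d; cell lines %s = %d\n",
            paste(cnt$splice_classes$brain, collapse = "+"),
            sum(cnt$splice_classes$brain),
            paste(cnt$splice_classes$cell_lines, collapse = "+"),
            sum(cnt$splice_classes$cell_lines)))
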