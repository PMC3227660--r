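#!/usr/bin/env Rscript
# Simulate the full input bundle for the isoform-level two-sample
# comparison: a multi-isoform gene catalog with toy genome, paired
# brain-like/cell-line-like transcriptomes with planted bifunctional,
# switch and novel-splice features, per-clade conservation tracks, probes
# and case/control matrices. Everything downstream (02-06) reads these
# files; ground truth goes to JSON for the later comparisons.

suppressPackageStartupMessages(library(isocompare))
seed <- 20260919 %% 100000
dir <- "results/synthetic_inputs"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)
wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

cat("== 01 simulate: building the study bundle (seed", seed, ") ==\n")
gb <- generate_gene_catalog(300, seed = seed, short_isoform_genes = 60)
cat("catalog:", length(gb$catalog$genes), "genes,",
    length(gb$catalog$transcripts), "transcripts on",
    length(gb$genome), "chromosome(s)\n")

pp <- generate_paired_transcriptomes(
  gb, seed = seed + 1,
  coding_frac = 0.96,
  bifunctional_counts = c(both = 3, a_only = 2, b_only = 2),
  switch_counts = c(lncrna_a_only = 3, lncrna_b_only = 3,
                    coding_a_only = 2, coding_b_only = 2),
  novel_per_class = 5)
cat("sample A:", nrow(pp$sample_a$expression), "expressed transcripts;",
    "sample B:", nrow(pp$sample_b$expression), "\n")

write_gtf(pp$transcripts, file.path(dir, "annotation.gtf"))
write_bed12(gb$catalog, file.path(dir, "catalog.bed12"))
write_genome_fasta(gb$genome, file.path(dir, "genome.fa"))
wt(pp$expression_a, "expression_a.tsv")
wt(pp$expression_b, "expression_b.tsv")
wt(pp$scores_a, "scores_a.tsv")
wt(pp$scores_b, "scores_b.tsv")

ct <- generate_conservation_tracks(gb$catalog, coverage_frac = 0.8,
                                   seed = seed + 2)
for (cl in names(ct$tracks)) {
  write_score_track(ct$tracks[[cl]]$scores,
                    file.path(dir, paste0(cl, ".bedGraph")))
  write_elements_bed(ct$tracks[[cl]]$elements,
                     file.path(dir, paste0(cl, ".bed")))
}
cat("conservation: planted elements under",
    length(ct$truth[[1]]$covered_transcripts), "of",
    length(gb$catalog$transcripts), "transcripts per clade\n")

# probes over the long ncRNAs the screen will target
lab_a <- classify_sample(pp$sample_a, pp$scores_a)
lab_b <- classify_sample(pp$sample_b, pp$scores_b)
lnc <- union(lab_a$transcript_id[lab_a$label == "LONG_NCRNA"],
             lab_b$transcript_id[lab_b$label == "LONG_NCRNA"])
seqs <- extract_transcript_sequences(gb$genome, pp$transcripts[lnc])
pr <- generate_probes(seqs, n_unique = 12, n_multi = 0, n_nomatch = 3,
                      seed = seed + 3)
dm <- generate_disease_matrices(nrow(pr$probes), 10, 10,
                                de_frac = 0.3, effect_size = 4,
                                corr_pairs = 5, rho = 0.66,
                                seed = seed + 4)
# ncRNA probe rows take the generated probe ids; gene-symbol probes get
# arbitrary non-matching sequences (only their matrix rows matter)
set.seed(seed + 5)
gene_probes <- data.frame(
  probe_id = rownames(dm$gene_mat),
  sequence = vapply(seq_len(nrow(dm$gene_mat)), function(i)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
          collapse = ""), character(1)),
  gene_symbol = dm$gene_symbols)
probes <- rbind(pr$probes, gene_probes)
wt(probes, "probes.tsv")
m <- rbind(dm$matrix, 2^dm$gene_mat - 1)
rownames(m) <- c(pr$probes$probe_id, rownames(dm$gene_mat))
wt(data.frame(probe_id = rownames(m), m, check.names = FALSE),
   "disease_matrix.tsv")
wt(data.frame(sample = colnames(m),
              group = rep(c("case", "control"), each = 10)), "groups.tsv")
cat("disease screen:", nrow(pr$probes), "ncRNA probes,",
    nrow(gene_probes), "gene probes,", ncol(m), "samples\n")

truth <- pp$truth
truth$conservation <- ct$truth
truth$probe_categories <- pr$truth
truth$de_probes <- pr$probes$probe_id[match(dm$truth$de_probes,
                                            rownames(dm$matrix))]
truth$corr_pairs <- dm$truth$pairs
jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, null = "null")
cat("ground truth written; bundle complete under", dir, "\n")
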