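test_that("coding call follows the score sign with noncoding ties", {
  expect_equal(label_coding(1.5), "coding")
  expect_equal(label_coding(-0.8), "noncoding")
  expect_equal(label_coding(0), "noncoding")
  expect_error(label_coding(NaN), "finite")
  # configurable cutoff
  expect_equal(label_coding(0.3, cutoff = 0.5), "noncoding")
})

test_that("transcript class applies the strict >200 nt long-ncRNA rule", {
  t250 <- tm("a", cbind(0, 250))
  t200 <- tm("b", cbind(0, 200))
  expect_equal(classify_transcript(t250, -1), "LONG_NCRNA")
  expect_equal(classify_transcript(t200, -1), "SHORT_NCRNA")
  expect_equal(classify_transcript(t250, 2), "PROTEIN_CODING")
  # spliced, not genomic, length decides: 2x150 exons over a long span
  t_spliced <- tm("c", cbind(c(0, 5000), c(150, 5150)))
  expect_equal(classify_transcript(t_spliced, -1), "LONG_NCRNA")
})

test_that("gene category requires a long ncRNA for bifunctionality", {
  expect_equal(classify_gene(c("PROTEIN_CODING", "LONG_NCRNA")),
               "BIFUNCTIONAL")
  expect_equal(classify_gene(c("LONG_NCRNA", "SHORT_NCRNA")), "NCRNA_ONLY")
  expect_equal(classify_gene(c("PROTEIN_CODING", "SHORT_NCRNA")),
               "CODING_ONLY")
  expect_equal(classify_gene("PROTEIN_CODING"), "CODING_ONLY")
  expect_error(classify_gene(character(0)), "no expressed")
})

test_that("labels partition the expressed set and categories partition
           the genes", {
  gb <- generate_gene_catalog(40, seed = 8, short_isoform_genes = 10)
  pp <- generate_paired_transcriptomes(gb, seed = 9, coding_frac = 0.7)
  lab <- classify_sample(pp$sample_a, pp$scores_a)
  expect_equal(nrow(lab), length(pp$sample_a$transcripts))
  expect_true(all(lab$label %in% c("PROTEIN_CODING", "LONG_NCRNA",
                                   "SHORT_NCRNA")))
  expect_equal(unname(lab$label),
               unname(pp$truth$true_label[lab$transcript_id]))
  cats <- classify_genes(lab)
  expect_equal(nrow(cats), length(expressed_genes(pp$sample_a)))
  expect_equal(sum(table(cats$category)), nrow(cats))
})
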