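test_that("catalog generation is deterministic and honors fixed
           distributions", {
  g1 <- generate_gene_catalog(10, seed = 1)
  g2 <- generate_gene_catalog(10, seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(g1$catalog, f1)
  write_gtf(g2$catalog, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$genome, g2$genome)

  # fixed one-isoform catalog pushes the downstream mean to 1.00
  one <- generate_gene_catalog(15, isoforms_per_gene = 1, seed = 2)
  pp <- generate_paired_transcriptomes(one, shared_gene_frac = 1, seed = 3)
  expect_equal(mean_isoforms_per_gene(pp$sample_a), 1)

  # fixed three-exon isoforms put all histogram mass in bin 3
  tri <- generate_gene_catalog(15, isoforms_per_gene = 1,
                               exons_per_isoform = 3, seed = 4)
  pp3 <- generate_paired_transcriptomes(tri, shared_gene_frac = 1, seed = 5)
  tab <- distribution_tables(pp3$sample_a)
  expect_equal(unname(tab$exon_counts[["3"]]), sum(tab$exon_counts))
})

test_that("paired generation plants gene overlap and coding split as
           requested", {
  gb <- generate_gene_catalog(100, seed = 6)
  pp <- generate_paired_transcriptomes(gb, shared_gene_frac = 0.6, seed = 7)
  ov <- compare_gene_sets(pp$sample_a, pp$sample_b)
  expect_equal(length(ov$common), round(0.6 * 100))
  expect_setequal(ov$common, pp$truth$genes_common)
  expect_setequal(ov$a_only, pp$truth$genes_a_only)

  # all-coding split leaves no long ncRNAs downstream
  pp1 <- generate_paired_transcriptomes(gb, coding_frac = 1, seed = 8)
  lab <- classify_sample(pp1$sample_a, pp1$scores_a)
  expect_equal(sum(lab$label == "LONG_NCRNA"), 0L)

  # determinism of the full bundle
  ppa <- generate_paired_transcriptomes(gb, seed = 9)
  ppb <- generate_paired_transcriptomes(gb, seed = 9)
  expect_identical(ppa$expression_a, ppb$expression_a)
  expect_identical(ppa$truth, ppb$truth)
})

test_that("planted identical-set fraction is recovered exactly", {
  gb <- generate_gene_catalog(80, isoforms_per_gene = c("2" = 0.6,
                                                        "3" = 0.4),
                              seed = 10)
  pp <- generate_paired_transcriptomes(gb, shared_gene_frac = 0.5,
                                       identical_set_frac = 0.3, seed = 11)
  ident <- identical_isoform_set_genes(pp$sample_a, pp$sample_b)
  n_common <- length(pp$truth$genes_common)
  expect_equal(length(ident), round(0.3 * n_common))
  expect_setequal(ident, pp$truth$identical_set_genes)
})

test_that("planted bifunctional and switch genes are recovered
           exactly when planted alone", {
  gb <- generate_gene_catalog(120, isoforms_per_gene = c("2" = 0.5,
                                                         "3" = 0.5),
                              seed = 12, short_isoform_genes = 40)
  # bifunctional-only planting: k genes in sample A
  ppb <- generate_paired_transcriptomes(
    gb, coding_frac = 1, seed = 13,
    bifunctional_counts = c(a_only = 25))
  cats <- classify_genes(classify_sample(ppb$sample_a, ppb$scores_a))
  expect_equal(sum(cats$category == "BIFUNCTIONAL"), 25L)
  expect_setequal(cats$gene_id[cats$category == "BIFUNCTIONAL"],
                  ppb$truth$bifunctional_a)

  # switch-only planting (10, 5, 3, 2)
  pps <- generate_paired_transcriptomes(
    gb, coding_frac = 1, seed = 14,
    switch_counts = c(lncrna_a_only = 10, lncrna_b_only = 5,
                      coding_a_only = 3, coding_b_only = 2))
  la <- classify_sample(pps$sample_a, pps$scores_a)
  lb <- classify_sample(pps$sample_b, pps$scores_b)
  sw <- category_switch_genes(pps$sample_a, pps$sample_b, la, lb)
  expect_equal(unname(lengths(sw)), c(10L, 5L, 3L, 2L))
  expect_setequal(sw$lncrna_a_only, pps$truth$switches$lncrna_a_only)
  expect_setequal(sw$coding_b_only, pps$truth$switches$coding_b_only)

  # infeasible planting errors out
  expect_error(generate_paired_transcriptomes(
    gb, seed = 15, switch_counts = c(lncrna_a_only = 1000)),
    "cannot support")
})

test_that("conservation planting covers the exact transcript fraction
           per clade", {
  gb <- generate_gene_catalog(60, seed = 16)
  ct <- generate_conservation_tracks(gb$catalog, coverage_frac = 0.8,
                                     seed = 17)
  n <- length(gb$catalog$transcripts)
  cs <- clade_conservation_summary(unname(gb$catalog$transcripts),
                                   ct$tracks)
  for (cl in names(ct$truth)) {
    expect_equal(
      cs$aggregate$fraction_with_element[cs$aggregate$clade == cl],
      round(0.8 * n) / n)
    covered <- cs$summary$transcript_id[cs$summary$clade == cl &
                                          cs$summary$contains_element]
    expect_setequal(covered, ct$truth[[cl]]$covered_transcripts)
  }
  # zero coverage -> all ratios zero
  ct0 <- generate_conservation_tracks(gb$catalog, coverage_frac = 0,
                                      seed = 18)
  cs0 <- clade_conservation_summary(unname(gb$catalog$transcripts),
                                    ct0$tracks)
  expect_true(all(cs0$summary$element_overlap_ratio == 0))
})

test_that("disease matrices are deterministic with planted DE set", {
  d1 <- generate_disease_matrices(50, 5, 5, de_frac = 0.2, seed = 19)
  d2 <- generate_disease_matrices(50, 5, 5, de_frac = 0.2, seed = 19)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$truth, d2$truth)
  expect_length(d1$truth$de_probes, 10L)
  expect_true(all(d1$matrix >= 0))
})

test_that("expression tables exercise the inclusive threshold boundary", {
  gb <- generate_gene_catalog(50, seed = 20)
  pp <- generate_paired_transcriptomes(gb, seed = 21, boundary_n = 3,
                                       decoy_frac = 0.2)
  expect_equal(sum(pp$expression_a$rpkm == 0.1), 3L)
  expect_true(any(pp$expression_a$rpkm < 0.1))  # decoys present
  expect_true(all(pp$sample_a$expression$rpkm >= 0.1))
  # the boundary records survive the filter
  boundary <- pp$expression_a$transcript_id[pp$expression_a$rpkm == 0.1]
  expect_true(all(boundary %in% pp$sample_a$expression$transcript_id))
})
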