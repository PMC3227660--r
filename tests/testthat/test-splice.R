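ann3 <- list(tm("a1", cbind(c(0, 200, 400), c(100, 300, 500))))

test_that("splice classes follow the fixed-precedence decision tree", {
  expect_equal(classify_splice_structure(
    tm("q1", cbind(c(0, 400), c(100, 500))), ann3), "EXON_SKIPPING")
  expect_equal(classify_splice_structure(
    tm("q2", cbind(0, 300)), ann3), "INTRON_RETENTION")
  expect_equal(classify_splice_structure(
    tm("q3", cbind(c(0, 250, 400), c(100, 300, 500))), ann3),
    "NOVEL_BOUNDARY_OR_EXON")
  expect_equal(classify_splice_structure(
    tm("q4", cbind(c(0, 200, 400), c(100, 300, 500))), ann3), "IDENTICAL")
  expect_error(classify_splice_structure(
    tm("q5", cbind(0, 100), gene = "OTHER"), ann3), "belongs to gene")
  expect_error(classify_splice_structure(
    tm("q6", cbind(0, 100), strand = "-"), ann3), "strand")
})

test_that("classification is invariant to annotated isoform order", {
  ann <- list(tm("a1", cbind(c(0, 200, 400), c(100, 300, 500))),
              tm("a2", cbind(c(0, 400), c(100, 500))),
              tm("a3", cbind(c(0, 200), c(100, 300))))
  qs <- list(tm("q1", cbind(0, 500)),
             tm("q2", cbind(c(0, 210), c(100, 300))),
             tm("q3", cbind(c(200, 400), c(300, 500))))
  for (q in qs) {
    ref <- classify_splice_structure(q, ann)
    expect_equal(classify_splice_structure(q, rev(ann)), ref)
    expect_equal(classify_splice_structure(q, ann[c(2, 1, 3)]), ref)
  }
})

test_that("terminal-end changes alone never classify as novel", {
  # trim/extend first start and last end, internal boundaries intact
  variants <- list(tm("v1", cbind(c(10, 200, 400), c(100, 300, 490))),
                   tm("v2", cbind(c(0, 200, 400), c(100, 300, 550))),
                   tm("v3", cbind(c(50, 200, 400), c(100, 300, 500))))
  for (v in variants) {
    expect_equal(classify_splice_structure(v, ann3), "EXON_SKIPPING")
  }
})

test_that("decision tree matches the rule-by-rule oracle over all
           <= 3-exon chains on a toy locus", {
  annotated <- list(tm("a1", cbind(c(0, 20, 40), c(10, 30, 50))),
                    tm("a2", cbind(c(0, 40), c(10, 50))))
  chains <- enumerate_chains(seq(0, 60, by = 5), 3L)
  for (i in seq_along(chains)) {
    q <- tm(paste0("q", i), chains[[i]])
    expect_equal(classify_splice_structure(q, annotated),
                 splice_oracle(q, annotated),
                 info = paste("chain", exon_chain_key(q)))
  }
})

test_that("tallies count classes and report unannotated genes", {
  gb <- generate_gene_catalog(30, seed = 21)
  sv <- generate_splice_variants(gb$catalog, n_per_class = 3, seed = 22)
  tl <- tally_splice_classes(sv$transcripts, gb$catalog)
  expect_equal(unname(tl$counts[c("INTRON_RETENTION",
                                  "NOVEL_BOUNDARY_OR_EXON",
                                  "EXON_SKIPPING")]),
               c(3L, 3L, 3L))
  expect_equal(sum(tl$counts), nrow(sv$classes))
  # per-transcript agreement with the planted class
  expect_equal(tl$classes$class[match(sv$classes$transcript_id,
                                      tl$classes$transcript_id)],
               sv$classes$class)
  # unannotated gene excluded with a warning
  stray <- tm("stray", cbind(0, 400), gene = "NOPE")
  expect_warning(tl2 <- tally_splice_classes(c(sv$transcripts, list(stray)),
                                             gb$catalog),
                 "unannotated")
  expect_equal(tl2$excluded, "stray")
})
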