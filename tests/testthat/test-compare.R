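test_that("set_overlap partitions and reports sample-relative
           percentages", {
  ov <- set_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_setequal(ov$common, c("g2", "g3"))
  expect_setequal(ov$a_only, "g1")
  expect_equal(ov$pct_a_only, 33.33)
  # identical sets
  same <- set_overlap(letters[1:5], letters[1:5])
  expect_length(same$a_only, 0L)
  expect_equal(same$pct_a_only, 0)
  # disjoint sets
  dis <- set_overlap(letters[1:3], letters[4:6])
  expect_equal(dis$pct_a_only, 100)
  expect_length(dis$common, 0L)
})

test_that("overlap operations agree with the exhaustive pairwise oracle
           and are symmetric", {
  set.seed(7)
  for (rep in 1:10) {
    ka <- sample(paste0("k", 1:30), sample(5:20, 1))
    kb <- sample(paste0("k", 1:30), sample(5:20, 1))
    ov <- set_overlap(ka, kb)
    orc <- overlap_oracle(ka, kb)
    expect_length(ov$common, orc$common)
    expect_length(ov$a_only, orc$a_only)
    expect_length(ov$b_only, orc$b_only)
    # partition closure
    expect_equal(length(ov$common) + length(ov$a_only), ov$n_a)
    expect_equal(length(ov$common) + length(ov$b_only), ov$n_b)
    # symmetry
    sw <- set_overlap(kb, ka)
    expect_setequal(sw$common, ov$common)
    expect_setequal(sw$a_only, ov$b_only)
  }
})

test_that("isoform identity modes coincide when ids mirror structures", {
  txa <- list(tm("T1", cbind(0, 300), gene = "G1"),
              tm("T2", cbind(c(0, 400), c(300, 700)), gene = "G1"))
  txb <- list(tm("T1", cbind(0, 300), gene = "G1"),
              tm("T3", cbind(c(0, 500), c(300, 800)), gene = "G1"))
  a <- make_sample(txa, "A")
  b <- make_sample(txb, "B")
  by_chain <- compare_isoform_sets(a, b, "exon_chain")
  by_id <- compare_isoform_sets(a, b, "transcript_id")
  expect_length(by_chain$common, 1L)
  expect_length(by_id$common, 1L)
  expect_equal(lengths(by_chain[c("a_only", "b_only")]),
               lengths(by_id[c("a_only", "b_only")]))
})

test_that("identical-isoform-set genes require equal key sets", {
  txa <- list(tm("T1", cbind(0, 300), gene = "G1"),
              tm("T2", cbind(c(0, 400), c(300, 700)), gene = "G1"),
              tm("T3", cbind(0, 250), gene = "G2"))
  txb <- list(tm("T1", cbind(0, 300), gene = "G1"),
              tm("T2", cbind(c(0, 400), c(300, 700)), gene = "G1"),
              tm("T3", cbind(0, 250), gene = "G2"),
              tm("T4", cbind(c(0, 300), c(250, 400)), gene = "G2"))
  ident <- identical_isoform_set_genes(make_sample(txa), make_sample(txb))
  expect_setequal(ident, "G1")  # G2 has an extra isoform in B
})

test_that("category switches and bifunctional union behave on toy
           profiles", {
  txa <- list(tm("c1t", cbind(0, 300), gene = "G1"),
              tm("l1t", cbind(0, 250), gene = "G2"))
  txb <- list(tm("c1t", cbind(0, 300), gene = "G1"),
              tm("c2t", cbind(c(0, 400), c(300, 700)), gene = "G2"))
  lab_a <- data.frame(transcript_id = c("c1t", "l1t"),
                      gene_id = c("G1", "G2"), score = c(2, -2),
                      label = c("PROTEIN_CODING", "LONG_NCRNA"))
  lab_b <- data.frame(transcript_id = c("c1t", "c2t"),
                      gene_id = c("G1", "G2"), score = c(2, 3),
                      label = c("PROTEIN_CODING", "PROTEIN_CODING"))
  sw <- category_switch_genes(make_sample(txa), make_sample(txb),
                              lab_a, lab_b)
  expect_setequal(sw$lncrna_a_only, "G2")
  expect_setequal(sw$coding_b_only, "G2")
  expect_length(sw$lncrna_b_only, 0L)
  expect_length(sw$coding_a_only, 0L)

  expect_equal(bifunctional_union(c("a", "b"), c("c", "d", "e"))$n_union, 5L)
  expect_equal(bifunctional_union(c("a", "b"), c("a", "b", "c"))$n_union, 3L)
  expect_equal(bifunctional_union(c("a", "b"), c("a", "b", "c"))$n_common, 2L)
})

test_that("distribution tables bin counts with an open top bin", {
  txs <- c(lapply(1:3, function(i) tm(paste0("s", i), cbind(0, 300),
                                      gene = paste0("G", i))),
           list(tm("m1", cbind(c(0, 400, 800, 1200, 1600, 2000, 2400),
                               c(300, 700, 1100, 1500, 1900, 2300, 2700)),
                   gene = "G1")))
  tab <- distribution_tables(make_sample(txs))
  expect_equal(unname(tab$exon_counts), c(3L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(unname(tab$isoforms_per_gene), c(2L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(tab$pct_multi_exon, 25)
  expect_equal(tab$pct_single_isoform, round_half_up(200 / 3, 2))

  # all single-exon transcripts
  tab1 <- distribution_tables(make_sample(txs[1:3]))
  expect_equal(tab1$pct_multi_exon, 0)

  # every gene one isoform
  expect_equal(mean_isoforms_per_gene(make_sample(txs[1:3])), 1)
  expect_error(mean_isoforms_per_gene(5, 0), "expressed gene")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(30.705, 2), 30.71)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
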