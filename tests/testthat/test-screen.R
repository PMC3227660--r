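test_that("probe matching applies the exact-and-unique rule", {
  seqs <- c(T1 = "AAACCCGGGTTT", T2 = "CCCGGGTTTAAA", T3 = "TTTTTTTTTTTT")
  probes <- data.frame(
    probe_id = c("p_unique", "p_multi", "p_none", "p_self_multi"),
    sequence = c("AAACCC",        # only in T1
                 "CCCGGGTTT",     # in T1 and T2
                 "GGGCCC",        # nowhere
                 "TTTTTT"),       # multiple offsets within T3
    stringsAsFactors = FALSE)
  res <- match_probes(probes, seqs)
  expect_equal(res$matches$probe_id, "p_unique")
  expect_equal(res$matches$transcript_id, "T1")
  expect_equal(res$matches$offset, 0L)
  expect_true(all(res$matches$unique))
  expect_setequal(res$excluded$probe_id[res$excluded$reason == "multi_match"],
                  c("p_multi", "p_self_multi"))
  expect_equal(res$excluded$probe_id[res$excluded$reason == "no_match"],
               "p_none")
})

test_that("probe matching equals the naive offset scan on generated
           fixtures", {
  gb <- generate_gene_catalog(20, seed = 41)
  seqs <- extract_transcript_sequences(gb$genome,
                                       unname(gb$catalog$transcripts))
  pr <- generate_probes(seqs, n_unique = 8, n_multi = 3, n_nomatch = 3,
                        seed = 42)
  res <- match_probes(pr$probes, seqs)
  ref <- naive_probe_scan(pr$probes, seqs)
  expect_setequal(res$matches$probe_id, ref$probe_id)
  ord <- match(ref$probe_id, res$matches$probe_id)
  expect_equal(res$matches$transcript_id[ord], ref$transcript_id)
  expect_equal(res$matches$offset[ord], ref$offset)
  # generated categories behave as planted
  expect_setequal(res$matches$probe_id,
                  pr$truth$probe_id[pr$truth$category == "unique"])
})

test_that("gene-symbol pre-filter removes annotated probes before
           matching", {
  seqs <- c(T1 = "AAACCCGGGTTT")
  probes <- data.frame(probe_id = c("p1", "p2"),
                       sequence = c("AAACCC", "GGGTTT"),
                       gene_symbol = c(NA, "TP53"),
                       stringsAsFactors = FALSE)
  res <- match_probes(probes, seqs, require_no_symbol = TRUE)
  expect_equal(res$matches$probe_id, "p1")
  expect_equal(res$excluded$reason, "no_symbol_filter")
})

test_that("differential expression handles degenerate rows and group
           errors", {
  m <- rbind(flat = rep(3, 8),
             shift = c(rep(10, 4), rep(2, 4)),
             noise = c(2.1, 2.3, 1.9, 2.2, 2.0, 2.2, 1.8, 2.1))
  colnames(m) <- paste0("s", 1:8)
  res <- differential_expression(m, list(paste0("s", 1:4), paste0("s", 5:8)))
  expect_false(res$differential[res$probe_id == "flat"])
  expect_true(res$constant[res$probe_id == "flat"])
  expect_equal(res$p_value[res$probe_id == "flat"], 1)
  expect_true(res$differential[res$probe_id == "shift"])
  expect_error(differential_expression(m, list("s1", paste0("s", 5:8))),
               "at least 2")
  expect_error(differential_expression(m, list(paste0("s", 1:4),
                                               paste0("s", 4:8))),
               "overlap")
})

test_that("BH q-values are monotone in p-value rank", {
  set.seed(51)
  dm <- generate_disease_matrices(80, 6, 6, de_frac = 0.2, seed = 52)
  res <- differential_expression(dm$matrix, dm$groups)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("correlation screen thresholds inclusively on |r| and
           exclusively on p", {
  x <- matrix(1:10, nrow = 1, dimnames = list("nc1", NULL))
  y <- matrix(2 * (1:10) + 3, nrow = 1, dimnames = list("g1", NULL))
  res <- correlation_screen(x, y)
  expect_equal(nrow(res$hits), 1L)  # perfectly collinear pair
  expect_equal(res$hits$r, 1)

  # inclusive r threshold: set r_min to the exact observed r
  set.seed(61)
  a <- matrix(rnorm(30), nrow = 1, dimnames = list("nc1", NULL))
  b <- matrix(0.6 * a[1, ] + 0.5 * rnorm(30), nrow = 1,
              dimnames = list("g1", NULL))
  r_obs <- cor(a[1, ], b[1, ])
  res2 <- correlation_screen(a, b, r_min = abs(r_obs))
  expect_equal(nrow(res2$hits), 1L)
  expect_equal(res2$hits$r, r_obs)

  # zero-variance rows are skipped, not errored
  z <- matrix(rep(1, 30), nrow = 1, dimnames = list("flat", NULL))
  res3 <- correlation_screen(z, b)
  expect_equal(res3$skipped, "flat")
  expect_equal(nrow(res3$hits), 0L)
})

test_that("correlation screen is invariant under joint sample
           permutation", {
  set.seed(62)
  dm <- generate_disease_matrices(10, 8, 8, corr_pairs = 4, rho = 0.7,
                                  seed = 63)
  ref <- correlation_screen(dm$ncrna_mat, dm$gene_mat, dm$gene_symbols)
  perm <- sample(ncol(dm$ncrna_mat))
  res <- correlation_screen(dm$ncrna_mat[, perm], dm$gene_mat[, perm],
                            dm$gene_symbols)
  expect_equal(res$hits, ref$hits)
})
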