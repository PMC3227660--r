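test_that("compute_rpkm matches the closed form and rejects bad input", {
  expect_equal(compute_rpkm(0, 1e6, 500), 0)
  expect_equal(compute_rpkm(100, 1e6, 1000), 100)
  # frozen hand check: 1e9 * 5 / (5e7 * 2500)
  expect_equal(compute_rpkm(5, 5e7, 2500), 0.04)
  expect_error(compute_rpkm(1, 0, 100), "library_size")
  expect_error(compute_rpkm(1, 1e6, 0), "spliced_length")
  expect_error(compute_rpkm(-1, 1e6, 100), "read_count")
})

test_that("RPKM is invariant under duplicating the library", {
  set.seed(42)
  for (i in 1:20) {
    C <- sample(0:5000, 1)
    N <- round(runif(1, 1e5, 1e8))
    L <- sample(200:10000, 1)
    expect_equal(compute_rpkm(2 * C, 2 * N, L), compute_rpkm(C, N, L))
  }
})

test_that("expressed filter is inclusive at the threshold and idempotent", {
  txs <- lapply(1:4, function(i) tm(paste0("T", i), cbind(0, 300),
                                    gene = paste0("G", i)))
  expr <- data.frame(transcript_id = paste0("T", 1:4),
                     rpkm = c(0.1, 0.0999, 5, 0))
  s <- filter_expressed(txs, expr)
  expect_setequal(s$expression$transcript_id, c("T1", "T3"))  # 0.1 retained
  expect_equal(s$filter$retained, 2L)
  expect_equal(s$filter$dropped, 2L)

  # threshold 0 keeps everything
  s0 <- filter_expressed(txs, expr, threshold = 0)
  expect_equal(nrow(s0$expression), 4L)

  # idempotence: refiltering the retained records changes nothing
  s2 <- filter_expressed(s$transcripts, s$expression)
  expect_identical(s2$expression, s$expression)

  expect_error(filter_expressed(txs, rbind(expr, expr[1, ])), "duplicate")
})

test_that("expression reader derives RPKM from counts and flags
           inconsistent columns", {
  txs <- list(tm("T1", cbind(0, 1000)), tm("T2", cbind(0, 2500)))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tread_count", "T1\t100", "T2\t5"), f)
  df <- read_expression_tsv(f, txs, library_size = 1e6)
  expect_equal(df$rpkm, c(100, 2))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tread_count\trpkm", "T1\t100\t99.0"), f2)
  expect_error(read_expression_tsv(f2, txs, library_size = 1e6),
               "disagrees")
})
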