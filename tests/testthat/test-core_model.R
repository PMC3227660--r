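test_that("transcript_model enforces exon-chain invariants", {
  t1 <- tm("T1", cbind(c(200, 0), c(300, 100)))  # unsorted input
  expect_equal(t1$exons[, "start"], c(0, 200))
  expect_equal(spliced_length(t1), 200)
  expect_equal(introns(t1), cbind(start = 100, end = 200))
  expect_error(tm("T2", cbind(0, 0)), "start < end")
  expect_error(tm("T3", cbind(c(0, 100), c(100, 200))), "adjacent")
  expect_error(tm("T4", cbind(c(0, 50), c(100, 150))), "overlap")
  expect_error(transcript_model("T5", "G", "c1", ".", cbind(0, 10)),
               "unstranded")
})

test_that("GTF coordinates convert to 0-based half-open and group by gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "src", "exon", "101", "200", ".", "+", ".",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    paste("c1", "src", "exon", "301", "400", ".", "+", ".",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    paste("c1", "src", "exon", "101", "400", ".", "+", ".",
          'gene_id "G1"; transcript_id "T2";', sep = "\t")), gtf)
  cat <- read_annotation(gtf, "gtf")
  expect_length(cat$genes, 1L)
  expect_setequal(cat$genes$G1, c("T1", "T2"))
  expect_equal(cat$transcripts$T1$exons,
               cbind(start = c(100, 300), end = c(200, 400)))
  expect_equal(spliced_length(cat$transcripts$T1), 200)
})

test_that("malformed annotation lines fail with the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "src", "exon", "101", "200", ".", "+", ".",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    "c1\tbroken line"), gtf)
  expect_error(read_annotation(gtf, "gtf"), "line 2")
})

test_that("BED12 blocks expand to exons and round-trip bit-exactly", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste("c1", "0", "150", "G1|T1", "0", "+", "0", "0", "0,0,0",
                   "2", "50,50,", "0,100,", sep = "\t"), bed)
  cat <- read_annotation(bed, "bed12")
  expect_equal(cat$transcripts$T1$gene_id, "G1")
  expect_equal(cat$transcripts$T1$exons,
               cbind(start = c(0, 100), end = c(50, 150)))

  # write-back round trip over a random multi-exon catalog
  gb <- generate_gene_catalog(12, seed = 4)
  out <- tempfile(fileext = ".bed")
  write_bed12(gb$catalog, out)
  back <- read_annotation(out, "bed12")
  for (id in names(gb$catalog$transcripts)) {
    expect_identical(back$transcripts[[id]]$exons,
                     gb$catalog$transcripts[[id]]$exons)
    expect_identical(back$transcripts[[id]]$gene_id,
                     gb$catalog$transcripts[[id]]$gene_id)
  }
})

test_that("spliced sequence extraction splices, strands and bounds-checks", {
  g <- c(c1 = "AAACCCGGG")
  expect_equal(extract_transcript_sequence(g, tm("a", cbind(0, 3))), "AAA")
  expect_equal(
    extract_transcript_sequence(g, tm("b", cbind(0, 3), strand = "-")),
    "TTT")
  expect_equal(
    extract_transcript_sequence(g, tm("c", cbind(c(0, 6), c(3, 9)))),
    "AAAGGG")
  expect_error(extract_transcript_sequence(g, tm("d", cbind(0, 50))),
               "beyond")
  expect_error(
    extract_transcript_sequence(g, tm("e", cbind(0, 3), chrom = "c9")),
    "not found")

  # length identity on random synthetic transcripts
  gb <- generate_gene_catalog(15, seed = 11)
  seqs <- extract_transcript_sequences(gb$genome,
                                       unname(gb$catalog$transcripts))
  lens <- vapply(gb$catalog$transcripts, spliced_length, numeric(1L))
  expect_equal(unname(nchar(seqs)), unname(lens))
})

test_that("exon_chain_key is injective over distinct chains and
           strand/boundary sensitive", {
  a <- tm("A", cbind(0, 100))
  b <- tm("B", cbind(0, 100))
  expect_identical(exon_chain_key(a), exon_chain_key(b))
  expect_false(exon_chain_key(tm("c", cbind(c(0, 200), c(100, 300)))) ==
                 exon_chain_key(tm("d", cbind(c(0, 201), c(100, 300)))))
  expect_false(exon_chain_key(a) ==
                 exon_chain_key(tm("e", cbind(0, 100), strand = "-")))

  # brute-force injectivity: all chains with <= 3 exons on a 30-base locus
  chains <- enumerate_chains(seq(0, 30, by = 5), 3L)
  keys <- vapply(seq_along(chains), function(i) {
    exon_chain_key(tm(paste0("t", i), chains[[i]]))
  }, character(1L))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("gene_catalog rejects duplicate transcript ids", {
  expect_error(gene_catalog(list(tm("X", cbind(0, 10)),
                                 tm("X", cbind(0, 20)))),
               "duplicate")
})
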