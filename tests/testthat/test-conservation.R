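test_that("base-score fraction counts exonic bases at or above cutoff", {
  t1 <- tm("t1", cbind(0, 100))
  full <- conservation_track("v", data.frame(chrom = "c1", start = 0,
                                             end = 100, score = 1),
                             data.frame(chrom = character(),
                                        start = numeric(), end = numeric()))
  expect_equal(base_conserved_fraction(t1, full), 1)

  empty <- conservation_track("v",
                              data.frame(chrom = character(),
                                         start = numeric(), end = numeric(),
                                         score = numeric()),
                              data.frame(chrom = character(),
                                         start = numeric(), end = numeric()))
  expect_equal(base_conserved_fraction(t1, empty), 0)  # missing = 0

  half <- conservation_track("v",
                             data.frame(chrom = "c1", start = c(0, 50),
                                        end = c(50, 100),
                                        score = c(1, 0.5)),
                             data.frame(chrom = character(),
                                        start = numeric(), end = numeric()))
  expect_equal(base_conserved_fraction(t1, half), 0.5)
  expect_equal(base_conserved_fraction(t1, half, cutoff = 0.5), 1)
})

test_that("element ratio uses interval arithmetic over exonic bases
           only", {
  t1 <- tm("t1", cbind(0, 100))
  expect_equal(element_overlap_ratio(t1, data.frame(chrom = character(),
                                                    start = numeric(),
                                                    end = numeric())), 0)
  expect_equal(element_overlap_ratio(
    t1, data.frame(chrom = "c1", start = 0, end = 100)), 1)
  expect_equal(element_overlap_ratio(
    t1, data.frame(chrom = "c1", start = 40, end = 60)), 0.2)
  # element spanning the intron adds nothing intronic
  t2 <- tm("t2", cbind(c(0, 200), c(100, 300)))
  expect_equal(element_overlap_ratio(
    t2, data.frame(chrom = "c1", start = 50, end = 250)), 0.5)
})

test_that("ratios equal per-base brute force on random fixtures", {
  set.seed(31)
  for (rep in 1:8) {
    n_ex <- sample(1:3, 1)
    starts <- cumsum(sample(5:30, n_ex)) + (0:(n_ex - 1)) * 40
    ends <- starts + sample(10:40, n_ex)
    t1 <- tm("t", cbind(starts, ends))
    runs <- data.frame(chrom = "c1",
                       start = seq(0, 280, by = 20),
                       end = seq(0, 280, by = 20) + sample(5:20, 15,
                                                           replace = TRUE))
    runs$score <- round(runif(15), 2)
    track <- conservation_track("v", runs,
                                runs[runs$score >= 0.5, c("chrom", "start",
                                                          "end")])
    expect_equal(base_conserved_fraction(t1, track, 0.7),
                 brute_base_fraction(t1, runs, 0.7))
    expect_equal(element_overlap_ratio(t1, track),
                 brute_element_ratio(t1, track$elements))
  }
})

test_that("lowering the cutoff never decreases the conserved fraction", {
  set.seed(32)
  t1 <- tm("t", cbind(c(0, 100), c(60, 180)))
  runs <- data.frame(chrom = "c1", start = seq(0, 180, by = 10),
                     end = seq(0, 180, by = 10) + 8,
                     score = runif(19))
  track <- conservation_track("v", runs,
                              data.frame(chrom = character(),
                                         start = numeric(), end = numeric()))
  fr <- vapply(seq(1, 0, by = -0.1), function(cut) {
    base_conserved_fraction(t1, track, cut)
  }, numeric(1L))
  expect_true(all(diff(fr) >= 0))
})

test_that("clade summary flags untracked chromosomes and aggregates
           per clade", {
  t_in <- tm("in", cbind(0, 100))
  t_out <- tm("out", cbind(0, 100), chrom = "c9")
  track <- conservation_track("primates10",
                              data.frame(chrom = "c1", start = 0, end = 100,
                                         score = 0.95),
                              data.frame(chrom = "c1", start = 0, end = 50))
  cs <- clade_conservation_summary(list(t_in, t_out), list(track))
  expect_equal(cs$summary$contains_element, c(TRUE, FALSE))
  expect_equal(cs$summary$chrom_in_track, c(TRUE, FALSE))
  expect_equal(cs$summary$element_overlap_ratio[2], 0)
  expect_equal(cs$aggregate$fraction_with_element, 0.5)
  # contains_element consistency with the ratio
  expect_identical(cs$summary$contains_element,
                   cs$summary$element_overlap_ratio > 0)
})

test_that("planted element fraction reproduces the target ratio across
           exon boundaries", {
  t1 <- tm("t", cbind(c(0, 200, 400), c(100, 300, 500)))  # 300 nt spliced
  for (frac in c(0.2, 0.5, 0.9)) {
    el <- plant_element_fraction(t1, frac)
    expect_equal(element_overlap_ratio(t1, el), frac)
  }
})

test_that("track I/O round-trips scores and elements through
           bedGraph/BED", {
  sc <- data.frame(chrom = "c1", start = c(0, 50), end = c(50, 100),
                   score = c(0.95, 0.2))
  el <- data.frame(chrom = "c1", start = c(10, 70), end = c(20, 90))
  sp <- tempfile(fileext = ".bedGraph")
  ep <- tempfile(fileext = ".bed")
  write_score_track(sc, sp)
  write_elements_bed(el, ep)
  expect_equal(read_score_track(sp), sc)
  expect_equal(read_elements_bed(ep), el)
})
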