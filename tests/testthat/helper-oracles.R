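# Shorthand constructor for toy transcripts
tm <- function(id, exons, gene = "G", chrom = "c1", strand = "+") {
  transcript_model(id, gene, chrom, strand, exons)
}

# Exhaustive pairwise-overlap oracle: counts by scanning every (a, b) key
# pair, no set operations.
overlap_oracle <- function(keys_a, keys_b) {
  keys_a <- unique(keys_a); keys_b <- unique(keys_b)
  common <- 0L
  for (ka in keys_a) {
    hit <- FALSE
    for (kb in keys_b) if (identical(ka, kb)) hit <- TRUE
    if (hit) common <- common + 1L
  }
  list(common = common,
       a_only = length(keys_a) - common,
       b_only = length(keys_b) - common)
}

# Per-base brute force for the base-score conserved fraction: expands the
# score runs base by base.
brute_base_fraction <- function(t, scores, cutoff) {
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(t$exons))) {
    for (pos in seq(t$exons[i, 1L], t$exons[i, 2L] - 1L)) {
      total <- total + 1L
      sc <- 0
      rows <- scores[scores$chrom == t$chrom &
                       scores$start <= pos & scores$end > pos, , drop = FALSE]
      if (nrow(rows)) sc <- rows$score[1L]
      if (sc >= cutoff) hits <- hits + 1L
    }
  }
  hits / total
}

# Per-base brute force for element overlap.
brute_element_ratio <- function(t, elements) {
  covered <- 0L
  total <- 0L
  for (i in seq_len(nrow(t$exons))) {
    for (pos in seq(t$exons[i, 1L], t$exons[i, 2L] - 1L)) {
      total <- total + 1L
      inside <- any(elements$chrom == t$chrom &
                      elements$start <= pos & elements$end > pos)
      if (inside) covered <- covered + 1L
    }
  }
  covered / total
}

# Rule-by-rule splice-class oracle using per-base membership sets instead
# of interval arithmetic.
splice_oracle <- function(t, annotated) {
  exon_bases <- function(x) {
    unlist(lapply(seq_len(nrow(x$exons)), function(i) {
      seq(x$exons[i, 1L], x$exons[i, 2L] - 1L)
    }))
  }
  same_chain <- function(a, b) {
    nrow(a$exons) == nrow(b$exons) && all(a$exons == b$exons)
  }
  if (any(vapply(annotated, same_chain, logical(1L), b = t))) {
    return("IDENTICAL")
  }
  ann_introns <- list()
  for (a in annotated) {
    n <- nrow(a$exons)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        ann_introns[[length(ann_introns) + 1L]] <-
          c(a$exons[i, 2L], a$exons[i + 1L, 1L])
      }
    }
  }
  for (i in seq_len(nrow(t$exons))) {
    eb <- seq(t$exons[i, 1L], t$exons[i, 2L] - 1L)
    for (intr in ann_introns) {
      ib <- seq(intr[1L], intr[2L] - 1L)
      # both splice sites strictly inside: the bases flanking the intron
      # on each side belong to the same exon as every intron base
      if (all(ib %in% eb) && (intr[1L] - 1L) %in% eb && intr[2L] %in% eb) {
        return("INTRON_RETENTION")
      }
    }
  }
  ann_bounds <- unique(unlist(lapply(annotated, function(a) {
    c(a$exons[, 1L], a$exons[, 2L])
  })))
  n <- nrow(t$exons)
  internal <- c(t$exons[-1L, 1L], t$exons[-n, 2L])
  if (length(internal) && any(!internal %in% ann_bounds)) {
    return("NOVEL_BOUNDARY_OR_EXON")
  }
  all_ann_bases <- unique(unlist(lapply(annotated, exon_bases)))
  for (i in seq_len(n)) {
    eb <- seq(t$exons[i, 1L], t$exons[i, 2L] - 1L)
    if (!any(eb %in% all_ann_bases)) return("NOVEL_BOUNDARY_OR_EXON")
  }
  "EXON_SKIPPING"
}

# Every exon chain with up to max_exons exons whose boundaries sit on a
# position grid (used for enumeration-based equivalence checks).
enumerate_chains <- function(grid, max_exons) {
  chains <- list()
  for (k in seq_len(max_exons)) {
    combos <- utils::combn(grid, 2L * k)
    for (j in seq_len(ncol(combos))) {
      b <- combos[, j]
      chains[[length(chains) + 1L]] <-
        cbind(b[seq(1L, 2L * k, by = 2L)], b[seq(2L, 2L * k, by = 2L)])
    }
  }
  chains
}

# Naive probe scan: every (probe, transcript, offset) triple.
naive_probe_scan <- function(probes, seqs) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    pat <- toupper(probes$sequence[i])
    plen <- nchar(pat)
    hits <- list()
    for (tid in names(seqs)) {
      s <- seqs[[tid]]
      if (nchar(s) < plen) next
      for (off in 0:(nchar(s) - plen)) {
        if (substr(s, off + 1L, off + plen) == pat) {
          hits[[length(hits) + 1L]] <- list(tid = tid, off = off)
        }
      }
    }
    if (length(hits) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probes$probe_id[i], transcript_id = hits[[1L]]$tid,
        offset = hits[[1L]]$off, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), transcript_id = character(),
               offset = integer(), stringsAsFactors = FALSE)
}

# Tiny sample_transcriptome straight from transcript models, all expressed.
make_sample <- function(transcripts, name = "S", rpkm = NULL) {
  ids <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  if (is.null(rpkm)) rpkm <- rep(1, length(ids))
  filter_expressed(transcripts,
                   data.frame(transcript_id = ids, rpkm = rpkm,
                              stringsAsFactors = FALSE),
                   threshold = 0.1, sample_name = name)
}
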