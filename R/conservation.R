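#' Construct a per-clade conservation track
#'
#' Holds base-level conservation scores (bedGraph-style runs) and predicted
#' conserved elements for one clade. Elements are merged on construction;
#' overlapping score runs are rejected because a base cannot have two
#' scores.
#'
#' @param clade Clade label, e.g. `"vertebrates46"`, `"placental33"`,
#'   `"primates10"` (free-form).
#' @param scores Data frame `chrom`, `start`, `end`, `score` (0-based
#'   half-open runs, scores in \[0, 1\]); may have zero rows.
#' @param elements Data frame `chrom`, `start`, `end`; may have zero rows.
#' @return Object of class `conservation_track`.
#' @export
conservation_track <- function(clade, scores, elements) {
  stopifnot(is.character(clade), length(clade) == 1L)
  if (nrow(scores)) {
    stopifnot(all(c("chrom", "start", "end", "score") %in% names(scores)),
              all(scores$start < scores$end),
              all(scores$score >= 0 & scores$score <= 1))
    by_chrom <- split(scores, scores$chrom)
    for (d in by_chrom) {
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
        stop("overlapping score runs on ", d$chrom[1L], call. = FALSE)
      }
    }
  }
  if (nrow(elements)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(elements)),
              all(elements$start < elements$end))
    elements <- merge_intervals(elements)
  }
  structure(list(clade = clade, scores = scores, elements = elements),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("<conservation_track> %s: %d score run(s), %d element(s)\n",
              x$clade, nrow(x$scores), nrow(x$elements)))
  invisible(x)
}

#' Merge (normalize) a set of genomic intervals
#'
#' @param df Data frame `chrom`, `start`, `end` (0-based half-open).
#' @return Data frame of disjoint sorted intervals per chromosome.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Exonic bases of t covered by intervals (data frame chrom/start/end).
exonic_overlap_bases <- function(t, intervals) {
  iv <- intervals[intervals$chrom == t$chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  ex <- IRanges::IRanges(start = t$exons[, 1L] + 1, end = t$exons[, 2L])
  run <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1, end = iv$end))
  sum(IRanges::width(IRanges::intersect(ex, run)))
}

#' Fraction of exonic bases at or above a conservation score cutoff
#'
#' Counts exonic (spliced) bases whose base score meets the cutoff and
#' divides by spliced length. Bases absent from the score track count as
#' score 0 (phastCons dumps omit some bases); set `missing_as_na = TRUE`
#' to drop untracked bases from the denominator instead.
#'
#' @param t A [transcript_model()].
#' @param track A [conservation_track()].
#' @param cutoff Score cutoff in \[0, 1\], default 0.9.
#' @param missing_as_na Drop untracked bases from the denominator
#'   (returns `NA` when no exonic base is tracked).
#' @return Fraction in \[0, 1\].
#' @export
base_conserved_fraction <- function(t, track, cutoff = 0.9,
                                    missing_as_na = FALSE) {
  stopifnot(inherits(t, "transcript_model"),
            inherits(track, "conservation_track"),
            cutoff >= 0, cutoff <= 1)
  sc <- track$scores
  hi <- sc[sc$chrom == t$chrom & sc$score >= cutoff, , drop = FALSE]
  n_hi <- exonic_overlap_bases(t, hi)
  denom <- if (missing_as_na) {
    exonic_overlap_bases(t, sc[sc$chrom == t$chrom, , drop = FALSE])
  } else {
    spliced_length(t)
  }
  if (denom == 0) return(NA_real_)
  n_hi / denom
}

#' Fraction of exonic bases covered by conserved elements
#'
#' Interval arithmetic over the transcript's exons against a merged
#' element set; intronic bases never contribute.
#'
#' @param t A [transcript_model()].
#' @param elements Data frame `chrom`, `start`, `end`, or a
#'   [conservation_track()] (its elements are used).
#' @return Fraction in \[0, 1\].
#' @export
element_overlap_ratio <- function(t, elements) {
  stopifnot(inherits(t, "transcript_model"))
  if (inherits(elements, "conservation_track")) elements <- elements$elements
  if (nrow(elements) == 0L) return(0)
  exonic_overlap_bases(t, merge_intervals(elements)) / spliced_length(t)
}

#' Per-transcript conservation summary across clades
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param tracks List of [conservation_track()] objects (one per clade).
#' @param cutoff Base-score cutoff, default 0.9.
#' @return List with `summary` — data frame of one row per transcript and
#'   clade (`transcript_id`, `clade`, `base_conserved_fraction`,
#'   `element_overlap_ratio`, `contains_element`, `chrom_in_track`) — and
#'   `aggregate` — data frame per clade with the fraction of transcripts
#'   containing at least one conserved element.
#' @export
clade_conservation_summary <- function(transcripts, tracks, cutoff = 0.9) {
  stopifnot(length(tracks) >= 1L)
  rows <- list()
  for (tr in tracks) {
    stopifnot(inherits(tr, "conservation_track"))
    track_chroms <- union(unique(tr$scores$chrom), unique(tr$elements$chrom))
    for (t in transcripts) {
      ratio <- element_overlap_ratio(t, tr)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = t$transcript_id,
        clade = tr$clade,
        base_conserved_fraction = base_conserved_fraction(t, tr, cutoff),
        element_overlap_ratio = ratio,
        contains_element = ratio > 0,
        chrom_in_track = t$chrom %in% track_chroms,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  agg <- stats::aggregate(contains_element ~ clade, data = summary, FUN = mean)
  names(agg)[2L] <- "fraction_with_element"
  list(summary = summary, aggregate = agg)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph path (also accepts fixed/variable-step wiggle via
#'   rtracklayer's reader when `format = "wig"`).
#' @param format `"bedGraph"` or `"wig"`.
#' @return Data frame `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
read_score_track <- function(path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             score = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Read a BED file of conserved elements
#'
#' @param path BED path (first three columns used).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_elements_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a score data frame as bedGraph
#' @param scores Data frame `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(scores, path) {
  writeLines(paste(scores$chrom,
                   format(scores$start, scientific = FALSE, trim = TRUE),
                   format(scores$end, scientific = FALSE, trim = TRUE),
                   format(scores$score, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write elements as 3-column BED
#' @param elements Data frame `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  writeLines(paste(elements$chrom,
                   format(elements$start, scientific = FALSE, trim = TRUE),
                   format(elements$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
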