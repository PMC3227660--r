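#' Construct a transcript model
#'
#' A transcript (isoform) is an ordered chain of exons on one chromosome and
#' strand. All coordinates are 0-based half-open; conversion from 1-based
#' formats happens only at I/O boundaries (see [read_annotation()]).
#'
#' @param transcript_id Transcript identifier (unique within a catalog).
#' @param gene_id Identifier of the gene the isoform belongs to.
#' @param chrom Chromosome name. Kept verbatim; mixing "chr1"/"1" dialects
#'   across inputs is the caller's responsibility (see [normalize_chrom()]).
#' @param strand `"+"` or `"-"`. Unstranded (`"."`) records are rejected
#'   because splice-site semantics require strand.
#' @param exons Two-column numeric matrix (or data frame) of exon
#'   `start`/`end` pairs, 0-based half-open. Exons are sorted by start and
#'   must be pairwise non-overlapping with a gap of at least one base
#'   between consecutive exons.
#'
#' @return An object of class `transcript_model`.
#' @examples
#' t1 <- transcript_model("T1", "G1", "chr1", "+",
#'                        cbind(c(0, 200), c(100, 300)))
#' spliced_length(t1)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id),
            is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' (got '", strand,
         "'); unstranded transcripts are not supported", call. = FALSE)
  }
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L || !is.numeric(exons)) {
    stop("exons must be a non-empty two-column numeric matrix", call. = FALSE)
  }
  storage.mode(exons) <- "double"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (any(exons[, 1L] < 0)) {
    stop("exon starts must be >= 0 in transcript ", transcript_id,
         call. = FALSE)
  }
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("every exon must satisfy start < end in transcript ", transcript_id,
         call. = FALSE)
  }
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1)) {
      stop("exons overlap or are adjacent (intron length < 1) in transcript ",
           transcript_id, call. = FALSE)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s, %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), spliced_length(x)))
  invisible(x)
}

#' Spliced (exonic) length of a transcript
#'
#' @param t A [transcript_model()].
#' @return Total exon length in bases.
#' @export
spliced_length <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  sum(t$exons[, 2L] - t$exons[, 1L])
}

#' Number of exons of a transcript
#' @param t A [transcript_model()].
#' @return Integer exon count.
#' @export
exon_count <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  nrow(t$exons)
}

#' Introns of a transcript
#'
#' @param t A [transcript_model()].
#' @return Two-column matrix of intron `start`/`end` (0-based half-open);
#'   zero rows for single-exon transcripts.
#' @export
introns <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  matrix(c(t$exons[-n, 2L], t$exons[-1L, 1L]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' Canonical exon-chain key
#'
#' Deterministic string identity for an isoform structure: two transcripts
#' get equal keys if and only if they lie on the same chromosome and strand
#' with bit-identical ordered exon coordinates (terminal ends included).
#' This operationalizes "identical isoforms" for cross-sample comparison
#' independent of transcript IDs.
#'
#' @param t A [transcript_model()].
#' @return A single string.
#' @examples
#' a <- transcript_model("A", "G", "chr1", "+", cbind(0, 100))
#' b <- transcript_model("B", "G", "chr1", "+", cbind(0, 100))
#' identical(exon_chain_key(a), exon_chain_key(b))
#' @export
exon_chain_key <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  paste0(t$chrom, t$strand, "|",
         paste(format(t$exons[, 1L], scientific = FALSE, trim = TRUE),
               format(t$exons[, 2L], scientific = FALSE, trim = TRUE),
               sep = "-", collapse = ","))
}

#' Normalize a chromosome-name dialect
#'
#' Inputs mixing "chr1" and "1" styles can be harmonized before building a
#' catalog. The default keeps names as-is.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"as-is"` (default), `"ucsc"` (ensure `chr` prefix) or
#'   `"ensembl"` (strip a `chr` prefix).
#' @return Character vector of the same length.
#' @export
normalize_chrom <- function(chrom, style = c("as-is", "ucsc", "ensembl")) {
  style <- match.arg(style)
  switch(style,
         "as-is" = chrom,
         "ucsc" = ifelse(startsWith(chrom, "chr"), chrom,
                         paste0("chr", chrom)),
         "ensembl" = sub("^chr", "", chrom))
}
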