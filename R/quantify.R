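#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = 1e9 * C / (N * L) for C exonic reads, library size N mapped reads
#' and spliced length L bases. Monotone increasing in C, decreasing in N
#' and L; invariant under duplicating the library (C and N doubled).
#'
#' @param read_count Non-negative read count(s) C (vectorized).
#' @param library_size Total mapped reads N (positive scalar).
#' @param spliced_length Spliced transcript length(s) L in bases (positive).
#' @return Numeric RPKM value(s).
#' @examples
#' compute_rpkm(100, 1e6, 1000)   # 100
#' compute_rpkm(5, 5e7, 2500)     # 0.04
#' @export
compute_rpkm <- function(read_count, library_size, spliced_length) {
  if (length(library_size) != 1L || !is.finite(library_size) ||
      library_size < 1) {
    stop("library_size must be a single value >= 1", call. = FALSE)
  }
  if (any(!is.finite(spliced_length)) || any(spliced_length < 1)) {
    stop("spliced_length must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(read_count)) || any(read_count < 0)) {
    stop("read_count must be >= 0", call. = FALSE)
  }
  1e9 * as.numeric(read_count) /
    (as.numeric(library_size) * as.numeric(spliced_length))
}

#' Read a transcript expression table
#'
#' Expected TSV columns: `transcript_id`, then `read_count` and/or `rpkm`.
#' When only counts are given, RPKM is computed from `library_size` and the
#' spliced lengths in `transcripts`. When both are given, they must agree
#' within `1e-6` relative error (RPKMs usually come from an upstream
#' quantifier; silent disagreement would hide unit mistakes).
#'
#' @param path TSV path.
#' @param transcripts Optional list of [transcript_model()] (needed to
#'   derive RPKM from counts).
#' @param library_size Optional total mapped reads N.
#' @return Data frame with columns `transcript_id`, `read_count` (NA when
#'   absent) and `rpkm`.
#' @export
read_expression_tsv <- function(path, transcripts = NULL,
                                library_size = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(df)) {
    stop("expression table must have a transcript_id column", call. = FALSE)
  }
  has_count <- "read_count" %in% names(df)
  has_rpkm <- "rpkm" %in% names(df)
  if (!has_count && !has_rpkm) {
    stop("expression table needs a read_count or rpkm column", call. = FALSE)
  }
  if (has_count && !has_rpkm) {
    if (is.null(transcripts) || is.null(library_size)) {
      stop("deriving RPKM from counts needs transcripts and library_size",
           call. = FALSE)
    }
    lens <- vapply(transcripts, spliced_length, numeric(1L))
    names(lens) <- vapply(transcripts, `[[`, character(1L), "transcript_id")
    missing <- setdiff(df$transcript_id, names(lens))
    if (length(missing)) {
      stop("no transcript model for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df$rpkm <- compute_rpkm(df$read_count, library_size,
                            lens[df$transcript_id])
  }
  if (has_count && has_rpkm && !is.null(transcripts) &&
      !is.null(library_size)) {
    lens <- vapply(transcripts, spliced_length, numeric(1L))
    names(lens) <- vapply(transcripts, `[[`, character(1L), "transcript_id")
    expect <- compute_rpkm(df$read_count, library_size,
                           lens[df$transcript_id])
    rel <- abs(df$rpkm - expect) / pmax(expect, .Machine$double.eps)
    bad <- which(rel > 1e-6 & !(df$read_count == 0 & df$rpkm == 0))
    if (length(bad)) {
      stop("rpkm column disagrees with counts for ",
           paste(df$transcript_id[bad[seq_len(min(3, length(bad)))]],
                 collapse = ", "),
           " (relative error > 1e-6)", call. = FALSE)
    }
  }
  if (!has_count) df$read_count <- NA_real_
  df[, c("transcript_id", "read_count", "rpkm")]
}

#' Filter to the expressed transcript set
#'
#' Retains exactly the records with `rpkm >= threshold` (inclusive, so the
#' default keeps a transcript at exactly 0.1 RPKM) and packages them with
#' their models as a sample transcriptome. Isoforms below the threshold are
#' typically unreliable reconstructions, hence the filter.
#'
#' @param transcripts List of [transcript_model()] objects covering every
#'   transcript_id in `expression`.
#' @param expression Data frame with columns `transcript_id`, `rpkm` and
#'   optionally `read_count` (see [read_expression_tsv()]).
#' @param threshold Minimum RPKM, default `0.1`.
#' @param sample_name Label for the sample.
#' @return A `sample_transcriptome`: list with `sample_name`, `transcripts`
#'   (named list of models), `expression` (retained rows) and a `filter`
#'   element recording counts retained/dropped.
#' @export
filter_expressed <- function(transcripts, expression, threshold = 0.1,
                             sample_name = "sample") {
  stopifnot(threshold >= 0, is.data.frame(expression))
  if (anyDuplicated(expression$transcript_id)) {
    dup <- unique(expression$transcript_id[duplicated(expression$transcript_id)])
    stop("duplicate expression record(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tids <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  names(transcripts) <- tids
  missing <- setdiff(expression$transcript_id, tids)
  if (length(missing)) {
    stop("no transcript model for expression record(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- expression$rpkm >= threshold
  kept <- expression[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(
    list(sample_name = sample_name,
         transcripts = transcripts[kept$transcript_id],
         expression = kept,
         filter = list(threshold = threshold,
                       retained = sum(keep), dropped = sum(!keep))),
    class = "sample_transcriptome"
  )
}

#' @export
print.sample_transcriptome <- function(x, ...) {
  cat(sprintf(
    "<sample_transcriptome> '%s': %d transcript(s) from %d gene(s) at RPKM >= %s\n",
    x$sample_name, length(x$transcripts), length(expressed_genes(x)),
    format(x$filter$threshold)))
  invisible(x)
}

#' Expressed genes of a sample
#'
#' A gene counts as expressed when at least one of its isoforms passed the
#' expression threshold.
#'
#' @param sample A `sample_transcriptome` from [filter_expressed()].
#' @return Character vector of gene IDs.
#' @export
expressed_genes <- function(sample) {
  stopifnot(inherits(sample, "sample_transcriptome"))
  unique(vapply(sample$transcripts, `[[`, character(1L), "gene_id"))
}

#' Isoform identity keys of a sample
#'
#' @param sample A `sample_transcriptome`.
#' @param identity `"exon_chain"` (structure-based, default) or
#'   `"transcript_id"`.
#' @return Character vector of keys, named by transcript_id.
#' @export
isoform_keys <- function(sample, identity = c("exon_chain", "transcript_id")) {
  identity <- match.arg(identity)
  stopifnot(inherits(sample, "sample_transcriptome"))
  tids <- vapply(sample$transcripts, `[[`, character(1L), "transcript_id")
  keys <- if (identity == "exon_chain") {
    vapply(sample$transcripts, exon_chain_key, character(1L))
  } else tids
  names(keys) <- tids
  keys
}
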