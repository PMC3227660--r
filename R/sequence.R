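#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write chromosome sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract the spliced transcript sequence
#'
#' Exon substrings are concatenated in genomic order and the whole spliced
#' sequence is reverse-complemented for minus-strand transcripts, so the
#' result reads 5'->3' in transcript orientation.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [read_genome_fasta()]).
#' @param t A [transcript_model()].
#' @return Uppercase sequence string of length [spliced_length()].
#' @examples
#' g <- c(chr1 = "AAACCCGGG")
#' t <- transcript_model("T", "G", "chr1", "+", cbind(c(0, 6), c(3, 9)))
#' extract_transcript_sequence(g, t)  # "AAAGGG"
#' @export
extract_transcript_sequence <- function(genome, t) {
  stopifnot(inherits(t, "transcript_model"))
  if (!t$chrom %in% names(genome)) {
    stop("chromosome '", t$chrom, "' not found in genome", call. = FALSE)
  }
  chrom_seq <- genome[[t$chrom]]
  if (max(t$exons[, 2L]) > nchar(chrom_seq)) {
    stop("exon of transcript ", t$transcript_id, " extends beyond ",
         t$chrom, " (length ", nchar(chrom_seq), ")", call. = FALSE)
  }
  pieces <- substring(chrom_seq, t$exons[, 1L] + 1, t$exons[, 2L])
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  toupper(s)
}

#' Spliced sequences for a set of transcripts
#'
#' @param genome Named character vector of chromosome sequences.
#' @param transcripts List of [transcript_model()] objects.
#' @return Named character vector keyed by transcript_id.
#' @export
extract_transcript_sequences <- function(genome, transcripts) {
  out <- vapply(transcripts, function(t) extract_transcript_sequence(genome, t),
                character(1L))
  names(out) <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  out
}
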