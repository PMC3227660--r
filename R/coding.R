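#' Coding/noncoding call from a coding-potential score
#'
#' Follows the CPC sign convention: a positive score means the sequence
#' features support protein-coding capacity. Scores at exactly the cutoff
#' are called noncoding.
#'
#' @param score Finite numeric score(s).
#' @param cutoff Decision cutoff, default 0.
#' @return Character vector, `"coding"` or `"noncoding"`.
#' @export
label_coding <- function(score, cutoff = 0) {
  if (any(!is.finite(score))) {
    stop("coding scores must be finite", call. = FALSE)
  }
  ifelse(score > cutoff, "coding", "noncoding")
}

#' Three-way transcript class from score and length
#'
#' A transcript is `PROTEIN_CODING` when its score calls coding; otherwise
#' it is a long noncoding RNA when strictly longer than `long_min - 1`
#' bases (default: longer than 200 nt) and a short noncoding RNA when not.
#'
#' @param t A [transcript_model()].
#' @param score Finite coding-potential score.
#' @param cutoff Coding-score cutoff passed to [label_coding()].
#' @param long_min Minimum spliced length (nt) of a long ncRNA; the default
#'   201 encodes the strict "> 200 nt" rule, so a 200-nt noncoding
#'   transcript is `SHORT_NCRNA`.
#' @return One of `"PROTEIN_CODING"`, `"LONG_NCRNA"`, `"SHORT_NCRNA"`.
#' @export
classify_transcript <- function(t, score, cutoff = 0, long_min = 201) {
  stopifnot(inherits(t, "transcript_model"))
  if (label_coding(score, cutoff) == "coding") return("PROTEIN_CODING")
  if (spliced_length(t) >= long_min) "LONG_NCRNA" else "SHORT_NCRNA"
}

#' Classify every transcript of a sample
#'
#' @param sample A `sample_transcriptome` from [filter_expressed()].
#' @param scores Data frame with columns `transcript_id` and `cpc_score`
#'   (every expressed transcript must be scored).
#' @inheritParams classify_transcript
#' @return Data frame with columns `transcript_id`, `gene_id`, `score`,
#'   `label`.
#' @export
classify_sample <- function(sample, scores, cutoff = 0, long_min = 201) {
  stopifnot(inherits(sample, "sample_transcriptome"),
            is.data.frame(scores),
            all(c("transcript_id", "cpc_score") %in% names(scores)))
  tids <- names(sample$transcripts)
  sc <- scores$cpc_score[match(tids, scores$transcript_id)]
  if (anyNA(sc)) {
    stop("missing coding score for: ",
         paste(utils::head(tids[is.na(sc)], 3L), collapse = ", "),
         call. = FALSE)
  }
  label <- vapply(seq_along(tids), function(i) {
    classify_transcript(sample$transcripts[[i]], sc[i], cutoff, long_min)
  }, character(1L))
  data.frame(
    transcript_id = tids,
    gene_id = vapply(sample$transcripts, `[[`, character(1L), "gene_id"),
    score = sc, label = label,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Gene coding category from its expressed isoform labels
#'
#' A gene is `BIFUNCTIONAL` when its expressed isoforms include at least
#' one protein-coding transcript and at least one long ncRNA — short
#' noncoding isoforms do not confer bifunctionality, because the category
#' tracks genes producing both a protein product and a long regulatory
#' RNA. Genes with no protein-coding isoform are `NCRNA_ONLY`; the rest
#' are `CODING_ONLY`.
#'
#' @param labels Non-empty character vector of transcript labels for one
#'   gene (values from [classify_transcript()]).
#' @return One of `"CODING_ONLY"`, `"NCRNA_ONLY"`, `"BIFUNCTIONAL"`.
#' @export
classify_gene <- function(labels) {
  if (length(labels) == 0L) {
    stop("gene has no expressed isoform labels", call. = FALSE)
  }
  bad <- setdiff(labels, c("PROTEIN_CODING", "LONG_NCRNA", "SHORT_NCRNA"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  has_coding <- "PROTEIN_CODING" %in% labels
  has_lnc <- "LONG_NCRNA" %in% labels
  if (has_coding && has_lnc) return("BIFUNCTIONAL")
  if (!has_coding) return("NCRNA_ONLY")
  "CODING_ONLY"
}

#' Gene coding categories for a classified sample
#'
#' @param assessments Data frame from [classify_sample()].
#' @return Data frame with columns `gene_id`, `category`.
#' @export
classify_genes <- function(assessments) {
  stopifnot(all(c("gene_id", "label") %in% names(assessments)))
  per_gene <- split(assessments$label, assessments$gene_id)
  data.frame(
    gene_id = names(per_gene),
    category = vapply(per_gene, classify_gene, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
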