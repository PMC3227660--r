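#' Classify a transcript's exon structure against its gene's annotation
#'
#' Novel long ncRNAs arising from annotated genes are placed into one of
#' three alternative-splicing classes by a fixed-precedence decision tree
#' (each transcript gets exactly one class):
#'
#' 1. `IDENTICAL` — the exon chain equals some annotated isoform's chain
#'    (terminal ends included).
#' 2. `INTRON_RETENTION` — some exon of the query fully contains an
#'    annotated intron, both splice sites strictly inside the exon.
#' 3. `NOVEL_BOUNDARY_OR_EXON` — some internal splice boundary of the
#'    query matches no annotated exon boundary of the gene, or some query
#'    exon overlaps no annotated exon at all.
#' 4. `EXON_SKIPPING` — otherwise: every internal boundary is annotated
#'    yet the chain differs from every annotated isoform.
#'
#' Retention outranks novelty outranks skipping because an engulfed intron
#' is the most structurally specific signal. "Internal boundary" excludes
#' the transcript's first start and last end: sequencing-derived 5'/3'
#' termini are unreliable, so terminal-end changes alone never count as
#' novel (such transcripts fall through to `EXON_SKIPPING`). The annotated
#' boundary and intron sets are unions over all the gene's isoforms, so
#' the result does not depend on the order of `annotated`.
#'
#' @param t Query [transcript_model()].
#' @param annotated Non-empty list of annotated [transcript_model()]s of
#'   the same gene, chromosome and strand.
#' @param precedence Class order tried after `IDENTICAL`; reorder for
#'   sensitivity analysis.
#' @return One class string.
#' @examples
#' ann <- transcript_model("a1", "G", "chr1", "+",
#'                         cbind(c(0, 200, 400), c(100, 300, 500)))
#' skip <- transcript_model("q", "G", "chr1", "+",
#'                          cbind(c(0, 400), c(100, 500)))
#' classify_splice_structure(skip, list(ann))  # EXON_SKIPPING
#' @export
classify_splice_structure <- function(t, annotated,
                                      precedence = c("INTRON_RETENTION",
                                                     "NOVEL_BOUNDARY_OR_EXON",
                                                     "EXON_SKIPPING")) {
  stopifnot(inherits(t, "transcript_model"),
            is.list(annotated), length(annotated) > 0L)
  stopifnot(setequal(precedence, c("INTRON_RETENTION",
                                   "NOVEL_BOUNDARY_OR_EXON",
                                   "EXON_SKIPPING")))
  for (a in annotated) {
    stopifnot(inherits(a, "transcript_model"))
    if (a$gene_id != t$gene_id) {
      stop("annotated isoform ", a$transcript_id, " belongs to gene ",
           a$gene_id, ", not ", t$gene_id, call. = FALSE)
    }
    if (a$chrom != t$chrom || a$strand != t$strand) {
      stop("chromosome/strand mismatch between ", t$transcript_id,
           " and annotated isoform ", a$transcript_id, call. = FALSE)
    }
  }
  ann_keys <- vapply(annotated, exon_chain_key, character(1L))
  if (exon_chain_key(t) %in% ann_keys) return("IDENTICAL")

  ann_introns <- do.call(rbind, lapply(annotated, introns))
  ann_exons <- do.call(rbind, lapply(annotated, `[[`, "exons"))
  ann_bounds <- unique(c(ann_exons[, 1L], ann_exons[, 2L]))

  checks <- list(
    INTRON_RETENTION = function() {
      if (is.null(ann_introns) || nrow(ann_introns) == 0L) return(FALSE)
      for (i in seq_len(nrow(t$exons))) {
        es <- t$exons[i, 1L]; ee <- t$exons[i, 2L]
        if (any(ann_introns[, 1L] > es & ann_introns[, 2L] < ee)) {
          return(TRUE)
        }
      }
      FALSE
    },
    NOVEL_BOUNDARY_OR_EXON = function() {
      n <- nrow(t$exons)
      internal <- c(t$exons[-1L, 1L], t$exons[-n, 2L])
      if (length(internal) && !all(internal %in% ann_bounds)) return(TRUE)
      for (i in seq_len(n)) {
        es <- t$exons[i, 1L]; ee <- t$exons[i, 2L]
        if (!any(ann_exons[, 1L] < ee & ann_exons[, 2L] > es)) return(TRUE)
      }
      FALSE
    },
    EXON_SKIPPING = function() TRUE
  )
  for (cls in precedence) if (checks[[cls]]()) return(cls)
  "EXON_SKIPPING"
}

#' Tally splice classes over a transcript set
#'
#' @param transcripts List of query [transcript_model()] objects (e.g. the
#'   long ncRNAs of bifunctional genes).
#' @param catalog Annotation [gene_catalog()]. Queries whose gene is not in
#'   the catalog are excluded and reported.
#' @param ... Passed to [classify_splice_structure()].
#' @return List with `classes` (data frame transcript_id, gene_id, class),
#'   `counts` (named vector over the four classes), `excluded`
#'   (transcript IDs with unannotated genes).
#' @export
tally_splice_classes <- function(transcripts, catalog, ...) {
  stopifnot(inherits(catalog, "gene_catalog"))
  gid <- vapply(transcripts, `[[`, character(1L), "gene_id")
  known <- gid %in% names(catalog$genes)
  excluded <- vapply(transcripts[!known], `[[`, character(1L),
                     "transcript_id")
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " transcript(s) with unannotated genes", call. = FALSE)
  }
  kept <- transcripts[known]
  cls <- vapply(kept, function(t) {
    classify_splice_structure(t, gene_transcripts(catalog, t$gene_id), ...)
  }, character(1L))
  lv <- c("IDENTICAL", "INTRON_RETENTION", "NOVEL_BOUNDARY_OR_EXON",
          "EXON_SKIPPING")
  list(
    classes = data.frame(
      transcript_id = vapply(kept, `[[`, character(1L), "transcript_id"),
      gene_id = gid[known], class = cls,
      row.names = NULL, stringsAsFactors = FALSE),
    counts = stats::setNames(as.integer(table(factor(cls, levels = lv))), lv),
    excluded = unname(excluded)
  )
}
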