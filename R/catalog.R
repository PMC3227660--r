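#' Build a gene catalog from transcript models
#'
#' A gene catalog groups annotated isoforms by gene. Transcript IDs must be
#' unique across the catalog.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `gene_catalog` with elements `transcripts`
#'   (named list keyed by transcript_id) and `genes` (named list keyed by
#'   gene_id, each a character vector of transcript IDs).
#' @export
gene_catalog <- function(transcripts) {
  stopifnot(is.list(transcripts), length(transcripts) > 0L)
  ok <- vapply(transcripts, inherits, logical(1L), "transcript_model")
  if (!all(ok)) stop("all elements must be transcript_model objects",
                     call. = FALSE)
  tids <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  dup <- tids[duplicated(tids)]
  if (length(dup)) {
    stop("duplicate transcript_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(transcripts) <- tids
  gids <- vapply(transcripts, `[[`, character(1L), "gene_id")
  genes <- split(tids, gids)
  structure(list(transcripts = transcripts, genes = genes),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d gene(s), %d transcript(s)\n",
              length(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Transcripts annotated for one gene
#' @param catalog A [gene_catalog()].
#' @param gene_id Gene identifier.
#' @return List of [transcript_model()] objects.
#' @export
gene_transcripts <- function(catalog, gene_id) {
  stopifnot(inherits(catalog, "gene_catalog"))
  ids <- catalog$genes[[gene_id]]
  if (is.null(ids)) stop("gene '", gene_id, "' not in catalog", call. = FALSE)
  catalog$transcripts[ids]
}

# Light structural pre-scan so parse failures name the offending line,
# which rtracklayer's own errors do not.
check_column_counts <- function(path, n_fields, skip_prefix = "#") {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, skip_prefix) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf != n_fields]
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", basename(path), ": expected ",
         n_fields, " tab-separated fields", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read gene annotation into a catalog
#'
#' Supports GTF (1-based closed coordinates, attributes `gene_id` and
#' `transcript_id`) and BED12 (0-based half-open, block fields expanded to
#' exons). Coordinates are converted to the internal 0-based half-open
#' convention on read. BED12 carries no gene field, so gene identity is
#' taken from a `gene|transcript` name convention: the part before the
#' first `|` is the gene_id; names without `|` make each transcript its own
#' gene. [write_bed12()] emits that convention, so write/read round-trips.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return A [gene_catalog()].
#' @export
read_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "gtf") {
    check_column_counts(path, 9L)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path, call. = FALSE)
    md <- S4Vectors::mcols(gr)
    if (is.null(md$transcript_id) || is.null(md$gene_id)) {
      stop("GTF exon lines must carry gene_id and transcript_id attributes",
           call. = FALSE)
    }
    df <- data.frame(
      transcript_id = as.character(md$transcript_id),
      gene_id = as.character(md$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    tx <- lapply(split(df, df$transcript_id), function(d) {
      if (length(unique(d$gene_id)) != 1L || length(unique(d$chrom)) != 1L ||
          length(unique(d$strand)) != 1L) {
        stop("inconsistent gene/chrom/strand for transcript ",
             d$transcript_id[1L], call. = FALSE)
      }
      transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                       d$strand[1L], cbind(d$start, d$end))
    })
    return(gene_catalog(unname(tx)))
  }
  # BED12
  check_column_counts(path, 12L)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("no records in ", path, call. = FALSE)
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("BED input lacks block (BED12) fields",
                            call. = FALSE)
  nm <- as.character(S4Vectors::mcols(gr)$name)
  tx <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    bl <- blocks[[i]]
    if (length(bl) == 0L) {
      stop("record '", nm[i], "' has zero exon blocks", call. = FALSE)
    }
    chrom_start <- GenomicRanges::start(gr)[i] - 1  # back to 0-based
    starts <- chrom_start + (IRanges::start(bl) - 1)
    ends <- chrom_start + IRanges::end(bl)
    gid <- if (grepl("|", nm[i], fixed = TRUE)) {
      sub("\\|.*$", "", nm[i])
    } else nm[i]
    tid <- if (grepl("|", nm[i], fixed = TRUE)) {
      sub("^[^|]*\\|", "", nm[i])
    } else nm[i]
    tx[[i]] <- transcript_model(
      tid, gid, as.character(GenomicRanges::seqnames(gr))[i],
      as.character(GenomicRanges::strand(gr))[i], cbind(starts, ends))
  }
  gene_catalog(tx)
}

#' Write transcripts as BED12
#'
#' Names are emitted as `gene_id|transcript_id` so [read_annotation()] can
#' recover gene grouping. Exon coordinates round-trip bit-exactly.
#'
#' @param x A [gene_catalog()] or list of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(x, path) {
  tx <- if (inherits(x, "gene_catalog")) x$transcripts else x
  lines <- vapply(tx, function(t) {
    s <- t$exons[, 1L]; e <- t$exons[, 2L]
    paste(t$chrom,
          format(s[1L], scientific = FALSE, trim = TRUE),
          format(e[length(e)], scientific = FALSE, trim = TRUE),
          paste0(t$gene_id, "|", t$transcript_id),
          0, t$strand,
          format(s[1L], scientific = FALSE, trim = TRUE),
          format(s[1L], scientific = FALSE, trim = TRUE),
          "0,0,0",
          length(s),
          paste0(paste(format(e - s, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(s - s[1L], scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write transcripts as GTF exon lines
#'
#' Minimal deterministic GTF writer (exon features only, 1-based closed
#' coordinates, `gene_id`/`transcript_id` attributes). Output is byte-stable
#' for a given input, which the synthetic generators rely on.
#'
#' @inheritParams write_bed12
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  tx <- if (inherits(x, "gene_catalog")) x$transcripts else x
  con <- file(path, "w")
  on.exit(close(con))
  for (t in tx) {
    for (i in seq_len(nrow(t$exons))) {
      writeLines(paste(
        t$chrom, "isocompare", "exon",
        format(t$exons[i, 1L] + 1, scientific = FALSE, trim = TRUE),
        format(t$exons[i, 2L], scientific = FALSE, trim = TRUE),
        ".", t$strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";',
                t$gene_id, t$transcript_id),
        sep = "\t"), con)
    }
  }
  invisible(path)
}
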