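#' Round half away from zero
#'
#' Report percentages the way printed tables round them (0.705 -> 0.71),
#' rather than banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

overlap_partition <- function(a, b) {
  a <- unique(a); b <- unique(b)
  common <- intersect(a, b)
  list(common = common,
       a_only = setdiff(a, b),
       b_only = setdiff(b, a),
       n_a = length(a), n_b = length(b))
}

#' Two-set overlap with sample-specific percentages
#'
#' Core of the gene- and isoform-level comparisons: partitions the union of
#' two key sets into common / A-only / B-only, and reports each exclusive
#' part as a percentage of its own sample's total, rounded half-up to two
#' decimals.
#'
#' @param a,b Character vectors of keys (gene IDs or isoform keys);
#'   duplicates are ignored.
#' @return List with `common`, `a_only`, `b_only` (character vectors),
#'   `n_a`, `n_b`, `pct_a_only`, `pct_b_only`.
#' @examples
#' ov <- set_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
#' ov$pct_a_only  # 33.33
#' @export
set_overlap <- function(a, b) {
  p <- overlap_partition(a, b)
  p$pct_a_only <- round_half_up(100 * length(p$a_only) / p$n_a, 2)
  p$pct_b_only <- round_half_up(100 * length(p$b_only) / p$n_b, 2)
  p
}

#' Gene-level overlap of two samples
#'
#' Genes are matched by gene_id alone: a gene expressed in both samples is
#' "common" even when the two samples express disjoint isoform sets of it
#' (that discrepancy is exactly what the isoform-level comparison exposes).
#'
#' @param a,b `sample_transcriptome` objects from [filter_expressed()].
#' @return As [set_overlap()].
#' @export
compare_gene_sets <- function(a, b) {
  stopifnot(inherits(a, "sample_transcriptome"),
            inherits(b, "sample_transcriptome"))
  set_overlap(expressed_genes(a), expressed_genes(b))
}

#' Isoform-level overlap of two samples
#'
#' Isoform identity is by full exon-chain equality by default (robust to
#' transcript-ID drift between runs) or by shared transcript_id. When
#' per-transcript labels are supplied, coding/noncoding sub-counts are
#' attached for each partition. An exon-chain key claimed by two different
#' genes within one sample is ambiguous; such keys are excluded and
#' reported.
#'
#' @param a,b `sample_transcriptome` objects.
#' @param identity `"exon_chain"` or `"transcript_id"`.
#' @param labels_a,labels_b Optional data frames from [classify_sample()].
#' @return As [set_overlap()], plus `subcounts` (when labels are given) and
#'   `ambiguous` (excluded keys).
#' @export
compare_isoform_sets <- function(a, b,
                                 identity = c("exon_chain", "transcript_id"),
                                 labels_a = NULL, labels_b = NULL) {
  identity <- match.arg(identity)
  ka <- isoform_keys(a, identity)
  kb <- isoform_keys(b, identity)
  drop_ambiguous <- function(keys, sample) {
    gid <- vapply(sample$transcripts[names(keys)], `[[`, character(1L),
                  "gene_id")
    genes_per_key <- tapply(gid, keys, function(g) length(unique(g)))
    amb <- names(genes_per_key)[genes_per_key > 1L]
    list(keys = keys[!keys %in% amb], ambiguous = amb)
  }
  da <- drop_ambiguous(ka, a)
  db <- drop_ambiguous(kb, b)
  ov <- set_overlap(da$keys, db$keys)
  ov$ambiguous <- union(da$ambiguous, db$ambiguous)
  if (!is.null(labels_a) && !is.null(labels_b)) {
    coding_keys <- function(keys, labels) {
      lab <- labels$label[match(names(keys), labels$transcript_id)]
      unique(keys[lab == "PROTEIN_CODING"])
    }
    ca <- coding_keys(da$keys, labels_a)
    cb <- coding_keys(db$keys, labels_b)
    nc_count <- function(part, coding) {
      c(coding = sum(part %in% coding), noncoding = sum(!part %in% coding))
    }
    ov$subcounts <- list(
      common = nc_count(ov$common, union(ca, cb)),
      a_only = nc_count(ov$a_only, ca),
      b_only = nc_count(ov$b_only, cb))
  }
  ov
}

#' Common genes with identical expressed isoform sets
#'
#' Among genes expressed in both samples, returns those whose expressed
#' isoform key-sets are exactly equal (same number, same structures) in A
#' and B. Their complement within the common genes is the
#' "generated different isoforms" set.
#'
#' @inheritParams compare_isoform_sets
#' @return Character vector of gene IDs.
#' @export
identical_isoform_set_genes <- function(a, b,
                                        identity = c("exon_chain",
                                                     "transcript_id")) {
  identity <- match.arg(identity)
  keys_by_gene <- function(s) {
    k <- isoform_keys(s, identity)
    g <- vapply(s$transcripts[names(k)], `[[`, character(1L), "gene_id")
    lapply(split(unname(k), g), function(x) sort(unique(x)))
  }
  ga <- keys_by_gene(a)
  gb <- keys_by_gene(b)
  common <- intersect(names(ga), names(gb))
  common[vapply(common, function(g) identical(ga[[g]], gb[[g]]), logical(1L))]
}

#' Genes switching coding category between samples
#'
#' Among genes expressed in both samples, finds (i) genes producing a long
#' ncRNA in A but none in B, (ii) the reverse, (iii) genes producing a
#' protein-coding isoform in A but none in B, and (iv) the reverse. A gene
#' can belong to one lncRNA set and one coding set at the same time (e.g.
#' noncoding-only in A, coding-only in B).
#'
#' @param a,b `sample_transcriptome` objects.
#' @param labels_a,labels_b Data frames from [classify_sample()].
#' @return List of character vectors `lncrna_a_only`, `lncrna_b_only`,
#'   `coding_a_only`, `coding_b_only`.
#' @export
category_switch_genes <- function(a, b, labels_a, labels_b) {
  common <- intersect(expressed_genes(a), expressed_genes(b))
  has_label <- function(labels, what) {
    unique(labels$gene_id[labels$label == what])
  }
  lnc_a <- has_label(labels_a, "LONG_NCRNA")
  lnc_b <- has_label(labels_b, "LONG_NCRNA")
  cod_a <- has_label(labels_a, "PROTEIN_CODING")
  cod_b <- has_label(labels_b, "PROTEIN_CODING")
  list(
    lncrna_a_only = intersect(common, setdiff(lnc_a, lnc_b)),
    lncrna_b_only = intersect(common, setdiff(lnc_b, lnc_a)),
    coding_a_only = intersect(common, setdiff(cod_a, cod_b)),
    coding_b_only = intersect(common, setdiff(cod_b, cod_a))
  )
}

#' Union of bifunctional genes across two samples
#'
#' @param bif_a,bif_b Character vectors of bifunctional gene IDs per sample
#'   (e.g. from [classify_genes()] rows with category `"BIFUNCTIONAL"`).
#' @return List with `genes` (the union), `n_union`, `n_common`.
#' @examples
#' bifunctional_union(paste0("g", 1:146), paste0("g", 98:282))
#' @export
bifunctional_union <- function(bif_a, bif_b) {
  bif_a <- unique(bif_a); bif_b <- unique(bif_b)
  u <- union(bif_a, bif_b)
  list(genes = u, n_union = length(u),
       n_common = length(intersect(bif_a, bif_b)))
}

#' Exon-count and isoforms-per-gene distributions of a sample
#'
#' @param sample A `sample_transcriptome`.
#' @param max_bin Last closed bin; counts at or above `max_bin + 1` fall in
#'   the open top bin. Default 5, giving bins 1..5 and "6+".
#' @return List with named integer vectors `exon_counts` and
#'   `isoforms_per_gene` (names `"1"`..`"5"`, `"6+"`), plus
#'   `pct_multi_exon` (share of transcripts with >= 2 exons) and
#'   `pct_single_isoform` (share of genes with exactly one isoform), both
#'   rounded half-up to 2 decimals.
#' @export
distribution_tables <- function(sample, max_bin = 5L) {
  stopifnot(inherits(sample, "sample_transcriptome"))
  ex <- vapply(sample$transcripts, exon_count, numeric(1L))
  gid <- vapply(sample$transcripts, `[[`, character(1L), "gene_id")
  iso <- as.numeric(table(gid))
  list(exon_counts = bin_counts(ex, max_bin),
       isoforms_per_gene = bin_counts(iso, max_bin),
       pct_multi_exon = pct_multi_exon(bin_counts(ex, max_bin)),
       pct_single_isoform = pct_single_isoform(bin_counts(iso, max_bin)))
}

#' Bin positive counts into 1..max_bin and an open top bin
#'
#' @param x Positive integer counts.
#' @param max_bin Last closed bin (default 5).
#' @return Named integer vector over bins `"1"`..`"max_bin"`, `"max_bin+1+"`.
#' @export
bin_counts <- function(x, max_bin = 5L) {
  stopifnot(all(x >= 1))
  bins <- c(as.character(seq_len(max_bin)), paste0(max_bin + 1L, "+"))
  out <- stats::setNames(integer(max_bin + 1L), bins)
  capped <- pmin(x, max_bin + 1L)
  tab <- table(factor(capped, levels = seq_len(max_bin + 1L)))
  out[] <- as.integer(tab)
  out
}

#' Share of multi-exon transcripts from a binned exon-count table
#'
#' @param exon_bins Named counts as produced by [bin_counts()], first bin =
#'   single-exon transcripts.
#' @return Percentage of transcripts with two or more exons, rounded
#'   half-up to 2 decimals.
#' @export
pct_multi_exon <- function(exon_bins) {
  total <- sum(exon_bins)
  round_half_up(100 * (total - exon_bins[[1L]]) / total, 2)
}

#' Share of single-isoform genes from a binned isoform-count table
#'
#' @param iso_bins Named counts as produced by [bin_counts()], first bin =
#'   genes with exactly one expressed isoform.
#' @return Percentage, rounded half-up to 2 decimals.
#' @export
pct_single_isoform <- function(iso_bins) {
  round_half_up(100 * iso_bins[[1L]] / sum(iso_bins), 2)
}

#' Mean expressed isoforms per expressed gene
#'
#' @param sample A `sample_transcriptome`, or the total isoform count when
#'   `n_genes` is given.
#' @param n_genes Optional total expressed-gene count (counts interface).
#' @return Mean isoforms/gene, rounded half-up to 2 decimals.
#' @examples
#' mean_isoforms_per_gene(32714, 18431)  # 1.77
#' @export
mean_isoforms_per_gene <- function(sample, n_genes = NULL) {
  if (inherits(sample, "sample_transcriptome")) {
    n_iso <- length(sample$transcripts)
    n_genes <- length(expressed_genes(sample))
  } else {
    n_iso <- sample
  }
  if (is.null(n_genes) || n_genes < 1) {
    stop("need at least one expressed gene", call. = FALSE)
  }
  round_half_up(n_iso / n_genes, 2)
}

#' Full two-sample comparison summary
#'
#' Convenience wrapper running the gene- and isoform-level comparisons,
#' the distribution tables, category-switch detection and the bifunctional
#' union in one call.
#'
#' @param a,b `sample_transcriptome` objects.
#' @param labels_a,labels_b Data frames from [classify_sample()].
#' @param identity Isoform identity mode, see [compare_isoform_sets()].
#' @return List with elements `genes`, `isoforms`, `identical_set_genes`,
#'   `switches`, `bifunctional`, `tables_a`, `tables_b`,
#'   `mean_isoforms_per_gene` (length-2 vector).
#' @export
comparison_summary <- function(a, b, labels_a, labels_b,
                               identity = c("exon_chain", "transcript_id")) {
  identity <- match.arg(identity)
  cats_a <- classify_genes(labels_a)
  cats_b <- classify_genes(labels_b)
  list(
    genes = compare_gene_sets(a, b),
    isoforms = compare_isoform_sets(a, b, identity, labels_a, labels_b),
    identical_set_genes = identical_isoform_set_genes(a, b, identity),
    switches = category_switch_genes(a, b, labels_a, labels_b),
    bifunctional = bifunctional_union(
      cats_a$gene_id[cats_a$category == "BIFUNCTIONAL"],
      cats_b$gene_id[cats_b$category == "BIFUNCTIONAL"]),
    tables_a = distribution_tables(a),
    tables_b = distribution_tables(b),
    mean_isoforms_per_gene = c(a = mean_isoforms_per_gene(a),
                               b = mean_isoforms_per_gene(b))
  )
}
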