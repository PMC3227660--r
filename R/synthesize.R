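#' @title Synthetic inputs with recorded ground truth
#' @description Generators for every input the pipeline consumes: a
#'   multi-isoform gene catalog with a toy genome, paired two-sample
#'   transcriptomes with controlled gene/isoform overlap and planted
#'   coding labels, conservation tracks with planted conserved elements,
#'   and case/control expression matrices with planted differential
#'   expression and correlated probe pairs. Every generator is
#'   deterministic under its seed and returns the ground truth needed to
#'   verify the corresponding pipeline stage.
#' @name synthetic-data
NULL

draw_counts <- function(spec, n) {
  if (is.function(spec)) return(as.integer(spec(n)))
  if (length(spec) == 1L && is.null(names(spec))) {
    return(rep(as.integer(spec), n))
  }
  vals <- as.integer(names(spec))
  if (anyNA(vals)) stop("distribution spec needs integer names", call. = FALSE)
  sample(vals, n, replace = TRUE, prob = as.numeric(spec))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a multi-isoform gene catalog and toy genome
#'
#' Genes are packed left to right on synthetic chromosomes with
#' non-overlapping loci. Each gene gets a master exon chain; its first
#' isoform is the full chain and further isoforms are distinct exon
#' subsets, so isoforms of one gene share exon sequence (which real
#' catalogs do, and which the probe and splice generators rely on).
#'
#' @param n_genes Number of genes (> 0).
#' @param isoforms_per_gene Distribution of isoform counts: a single
#'   integer, a named probability vector (names = counts), or
#'   `function(n)`.
#' @param exons_per_isoform Distribution of exon counts, same forms.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @param exon_len_range,intron_len_range Integer ranges to draw exon and
#'   intron lengths from (introns >= 1 base by construction).
#' @param short_isoform_genes Number of genes additionally given a short
#'   (<= 200 nt) single-exon isoform, needed for planting genes whose
#'   noncoding product is short in one sample.
#' @param genes_per_chrom Genes laid per synthetic chromosome.
#' @param max_chrom_len Sizing guard: packing a chromosome beyond this
#'   length is an error.
#' @return List with `catalog` (a [gene_catalog()]) and `genome` (named
#'   character vector of chromosome sequences).
#' @export
generate_gene_catalog <- function(n_genes,
                                  isoforms_per_gene = c("1" = 0.66,
                                                        "2" = 0.18,
                                                        "3" = 0.08,
                                                        "4" = 0.05,
                                                        "5" = 0.03),
                                  exons_per_isoform = NULL,
                                  seed = 1L,
                                  exon_len_range = c(80L, 300L),
                                  intron_len_range = c(60L, 400L),
                                  short_isoform_genes = 0L,
                                  genes_per_chrom = 50L,
                                  max_chrom_len = 5e7) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  if (is.null(exons_per_isoform)) {
    exons_per_isoform <- stats::setNames(c(0.06, 0.08, 0.10, 0.11, 0.10, 0.55),
                                         as.character(1:6))
  }
  n_iso <- pmax(draw_counts(isoforms_per_gene, n_genes), 1L)
  transcripts <- list()
  chrom_ends <- numeric(0)
  short_genes <- sort(sample.int(n_genes, min(short_isoform_genes, n_genes)))
  for (g in seq_len(n_genes)) {
    chrom_i <- ((g - 1L) %/% genes_per_chrom) + 1L
    chrom <- paste0("chrS", chrom_i)
    pos <- if (chrom %in% names(chrom_ends)) chrom_ends[[chrom]] + 500 else 200
    k <- n_iso[g]
    e_counts <- pmax(draw_counts(exons_per_isoform, k), 1L)
    # a multi-isoform gene needs a master chain with room for distinct
    # proper subsets; same for genes carrying a nested short isoform
    e_master <- max(e_counts, if (g %in% short_genes || k > 1L) 2L else 1L)
    exon_lens <- sample(exon_len_range[1L]:exon_len_range[2L], e_master,
                        replace = TRUE)
    intron_lens <- if (e_master > 1L) {
      sample(intron_len_range[1L]:intron_len_range[2L], e_master - 1L,
             replace = TRUE)
    } else integer(0)
    starts <- pos + cumsum(c(0, exon_lens[-e_master] + intron_lens))
    ends <- starts + exon_lens
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%04d", g)
    subsets_seen <- character(0)
    for (i in seq_len(k)) {
      if (i == 1L) {
        idx <- seq_len(e_master)
      } else {
        e_i <- min(e_counts[i], e_master - 1L)  # proper subset of the master
        idx <- NULL
        for (try in seq_len(50L)) {
          cand <- sort(sample.int(e_master, e_i))
          key <- paste(cand, collapse = ",")
          if (!key %in% subsets_seen &&
              !(i > 1L && identical(cand, seq_len(e_master)))) {
            idx <- cand; break
          }
        }
        if (is.null(idx)) next  # gene saturated; emit fewer isoforms
      }
      subsets_seen <- c(subsets_seen, paste(idx, collapse = ","))
      transcripts[[length(transcripts) + 1L]] <- transcript_model(
        sprintf("%s.T%d", gid, i), gid, chrom, strand,
        cbind(starts[idx], ends[idx]))
    }
    if (g %in% short_genes) {
      # short single-exon isoform strictly nested in the first master exon,
      # so its chain can never collide with an annotated subset chain
      sl <- min(sample(120:180, 1L), exon_lens[1L] - 2L)
      s0 <- starts[1L] + 1L
      transcripts[[length(transcripts) + 1L]] <- transcript_model(
        sprintf("%s.Tshort", gid), gid, chrom, strand,
        cbind(s0, s0 + sl))
    }
    chrom_ends[[chrom]] <- ends[e_master]
    if (chrom_ends[[chrom]] > max_chrom_len) {
      stop("chromosome packing exceeds max_chrom_len; reduce n_genes or ",
           "sizes", call. = FALSE)
    }
  }
  genome <- vapply(names(chrom_ends), function(ch) {
    random_dna(chrom_ends[[ch]] + 200)
  }, character(1L))
  list(catalog = gene_catalog(transcripts), genome = genome)
}

#' Generate paired sample transcriptomes with planted ground truth
#'
#' Builds two expressed transcriptomes over a catalog with controlled
#' gene- and isoform-level overlap, planted coding labels, and optional
#' planted feature classes: identical-isoform-set genes, bifunctional
#' genes, category-switch genes and novel spliced long ncRNAs. Because a
#' gene's derived categories are coupled (a common gene with a coding and
#' a long noncoding isoform in A only is simultaneously bifunctional-in-A
#' and lncRNA-in-A-only), planting uses disjoint gene groups with fully
#' determined label profiles and the returned `truth` records the exact
#' realized expectation for every downstream set; plant one feature class
#' at a time when you need planted counts to equal realized counts.
#'
#' Expression tables carry RPKM only (as produced by an upstream
#' quantifier); expressed records draw from a log-normal clamped at the
#' threshold, a few records sit exactly at the threshold to exercise the
#' inclusive filter, and decoy records for unexpressed isoforms sit just
#' below it.
#'
#' @param catalog_bundle Result of [generate_gene_catalog()] (list with
#'   `catalog` and `genome`), or a bare [gene_catalog()].
#' @param shared_gene_frac Fraction of catalog genes expressed in both
#'   samples; the remainder splits evenly into A-only and B-only.
#' @param shared_isoform_frac Probability an isoform of an unplanted
#'   common gene is expressed in both samples.
#' @param coding_frac Probability an unplanted transcript is
#'   protein-coding.
#' @param long_min Minimum long-ncRNA spliced length (strict > 200 nt
#'   rule as 201).
#' @param threshold Expression threshold the samples are filtered at.
#' @param identical_set_frac If non-NULL, exact fraction of common genes
#'   whose expressed isoform sets are identical in A and B (requires
#'   enough multi-isoform genes to force the complement unequal).
#' @param switch_counts Named counts `lncrna_a_only`, `lncrna_b_only`,
#'   `coding_a_only`, `coding_b_only` of planted category-switch genes
#'   (each needs a catalog gene with a long and a short isoform).
#' @param bifunctional_counts Named counts `a_only`, `b_only`, `both` of
#'   planted bifunctional genes (each needs two long isoforms).
#' @param novel_per_class Novel long-ncRNA transcripts per splice class
#'   planted into sample A (see [generate_splice_variants()]).
#' @param rpkm_meanlog,rpkm_sdlog Log-normal RPKM parameters.
#' @param boundary_n Records pinned exactly at `threshold` per sample.
#' @param decoy_frac Sub-threshold decoy records per sample, as a
#'   fraction of that sample's expressed records.
#' @param sample_names Length-2 character vector.
#' @param seed Integer seed.
#' @return List: `expression_a`/`expression_b` (data frames
#'   `transcript_id`, `rpkm`, including decoys), `scores_a`/`scores_b`
#'   (data frames `transcript_id`, `cpc_score`), `transcripts` (named
#'   list of all models incl. novel ones), `sample_a`/`sample_b`
#'   (filtered `sample_transcriptome`s for convenience), and `truth`.
#' @export
generate_paired_transcriptomes <- function(catalog_bundle,
                                           shared_gene_frac = 0.49,
                                           shared_isoform_frac = 0.3,
                                           coding_frac = 0.96,
                                           long_min = 201L,
                                           threshold = 0.1,
                                           identical_set_frac = NULL,
                                           switch_counts = c(lncrna_a_only = 0,
                                                             lncrna_b_only = 0,
                                                             coding_a_only = 0,
                                                             coding_b_only = 0),
                                           bifunctional_counts = c(a_only = 0,
                                                                   b_only = 0,
                                                                   both = 0),
                                           novel_per_class = 0L,
                                           rpkm_meanlog = log(5),
                                           rpkm_sdlog = 1,
                                           boundary_n = 2L,
                                           decoy_frac = 0.15,
                                           sample_names = c("A", "B"),
                                           seed = 1L) {
  catalog <- if (inherits(catalog_bundle, "gene_catalog")) catalog_bundle
             else catalog_bundle$catalog
  stopifnot(inherits(catalog, "gene_catalog"),
            shared_gene_frac >= 0, shared_gene_frac <= 1,
            shared_isoform_frac >= 0, shared_isoform_frac <= 1,
            coding_frac >= 0, coding_frac <= 1)
  sw <- c(lncrna_a_only = 0, lncrna_b_only = 0,
          coding_a_only = 0, coding_b_only = 0)
  sw[names(switch_counts)] <- switch_counts
  bf <- c(a_only = 0, b_only = 0, both = 0)
  bf[names(bifunctional_counts)] <- bifunctional_counts
  set.seed(seed)

  genes <- sample(names(catalog$genes))
  n_genes <- length(genes)
  n_common <- round(shared_gene_frac * n_genes)
  n_rest <- n_genes - n_common

  len_of <- vapply(catalog$transcripts, spliced_length, numeric(1L))
  long_ids_of <- function(g) {
    ids <- catalog$genes[[g]]
    ids[len_of[ids] >= long_min]
  }
  short_ids_of <- function(g) {
    ids <- catalog$genes[[g]]
    ids[len_of[ids] < long_min]
  }
  can_bif <- vapply(genes, function(g) length(long_ids_of(g)) >= 2L,
                    logical(1L))
  can_sw <- vapply(genes, function(g) {
    length(long_ids_of(g)) >= 1L && length(short_ids_of(g)) >= 1L
  }, logical(1L))

  take <- function(pool, n, what) {
    if (length(pool) < n) {
      stop("catalog cannot support planting ", n, " ", what,
           " gene(s); only ", length(pool), " eligible", call. = FALSE)
    }
    pool[seq_len(n)]
  }
  pool_sw <- genes[can_sw]
  g_lnc_a <- take(pool_sw, sw[["lncrna_a_only"]], "lncrna_a_only")
  pool_sw <- setdiff(pool_sw, g_lnc_a)
  g_lnc_b <- take(pool_sw, sw[["lncrna_b_only"]], "lncrna_b_only")
  pool_sw <- setdiff(pool_sw, g_lnc_b)
  g_cod_a <- take(pool_sw, sw[["coding_a_only"]], "coding_a_only")
  pool_sw <- setdiff(pool_sw, g_cod_a)
  g_cod_b <- take(pool_sw, sw[["coding_b_only"]], "coding_b_only")
  used <- c(g_lnc_a, g_lnc_b, g_cod_a, g_cod_b)
  pool_bif <- setdiff(genes[can_bif], used)
  g_bif_both <- take(pool_bif, bf[["both"]], "bifunctional-both")
  pool_bif <- setdiff(pool_bif, g_bif_both)
  g_bif_a <- take(pool_bif, bf[["a_only"]], "bifunctional-A")
  pool_bif <- setdiff(pool_bif, g_bif_a)
  g_bif_b <- take(pool_bif, bf[["b_only"]], "bifunctional-B")
  special <- c(used, g_bif_both, g_bif_a, g_bif_b)
  if (length(special) > n_common) {
    stop("planted groups exceed the number of common genes", call. = FALSE)
  }
  plain_pool <- setdiff(genes, special)
  g_common_plain <- plain_pool[seq_len(n_common - length(special))]
  rest <- setdiff(plain_pool, g_common_plain)
  g_a_only <- rest[seq_len(ceiling(n_rest / 2))]
  g_b_only <- setdiff(rest, g_a_only)
  g_common <- c(special, g_common_plain)

  membership <- stats::setNames(rep("none", length(catalog$transcripts)),
                                names(catalog$transcripts))
  coding <- stats::setNames(stats::runif(length(membership)) < coding_frac,
                            names(membership))

  plant <- function(gs, pick, memb, code) {
    for (g in gs) {
      ids <- pick(g)
      membership[ids] <<- memb
      coding[ids] <<- code
    }
  }
  plant(g_bif_both, function(g) long_ids_of(g)[1:2], c("both", "both"),
        c(TRUE, FALSE))
  plant(g_bif_a, function(g) long_ids_of(g)[1:2], c("both", "A"),
        c(TRUE, FALSE))
  plant(g_bif_b, function(g) long_ids_of(g)[1:2], c("both", "B"),
        c(TRUE, FALSE))
  plant(g_lnc_a, function(g) c(long_ids_of(g)[1L], short_ids_of(g)[1L]),
        c("A", "B"), c(FALSE, FALSE))
  plant(g_lnc_b, function(g) c(long_ids_of(g)[1L], short_ids_of(g)[1L]),
        c("B", "A"), c(FALSE, FALSE))
  plant(g_cod_a, function(g) c(long_ids_of(g)[1L], short_ids_of(g)[1L]),
        c("A", "B"), c(TRUE, FALSE))
  plant(g_cod_b, function(g) c(long_ids_of(g)[1L], short_ids_of(g)[1L]),
        c("B", "A"), c(TRUE, FALSE))

  g_identical <- character(0)
  if (!is.null(identical_set_frac)) {
    k_id <- round(identical_set_frac * n_common)
    k_plain <- k_id - length(g_bif_both)
    if (k_plain < 0 || k_plain > length(g_common_plain)) {
      stop("identical_set_frac incompatible with planted groups",
           call. = FALSE)
    }
    g_identical <- g_common_plain[seq_len(k_plain)]
    g_forced_diff <- setdiff(g_common_plain, g_identical)
    n_multi <- vapply(g_forced_diff,
                      function(g) length(catalog$genes[[g]]), integer(1L))
    if (any(n_multi < 2L)) {
      stop("forcing unequal isoform sets needs >= 2 isoforms per gene; ",
           sum(n_multi < 2L), " single-isoform gene(s) in the way",
           call. = FALSE)
    }
    for (g in g_identical) membership[catalog$genes[[g]]] <- "both"
    for (g in g_forced_diff) {
      ids <- catalog$genes[[g]]
      membership[ids[1L]] <- "both"
      membership[ids[2L]] <- sample(c("A", "B"), 1L)
      extra <- ids[-(1:2)]
      if (length(extra)) {
        membership[extra] <- sample(c("both", "A", "B"), length(extra),
                                    replace = TRUE,
                                    prob = c(shared_isoform_frac,
                                             (1 - shared_isoform_frac) / 2,
                                             (1 - shared_isoform_frac) / 2))
      }
    }
  } else {
    for (g in g_common_plain) {
      ids <- catalog$genes[[g]]
      membership[ids] <- sample(c("both", "A", "B"), length(ids),
                                replace = TRUE,
                                prob = c(shared_isoform_frac,
                                         (1 - shared_isoform_frac) / 2,
                                         (1 - shared_isoform_frac) / 2))
      if (!any(membership[ids] %in% c("both", "A"))) {
        membership[ids[sample.int(length(ids), 1L)]] <- "both"
      }
      if (!any(membership[ids] %in% c("both", "B"))) {
        flip <- ids[membership[ids] != "both"][1L]
        membership[flip] <- "both"
      }
    }
  }
  for (g in g_a_only) {
    ids <- catalog$genes[[g]]
    on <- stats::runif(length(ids)) < 0.8
    if (!any(on)) on[sample.int(length(ids), 1L)] <- TRUE
    membership[ids[on]] <- "A"
  }
  for (g in g_b_only) {
    ids <- catalog$genes[[g]]
    on <- stats::runif(length(ids)) < 0.8
    if (!any(on)) on[sample.int(length(ids), 1L)] <- TRUE
    membership[ids[on]] <- "B"
  }

  transcripts <- catalog$transcripts
  novel_truth <- NULL
  if (novel_per_class > 0L) {
    donors <- c(g_common, g_a_only)
    sv <- generate_splice_variants(catalog, n_per_class = novel_per_class,
                                   genes = donors, min_length = long_min,
                                   seed = seed + 1L)
    for (t in sv$transcripts) {
      transcripts[[t$transcript_id]] <- t
      membership[t$transcript_id] <- "A"
      coding[t$transcript_id] <- FALSE
    }
    novel_truth <- sv$classes
  }

  tids <- names(transcripts)
  lens <- vapply(transcripts, spliced_length, numeric(1L))
  coding <- coding[tids]
  true_label <- ifelse(coding, "PROTEIN_CODING",
                       ifelse(lens >= long_min, "LONG_NCRNA", "SHORT_NCRNA"))
  names(true_label) <- tids
  score <- ifelse(coding, stats::runif(length(tids), 0.5, 5),
                  stats::runif(length(tids), -5, -0.5))
  names(score) <- tids

  build_sample <- function(side, name) {
    exp_ids <- tids[membership[tids] %in% c("both", side)]
    rpkm <- pmax(stats::rlnorm(length(exp_ids), rpkm_meanlog, rpkm_sdlog),
                 threshold)
    if (boundary_n > 0L && length(exp_ids)) {
      rpkm[sample.int(length(rpkm), min(boundary_n, length(rpkm)))] <-
        threshold
    }
    off_ids <- setdiff(tids, exp_ids)
    n_decoy <- min(length(off_ids), round(decoy_frac * length(exp_ids)))
    decoys <- if (n_decoy > 0L) sample(off_ids, n_decoy) else character(0)
    df <- data.frame(
      transcript_id = c(exp_ids, decoys),
      rpkm = c(rpkm, stats::runif(length(decoys), 0.01, 0.0999)),
      stringsAsFactors = FALSE)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expression_a <- build_sample("A", sample_names[1L])
  expression_b <- build_sample("B", sample_names[2L])
  scores_df <- function(df) data.frame(transcript_id = df$transcript_id,
                                       cpc_score = score[df$transcript_id],
                                       row.names = NULL,
                                       stringsAsFactors = FALSE)

  # realized expectations, derived from the assignment itself
  in_a <- tids[membership[tids] %in% c("both", "A")]
  in_b <- tids[membership[tids] %in% c("both", "B")]
  gene_of <- vapply(transcripts, `[[`, character(1L), "gene_id")
  genes_a <- unique(gene_of[in_a]); genes_b <- unique(gene_of[in_b])
  common_genes <- intersect(genes_a, genes_b)
  sets_a <- lapply(split(in_a, gene_of[in_a]), sort)
  sets_b <- lapply(split(in_b, gene_of[in_b]), sort)
  ident <- common_genes[vapply(common_genes, function(g)
    identical(sets_a[[g]], sets_b[[g]]), logical(1L))]
  has <- function(ids, lab) unique(gene_of[ids][true_label[ids] == lab])
  lnc_a <- has(in_a, "LONG_NCRNA"); lnc_b <- has(in_b, "LONG_NCRNA")
  cod_a <- has(in_a, "PROTEIN_CODING"); cod_b <- has(in_b, "PROTEIN_CODING")
  truth <- list(
    seed = seed,
    params = list(shared_gene_frac = shared_gene_frac,
                  shared_isoform_frac = shared_isoform_frac,
                  coding_frac = coding_frac, long_min = long_min,
                  threshold = threshold,
                  identical_set_frac = identical_set_frac,
                  switch_counts = sw, bifunctional_counts = bf),
    genes_common = sort(common_genes),
    genes_a_only = sort(setdiff(genes_a, genes_b)),
    genes_b_only = sort(setdiff(genes_b, genes_a)),
    isoforms_common = sort(intersect(in_a, in_b)),
    isoforms_a_only = sort(setdiff(in_a, in_b)),
    isoforms_b_only = sort(setdiff(in_b, in_a)),
    identical_set_genes = sort(ident),
    bifunctional_a = sort(intersect(lnc_a, cod_a)),
    bifunctional_b = sort(intersect(lnc_b, cod_b)),
    switches = list(
      lncrna_a_only = sort(intersect(common_genes, setdiff(lnc_a, lnc_b))),
      lncrna_b_only = sort(intersect(common_genes, setdiff(lnc_b, lnc_a))),
      coding_a_only = sort(intersect(common_genes, setdiff(cod_a, cod_b))),
      coding_b_only = sort(intersect(common_genes, setdiff(cod_b, cod_a)))),
    true_label = true_label,
    novel_classes = novel_truth)

  sample_a <- filter_expressed(transcripts, expression_a, threshold,
                               sample_names[1L])
  sample_b <- filter_expressed(transcripts, expression_b, threshold,
                               sample_names[2L])
  list(expression_a = expression_a, expression_b = expression_b,
       scores_a = scores_df(expression_a), scores_b = scores_df(expression_b),
       transcripts = transcripts,
       sample_a = sample_a, sample_b = sample_b, truth = truth)
}

#' Plant novel transcripts with known splice classes
#'
#' Each variant is an explicit edit of a gene's full annotated chain, so
#' its class under the classifier's precedence is unambiguous by
#' construction: merging two consecutive exons engulfs their intron
#' (`INTRON_RETENTION`); extending an exon end partway into its intron
#' creates an unannotated internal boundary without engulfing anything
#' (`NOVEL_BOUNDARY_OR_EXON`); dropping an internal exon keeps every
#' boundary annotated while changing the chain (`EXON_SKIPPING`).
#' Candidate edits whose chain collides with an annotated isoform are
#' skipped.
#'
#' @param catalog A [gene_catalog()].
#' @param n_per_class Variants per class.
#' @param genes Optional gene pool to draw donors from (default: all).
#' @param min_length Minimum spliced length of a variant (default 201 so
#'   variants qualify as long ncRNAs).
#' @param seed Integer seed.
#' @return List with `transcripts` (list of novel [transcript_model()]s)
#'   and `classes` (data frame `transcript_id`, `gene_id`, `class`).
#' @export
generate_splice_variants <- function(catalog, n_per_class = 1L,
                                     genes = NULL, min_length = 201L,
                                     seed = 1L) {
  stopifnot(inherits(catalog, "gene_catalog"), n_per_class >= 1L)
  set.seed(seed)
  if (is.null(genes)) genes <- names(catalog$genes)
  genes <- sample(genes)
  ann_keys_of <- function(g) {
    vapply(gene_transcripts(catalog, g), exon_chain_key, character(1L))
  }
  master_of <- function(g) {
    tx <- gene_transcripts(catalog, g)
    tx[[which.max(vapply(tx, exon_count, numeric(1L)))]]
  }
  out <- list()
  rows <- list()
  make <- function(class, builder, need_exons) {
    made <- 0L
    for (g in genes) {
      if (made >= n_per_class) break
      m <- master_of(g)
      if (exon_count(m) < need_exons) next
      cand <- builder(m)
      if (is.null(cand)) next
      if (spliced_length(cand) < min_length) next
      if (exon_chain_key(cand) %in% ann_keys_of(g)) next
      made <- made + 1L
      out[[length(out) + 1L]] <<- cand
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript_id = cand$transcript_id, gene_id = g, class = class,
        stringsAsFactors = FALSE)
    }
    if (made < n_per_class) {
      stop("could not plant ", n_per_class, " ", class,
           " variant(s); catalog too small or exon chains too short",
           call. = FALSE)
    }
  }
  make("INTRON_RETENTION", function(m) {
    j <- sample.int(exon_count(m) - 1L, 1L)
    ex <- m$exons
    ex[j, 2L] <- ex[j + 1L, 2L]
    ex <- ex[-(j + 1L), , drop = FALSE]
    transcript_model(paste0("novelIR.", m$gene_id), m$gene_id, m$chrom,
                     m$strand, ex)
  }, need_exons = 2L)
  make("NOVEL_BOUNDARY_OR_EXON", function(m) {
    j <- sample.int(exon_count(m) - 1L, 1L)
    gap <- m$exons[j + 1L, 1L] - m$exons[j, 2L]
    d <- floor(gap / 2)
    if (d < 5) return(NULL)
    ex <- m$exons
    ex[j, 2L] <- ex[j, 2L] + d
    transcript_model(paste0("novelNB.", m$gene_id), m$gene_id, m$chrom,
                     m$strand, ex)
  }, need_exons = 2L)
  make("EXON_SKIPPING", function(m) {
    j <- sample(2:(exon_count(m) - 1L), 1L)
    ex <- m$exons[-j, , drop = FALSE]
    transcript_model(paste0("novelES.", m$gene_id), m$gene_id, m$chrom,
                     m$strand, ex)
  }, need_exons = 3L)
  classes <- do.call(rbind, rows)
  rownames(classes) <- NULL
  list(transcripts = out, classes = classes)
}

#' Generate conservation tracks with planted element coverage
#'
#' For each clade, conserved elements are planted under an exact number of
#' transcripts: genes are chosen (greedy packing over their isoform
#' counts) so that the covered transcripts number exactly
#' `round(coverage_frac * n_transcripts)`, and one element is laid over
#' each merged exon region of every chosen gene, so every isoform of a
#' chosen gene overlaps an element and no other transcript does. Base
#' scores are emitted as bedGraph-style runs: scores in \[0.9, 1\] over
#' planted elements, background scores in \[0, 0.89) over the exons of
#' uncovered genes.
#'
#' @param catalog A [gene_catalog()] (or the list from
#'   [generate_gene_catalog()]).
#' @param coverage_frac Scalar or per-clade vector of target fractions of
#'   transcripts containing an element.
#' @param clades Clade labels.
#' @param seed Integer seed.
#' @return List with `tracks` (list of [conservation_track()]s, one per
#'   clade) and `truth` (per clade: covered transcript IDs and the
#'   realized coverage fraction).
#' @export
generate_conservation_tracks <- function(catalog, coverage_frac = 0.8,
                                         clades = c("vertebrates46",
                                                    "placental33",
                                                    "primates10"),
                                         seed = 1L) {
  if (!inherits(catalog, "gene_catalog")) catalog <- catalog$catalog
  stopifnot(all(coverage_frac >= 0), all(coverage_frac <= 1))
  coverage_frac <- rep_len(coverage_frac, length(clades))
  set.seed(seed)
  n_tx <- length(catalog$transcripts)
  gene_sizes <- lengths(catalog$genes)
  gene_exons <- lapply(names(catalog$genes), function(g) {
    tx <- gene_transcripts(catalog, g)
    ex <- do.call(rbind, lapply(tx, `[[`, "exons"))
    merge_intervals(data.frame(chrom = tx[[1L]]$chrom, start = ex[, 1L],
                               end = ex[, 2L], stringsAsFactors = FALSE))
  })
  names(gene_exons) <- names(catalog$genes)

  tracks <- list()
  truth <- list()
  for (ci in seq_along(clades)) {
    k <- round(coverage_frac[ci] * n_tx)
    order_g <- sample(names(catalog$genes))
    covered_genes <- character(0)
    remaining <- k
    for (g in order_g) {
      if (remaining == 0L) break
      if (gene_sizes[[g]] <= remaining) {
        covered_genes <- c(covered_genes, g)
        remaining <- remaining - gene_sizes[[g]]
      }
    }
    if (remaining > 0L) {
      stop("cannot cover exactly ", k, " transcript(s) for clade ",
           clades[ci], "; gene isoform counts do not pack", call. = FALSE)
    }
    elements <- if (length(covered_genes)) {
      do.call(rbind, gene_exons[covered_genes])
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    }
    bg_genes <- setdiff(names(catalog$genes), covered_genes)
    background <- if (length(bg_genes)) {
      do.call(rbind, gene_exons[bg_genes])
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    }
    scores <- rbind(
      if (nrow(elements)) cbind(elements,
                                score = stats::runif(nrow(elements), 0.9, 1))
      else NULL,
      if (nrow(background)) cbind(background,
                                  score = stats::runif(nrow(background),
                                                       0, 0.889))
      else NULL)
    if (is.null(scores)) {
      scores <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), score = numeric(),
                           stringsAsFactors = FALSE)
    }
    rownames(scores) <- NULL
    tracks[[clades[ci]]] <- conservation_track(clades[ci], scores, elements)
    covered_tx <- unlist(catalog$genes[covered_genes], use.names = FALSE)
    truth[[clades[ci]]] <- list(covered_transcripts = sort(covered_tx),
                                coverage_frac = length(covered_tx) / n_tx)
  }
  list(tracks = tracks, truth = truth)
}

#' Plant a single element covering an exact fraction of a transcript
#'
#' Returns one genomic interval whose intersection with the transcript's
#' exons is exactly `round(frac * spliced_length(t))` bases, starting at
#' the transcript's leftmost exonic base (introns inside the interval do
#' not count, by construction of the overlap arithmetic).
#'
#' @param t A [transcript_model()].
#' @param frac Target fraction in (0, 1\].
#' @return One-row data frame `chrom`, `start`, `end`.
#' @export
plant_element_fraction <- function(t, frac) {
  stopifnot(inherits(t, "transcript_model"), frac > 0, frac <= 1)
  m <- round(frac * spliced_length(t))
  stopifnot(m >= 1)
  lens <- t$exons[, 2L] - t$exons[, 1L]
  cum <- cumsum(lens)
  j <- which(cum >= m)[1L]
  within <- m - if (j > 1L) cum[j - 1L] else 0
  data.frame(chrom = t$chrom, start = t$exons[1L, 1L],
             end = t$exons[j, 1L] + within, stringsAsFactors = FALSE)
}

#' Generate case/control expression matrices with planted signal
#'
#' The main matrix has a log-normal background (`2^L - 1` with `L` drawn
#' normal on the log2 scale, so `log2(x + 1)` recovers `L` exactly) and a
#' planted mean shift of `effect_size` background-SD in the case columns
#' of a known probe subset. Correlated probe pairs are returned as two
#' aligned matrices on the log2 scale whose row pairs are bivariate
#' normal at the planted correlation.
#'
#' @param n_probes Rows of the main matrix.
#' @param n_case,n_control Samples per group.
#' @param de_frac Fraction of probes given the mean shift.
#' @param effect_size Shift in background-SD units (log2 scale).
#' @param corr_pairs Number of planted ncRNA-gene probe pairs.
#' @param rho Planted Pearson correlation, |rho| < 1.
#' @param base_mean,base_sd Background location/scale on the log2 scale.
#' @param seed Integer seed.
#' @return List: `matrix` (probes x samples), `groups` (list `case`,
#'   `control` of column names), `ncrna_mat`, `gene_mat`, `gene_symbols`,
#'   and `truth` (`de_probes`, `pairs`, `rho`, `seed`).
#' @export
generate_disease_matrices <- function(n_probes = 100L, n_case = 10L,
                                      n_control = 10L, de_frac = 0.1,
                                      effect_size = 4, corr_pairs = 0L,
                                      rho = 0, base_mean = 6, base_sd = 1,
                                      seed = 1L) {
  stopifnot(n_probes >= 1L, n_case >= 2L, n_control >= 2L,
            de_frac >= 0, de_frac <= 1, abs(rho) < 1)
  set.seed(seed)
  n <- n_case + n_control
  samples <- c(paste0("case", seq_len(n_case)),
               paste0("ctrl", seq_len(n_control)))
  mu <- stats::rnorm(n_probes, base_mean, 0.5)
  L <- matrix(stats::rnorm(n_probes * n, mean = mu, sd = base_sd),
              nrow = n_probes)
  de_probes <- sort(sample.int(n_probes, round(de_frac * n_probes)))
  L[de_probes, seq_len(n_case)] <- L[de_probes, seq_len(n_case)] +
    effect_size * base_sd
  m <- pmax(2^L - 1, 0)
  rownames(m) <- sprintf("P%05d", seq_len(n_probes))
  colnames(m) <- samples

  ncrna_mat <- gene_mat <- NULL
  gene_symbols <- character(0)
  pairs <- NULL
  if (corr_pairs > 0L) {
    z1 <- matrix(stats::rnorm(corr_pairs * n), nrow = corr_pairs)
    z2 <- matrix(stats::rnorm(corr_pairs * n), nrow = corr_pairs)
    ncrna_mat <- base_mean + base_sd * z1
    gene_mat <- base_mean + base_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    rownames(ncrna_mat) <- sprintf("NC%04d", seq_len(corr_pairs))
    rownames(gene_mat) <- sprintf("GP%04d", seq_len(corr_pairs))
    colnames(ncrna_mat) <- colnames(gene_mat) <- samples
    gene_symbols <- sprintf("GENE%d", seq_len(corr_pairs))
    pairs <- data.frame(ncrna_probe_id = rownames(ncrna_mat),
                        gene_probe_id = rownames(gene_mat),
                        stringsAsFactors = FALSE)
  }
  list(matrix = m,
       groups = list(case = samples[seq_len(n_case)],
                     control = samples[n_case + seq_len(n_control)]),
       ncrna_mat = ncrna_mat, gene_mat = gene_mat,
       gene_symbols = gene_symbols,
       truth = list(de_probes = rownames(m)[de_probes], pairs = pairs,
                    rho = rho, seed = seed))
}

count_probe_hits <- function(pat, subject) {
  sum(Biostrings::vcountPattern(pat, subject))
}

#' Generate oligo probes with known match status
#'
#' Draws probes from supplied spliced transcript sequences with verified
#' ground truth: `unique` probes occur at exactly one position across the
#' whole set, `multi` probes at two or more (exploiting exon sharing
#' between isoforms), `nomatch` probes nowhere.
#'
#' @param sequences Named character vector of transcript sequences.
#' @param n_unique,n_multi,n_nomatch Probe counts per category.
#' @param probe_len Probe length in nt (default 25, short-oligo style).
#' @param seed Integer seed.
#' @return List with `probes` (data frame `probe_id`, `sequence`,
#'   `gene_symbol` = `NA`) and `truth` (data frame `probe_id`,
#'   `category`, `source_transcript`).
#' @export
generate_probes <- function(sequences, n_unique = 10L, n_multi = 2L,
                            n_nomatch = 2L, probe_len = 25L, seed = 1L) {
  stopifnot(length(sequences) > 0L, !is.null(names(sequences)))
  set.seed(seed)
  subject <- Biostrings::DNAStringSet(sequences)
  long_enough <- names(sequences)[nchar(sequences) >= probe_len]
  if (!length(long_enough)) {
    stop("no transcript sequence reaches probe_len", call. = FALSE)
  }
  draw_from <- function(target_hits, cmp, n_want, tag) {
    got <- list()
    for (try in seq_len(2000L)) {
      if (length(got) >= n_want) break
      tid <- sample(long_enough, 1L)
      s <- sequences[[tid]]
      pos <- sample.int(nchar(s) - probe_len + 1L, 1L)
      pat <- substr(s, pos, pos + probe_len - 1L)
      if (grepl("N", pat, fixed = TRUE)) next
      hits <- count_probe_hits(pat, subject)
      if (cmp(hits, target_hits) && !pat %in% vapply(got, `[[`, "", "seq")) {
        got[[length(got) + 1L]] <- list(seq = pat, src = tid)
      }
    }
    if (length(got) < n_want) {
      stop("could not draw ", n_want, " ", tag, " probe(s)", call. = FALSE)
    }
    got
  }
  uniq <- if (n_unique > 0L) {
    draw_from(1L, `==`, n_unique, "unique")
  } else list()
  multi <- if (n_multi > 0L) {
    draw_from(2L, `>=`, n_multi, "multi-match")
  } else list()
  nomatch <- list()
  for (try in seq_len(2000L)) {
    if (length(nomatch) >= n_nomatch) break
    pat <- random_dna(probe_len)
    if (count_probe_hits(pat, subject) == 0L) {
      nomatch[[length(nomatch) + 1L]] <- list(seq = pat, src = NA_character_)
    }
  }
  if (length(nomatch) < n_nomatch) {
    stop("could not draw ", n_nomatch, " no-match probe(s)", call. = FALSE)
  }
  all <- c(uniq, multi, nomatch)
  category <- c(rep("unique", length(uniq)), rep("multi", length(multi)),
                rep("nomatch", length(nomatch)))
  probes <- data.frame(
    probe_id = sprintf("PRB%04d", seq_along(all)),
    sequence = vapply(all, `[[`, "", "seq"),
    gene_symbol = NA_character_, stringsAsFactors = FALSE)
  list(probes = probes,
       truth = data.frame(probe_id = probes$probe_id, category = category,
                          source_transcript = vapply(all, `[[`, "", "src"),
                          stringsAsFactors = FALSE))
}
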