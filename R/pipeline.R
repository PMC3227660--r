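#' Pipeline configuration
#'
#' Bundles input paths and thresholds for [run_pipeline()]. Threshold
#' defaults are the analysis' reference values: expressed at >= 0.1 RPKM,
#' long ncRNA strictly > 200 nt, coding at score > 0, conserved base at
#' score >= 0.9, correlation hits at |r| >= 0.4 and p < 0.05, DE at
#' FDR < 0.05. All thresholds are range-checked here so a stage never
#' starts with an out-of-range value.
#'
#' @param annotation Annotation path (GTF or BED12).
#' @param annotation_format `"gtf"` or `"bed12"`.
#' @param expression_a,expression_b Expression TSV paths.
#' @param scores_a,scores_b Coding-score TSV paths (`transcript_id`,
#'   `cpc_score`).
#' @param genome Genome FASTA path.
#' @param conservation Named list (clade -> list with `scores` bedGraph
#'   path and `elements` BED path).
#' @param probes Probe TSV path (`probe_id`, `sequence`, `gene_symbol`).
#' @param disease_matrix Expression-matrix TSV (first column `probe_id`,
#'   then sample columns).
#' @param disease_groups Group TSV (`sample`, `group` with values
#'   `case`/`control`).
#' @param min_rpkm,lncrna_min_len,coding_cutoff,cons_cutoff,r_min,p_max,fdr
#'   Thresholds (defaults 0.1, 201, 0, 0.9, 0.4, 0.05, 0.05).
#' @param identity Isoform identity mode for comparisons.
#' @param sample_names Length-2 labels for samples A and B.
#' @param seed Integer seed recorded in the manifest (stages themselves
#'   are deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(annotation = NULL, annotation_format = "gtf",
                            expression_a = NULL, expression_b = NULL,
                            scores_a = NULL, scores_b = NULL,
                            genome = NULL, conservation = NULL,
                            probes = NULL, disease_matrix = NULL,
                            disease_groups = NULL,
                            min_rpkm = 0.1, lncrna_min_len = 201,
                            coding_cutoff = 0, cons_cutoff = 0.9,
                            r_min = 0.4, p_max = 0.05, fdr = 0.05,
                            identity = c("exon_chain", "transcript_id"),
                            sample_names = c("A", "B"), seed = 1L) {
  identity <- match.arg(identity)
  stopifnot(min_rpkm >= 0, lncrna_min_len >= 1,
            cons_cutoff >= 0, cons_cutoff <= 1,
            r_min >= 0, r_min <= 1, p_max > 0, p_max <= 1,
            fdr > 0, fdr <= 1, length(sample_names) == 2L)
  structure(list(
    annotation = annotation, annotation_format = annotation_format,
    expression_a = expression_a, expression_b = expression_b,
    scores_a = scores_a, scores_b = scores_b, genome = genome,
    conservation = conservation, probes = probes,
    disease_matrix = disease_matrix, disease_groups = disease_groups,
    min_rpkm = min_rpkm, lncrna_min_len = lncrna_min_len,
    coding_cutoff = coding_cutoff, cons_cutoff = cons_cutoff,
    r_min = r_min, p_max = p_max, fdr = fdr, identity = identity,
    sample_names = sample_names, seed = seed), class = "pipeline_config")
}

stage_requirements <- list(
  quantify = c("annotation", "expression_a", "expression_b"),
  classify = c("annotation", "expression_a", "expression_b",
               "scores_a", "scores_b"),
  compare = c("annotation", "expression_a", "expression_b",
              "scores_a", "scores_b"),
  splice = c("annotation", "expression_a", "expression_b",
             "scores_a", "scores_b"),
  conserve = c("annotation", "expression_a", "expression_b",
               "scores_a", "scores_b", "conservation"),
  screen = c("annotation", "expression_a", "expression_b",
             "scores_a", "scores_b", "genome", "probes",
             "disease_matrix", "disease_groups")
)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run pipeline stages over configured inputs
#'
#' Validates that every input required by the selected stages exists
#' before any stage runs (fail fast, no partial outputs on a missing
#' input), then executes the stages in dependency order and writes their
#' tables plus a `manifest.json` (inputs, thresholds, seed, per-stage
#' record counts) and a `summary.json` of headline numbers. All stages
#' are deterministic, so re-running an identical config reproduces
#' `summary.json` byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("quantify", "classify", "compare",
#'   "splice", "conserve", "screen")`; dependencies are implied (every
#'   stage needs quantify+classify inputs).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("quantify", "classify", "compare",
                                    "splice", "conserve", "screen"),
                         out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  required <- unique(unlist(stage_requirements[stages]))
  for (key in required) {
    val <- config[[key]]
    if (is.null(val)) {
      stop("stage input '", key, "' missing from config", call. = FALSE)
    }
    paths <- if (key == "conservation") {
      unlist(val, use.names = FALSE)
    } else val
    for (p in paths) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(inputs = config[required],
                   thresholds = config[c("min_rpkm", "lncrna_min_len",
                                         "coding_cutoff", "cons_cutoff",
                                         "r_min", "p_max", "fdr")],
                   identity = config$identity, seed = config$seed,
                   stages = list())
  res <- list()

  catalog <- read_annotation(config$annotation, config$annotation_format)
  tx <- catalog$transcripts
  exp_a <- read_expression_tsv(config$expression_a)
  exp_b <- read_expression_tsv(config$expression_b)
  sample_a <- filter_expressed(tx, exp_a, config$min_rpkm,
                               config$sample_names[1L])
  sample_b <- filter_expressed(tx, exp_b, config$min_rpkm,
                               config$sample_names[2L])
  res$samples <- list(a = sample_a, b = sample_b)
  if ("quantify" %in% stages) {
    write_tsv(sample_a$expression, file.path(out_dir, "expressed_a.tsv"))
    write_tsv(sample_b$expression, file.path(out_dir, "expressed_b.tsv"))
    manifest$stages$quantify <- list(
      a = sample_a$filter, b = sample_b$filter)
  }

  need_labels <- any(c("classify", "compare", "splice", "conserve",
                       "screen") %in% stages)
  if (need_labels) {
    sc_a <- utils::read.delim(config$scores_a, stringsAsFactors = FALSE)
    sc_b <- utils::read.delim(config$scores_b, stringsAsFactors = FALSE)
    labels_a <- classify_sample(sample_a, sc_a, config$coding_cutoff,
                                config$lncrna_min_len)
    labels_b <- classify_sample(sample_b, sc_b, config$coding_cutoff,
                                config$lncrna_min_len)
    cats_a <- classify_genes(labels_a)
    cats_b <- classify_genes(labels_b)
    res$labels <- list(a = labels_a, b = labels_b)
    res$gene_categories <- list(a = cats_a, b = cats_b)
    if ("classify" %in% stages) {
      write_tsv(labels_a, file.path(out_dir, "labels_a.tsv"))
      write_tsv(labels_b, file.path(out_dir, "labels_b.tsv"))
      write_tsv(cats_a, file.path(out_dir, "gene_categories_a.tsv"))
      write_tsv(cats_b, file.path(out_dir, "gene_categories_b.tsv"))
      manifest$stages$classify <- list(
        a = as.list(table(labels_a$label)),
        b = as.list(table(labels_b$label)))
    }
  }

  if ("compare" %in% stages) {
    cmp <- comparison_summary(sample_a, sample_b, labels_a, labels_b,
                              config$identity)
    res$comparison <- cmp
    jsonlite::write_json(list(
      genes = list(n_a = cmp$genes$n_a, n_b = cmp$genes$n_b,
                   n_common = length(cmp$genes$common),
                   pct_a_only = cmp$genes$pct_a_only,
                   pct_b_only = cmp$genes$pct_b_only),
      isoforms = list(n_a = cmp$isoforms$n_a, n_b = cmp$isoforms$n_b,
                      n_common = length(cmp$isoforms$common),
                      pct_a_only = cmp$isoforms$pct_a_only,
                      pct_b_only = cmp$isoforms$pct_b_only),
      identical_set_genes = length(cmp$identical_set_genes),
      switches = lapply(cmp$switches, length),
      bifunctional_union = cmp$bifunctional$n_union,
      mean_isoforms_per_gene = as.list(cmp$mean_isoforms_per_gene)),
      file.path(out_dir, "comparison_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$compare <- list(
      common_genes = length(cmp$genes$common),
      common_isoforms = length(cmp$isoforms$common))
  }

  if ("splice" %in% stages) {
    bif_lnc <- function(sample, labels, cats) {
      bif <- cats$gene_id[cats$category == "BIFUNCTIONAL"]
      ids <- labels$transcript_id[labels$label == "LONG_NCRNA" &
                                    labels$gene_id %in% bif]
      sample$transcripts[ids]
    }
    tl_a <- tally_splice_classes(bif_lnc(sample_a, labels_a, cats_a), catalog)
    tl_b <- tally_splice_classes(bif_lnc(sample_b, labels_b, cats_b), catalog)
    res$splice <- list(a = tl_a, b = tl_b)
    write_tsv(tl_a$classes, file.path(out_dir, "splice_classes_a.tsv"))
    write_tsv(tl_b$classes, file.path(out_dir, "splice_classes_b.tsv"))
    manifest$stages$splice <- list(a = as.list(tl_a$counts),
                                   b = as.list(tl_b$counts))
  }

  if ("conserve" %in% stages) {
    lnc_ids <- union(labels_a$transcript_id[labels_a$label == "LONG_NCRNA"],
                     labels_b$transcript_id[labels_b$label == "LONG_NCRNA"])
    lnc_tx <- tx[intersect(lnc_ids, names(tx))]
    tracks <- lapply(names(config$conservation), function(cl) {
      conservation_track(cl,
                         read_score_track(config$conservation[[cl]]$scores),
                         read_elements_bed(config$conservation[[cl]]$elements))
    })
    cons <- clade_conservation_summary(lnc_tx, tracks, config$cons_cutoff)
    res$conservation <- cons
    write_tsv(cons$summary, file.path(out_dir, "conservation_summary.tsv"))
    write_tsv(cons$aggregate, file.path(out_dir, "conservation_aggregate.tsv"))
    manifest$stages$conserve <- list(transcripts = length(lnc_tx),
                                     clades = length(tracks))
  }

  if ("screen" %in% stages) {
    genome <- read_genome_fasta(config$genome)
    lnc_ids <- union(labels_a$transcript_id[labels_a$label == "LONG_NCRNA"],
                     labels_b$transcript_id[labels_b$label == "LONG_NCRNA"])
    seqs <- extract_transcript_sequences(genome, tx[intersect(lnc_ids,
                                                              names(tx))])
    probes <- utils::read.delim(config$probes, stringsAsFactors = FALSE)
    pm <- match_probes(probes, seqs)
    mat_df <- utils::read.delim(config$disease_matrix, check.names = FALSE,
                                stringsAsFactors = FALSE)
    m <- as.matrix(mat_df[, -1L, drop = FALSE])
    rownames(m) <- mat_df[[1L]]
    grp <- utils::read.delim(config$disease_groups,
                             stringsAsFactors = FALSE)
    groups <- list(case = grp$sample[grp$group == "case"],
                   control = grp$sample[grp$group == "control"])
    nc_rows <- intersect(pm$matches$probe_id, rownames(m))
    de <- if (length(nc_rows) >= 1L) {
      differential_expression(m[nc_rows, , drop = FALSE], groups,
                              alpha = config$fdr)
    } else NULL
    sym_probes <- probes$probe_id[!is.na(probes$gene_symbol) &
                                    nzchar(probes$gene_symbol)]
    gene_rows <- intersect(sym_probes, rownames(m))
    corr <- if (length(nc_rows) >= 1L && length(gene_rows) >= 1L) {
      correlation_screen(
        m[nc_rows, , drop = FALSE], m[gene_rows, , drop = FALSE],
        probes$gene_symbol[match(gene_rows, probes$probe_id)],
        config$r_min, config$p_max)
    } else NULL
    res$screen <- list(matches = pm, de = de, correlation = corr)
    write_tsv(pm$matches, file.path(out_dir, "probe_matches.tsv"))
    if (!is.null(de)) write_tsv(de, file.path(out_dir, "de_results.tsv"))
    if (!is.null(corr)) {
      write_tsv(corr$hits, file.path(out_dir, "correlation_hits.tsv"))
    }
    manifest$stages$screen <- list(
      probes_in = nrow(probes), matched = nrow(pm$matches),
      excluded = nrow(pm$excluded),
      de_flagged = if (is.null(de)) 0L else sum(de$differential),
      corr_hits = if (is.null(corr)) 0L else nrow(corr$hits))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(manifest$stages, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
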