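#' Match microarray probes to transcripts, exact and unique
#'
#' A probe is reported only when its sequence occurs as an exact substring
#' at exactly one position across all supplied transcript sequences ("exact
#' and unique"): probes hitting two positions — in one transcript or two —
#' are excluded as ambiguous, probes hitting none as unmatched. By default
#' only the sense (spliced, strand-corrected) sequence is searched; set
#' `both_orientations = TRUE` to also count reverse-complement hits, for
#' arrays whose probe orientation is uncertain.
#'
#' @param probes Data frame with columns `probe_id`, `sequence` and
#'   optionally `gene_symbol`.
#' @param sequences Named character vector of spliced transcript sequences
#'   (names = transcript IDs), e.g. from [extract_transcript_sequences()].
#' @param both_orientations Also search the reverse complement of each
#'   probe.
#' @param require_no_symbol Pre-filter to probes without a gene symbol
#'   (empty or `NA` `gene_symbol`), the convention for finding probes free
#'   to represent unannotated transcripts.
#' @return List with `matches` (data frame `probe_id`, `transcript_id`,
#'   `offset` — 0-based position in the spliced sequence — and `unique`,
#'   always `TRUE`) and `excluded` (data frame `probe_id`, `reason` in
#'   `"no_match"`/`"multi_match"`/`"no_symbol_filter"`).
#' @export
match_probes <- function(probes, sequences, both_orientations = FALSE,
                         require_no_symbol = FALSE) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence") %in% names(probes)),
            length(sequences) > 0L, !is.null(names(sequences)))
  probes$sequence <- toupper(probes$sequence)
  stopifnot(all(nzchar(probes$sequence)))
  excluded <- list()
  if (require_no_symbol) {
    has_sym <- !is.null(probes$gene_symbol) &&
      any(!is.na(probes$gene_symbol) & nzchar(probes$gene_symbol))
    if (has_sym) {
      drop <- !is.na(probes$gene_symbol) & nzchar(probes$gene_symbol)
      if (any(drop)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          probe_id = probes$probe_id[drop], reason = "no_symbol_filter",
          stringsAsFactors = FALSE)
        probes <- probes[!drop, , drop = FALSE]
      }
    }
  }
  subject <- Biostrings::DNAStringSet(sequences)
  match_rows <- list()
  for (i in seq_len(nrow(probes))) {
    pat <- probes$sequence[i]
    hits <- Biostrings::vmatchPattern(pat, subject)
    n_hits <- sum(lengths(hits))
    if (both_orientations) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pat)))
      rc_hits <- Biostrings::vmatchPattern(rc, subject)
      n_hits <- n_hits + sum(lengths(rc_hits))
    }
    if (n_hits == 1L && sum(lengths(hits)) == 1L) {
      j <- which(lengths(hits) == 1L)
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        probe_id = probes$probe_id[i],
        transcript_id = names(sequences)[j],
        offset = Biostrings::start(hits[[j]]) - 1L,
        unique = TRUE, stringsAsFactors = FALSE)
    } else if (n_hits == 1L) {
      # single hit but only on the reverse complement
      j <- which(lengths(rc_hits) == 1L)
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        probe_id = probes$probe_id[i],
        transcript_id = names(sequences)[j],
        offset = Biostrings::start(rc_hits[[j]]) - 1L,
        unique = TRUE, stringsAsFactors = FALSE)
    } else {
      excluded[[length(excluded) + 1L]] <- data.frame(
        probe_id = probes$probe_id[i],
        reason = if (n_hits == 0L) "no_match" else "multi_match",
        stringsAsFactors = FALSE)
    }
  }
  empty_m <- data.frame(probe_id = character(), transcript_id = character(),
                        offset = integer(), unique = logical(),
                        stringsAsFactors = FALSE)
  empty_e <- data.frame(probe_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  list(matches = if (length(match_rows)) do.call(rbind, match_rows)
       else empty_m,
       excluded = if (length(excluded)) do.call(rbind, excluded)
       else empty_e)
}

# Row-wise Welch t-test on a numeric matrix, vectorized.
row_welch <- function(m, case_idx, ctrl_idx) {
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  x1 <- m[, case_idx, drop = FALSE]
  x2 <- m[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  # flat rows (no variance, no shift) are flagged; a clean separation with
  # zero within-group variance is still a discovery
  list(diff = diff, p = p, constant = degenerate & diff == 0)
}

#' Two-group differential expression (Welch t on log2, BH FDR)
#'
#' Per probe: Welch's two-sample t-test on `log2(x + 1)` values, then
#' Benjamini-Hochberg q-values; a probe is called differential at
#' `q < alpha`. Rows that are constant across all samples get `p = 1` by
#' convention and are flagged.
#'
#' @param matrix Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param groups List of two character vectors of column names (or two
#'   integer index vectors): `groups[[1]]` = cases, `groups[[2]]` =
#'   controls. Each group needs at least 2 samples.
#' @param alpha FDR level, default 0.05.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`; set
#'   `FALSE` for matrices already on a log scale).
#' @return Data frame `probe_id`, `mean_diff` (case minus control on the
#'   log scale), `p_value`, `q_value`, `differential`, `constant`.
#' @export
differential_expression <- function(matrix, groups, alpha = 0.05,
                                    log_transform = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), length(groups) == 2L)
  idx <- lapply(groups, function(g) {
    if (is.character(g)) {
      i <- match(g, colnames(matrix))
      if (anyNA(i)) stop("unknown sample(s): ",
                         paste(g[is.na(i)], collapse = ", "), call. = FALSE)
      i
    } else as.integer(g)
  })
  if (any(lengths(idx) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (length(intersect(idx[[1L]], idx[[2L]]))) {
    stop("groups overlap", call. = FALSE)
  }
  m <- if (log_transform) log2(matrix + 1) else matrix
  w <- row_welch(m, idx[[1L]], idx[[2L]])
  q <- stats::p.adjust(w$p, method = "BH")
  data.frame(
    probe_id = if (is.null(rownames(matrix)))
      as.character(seq_len(nrow(matrix))) else rownames(matrix),
    mean_diff = w$diff, p_value = w$p, q_value = q,
    differential = q < alpha & !w$constant,
    constant = w$constant,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation screen between ncRNA probes and gene probes
#'
#' Pearson correlation of every ncRNA-probe row against every gene-probe
#' row across the same samples; the two-sided p-value comes from the t
#' transform with n - 2 degrees of freedom. A pair is a hit when
#' `|r| >= r_min` (inclusive) and `p < p_max` (exclusive). Zero-variance
#' rows cannot be correlated and are skipped with a log entry.
#'
#' @param ncrna_mat Numeric matrix, ncRNA probes in rows, samples in
#'   columns (n >= 3).
#' @param gene_mat Numeric matrix, gene probes in rows, same columns.
#' @param gene_symbols Optional character vector of symbols parallel to
#'   `gene_mat` rows.
#' @param r_min Minimum absolute correlation, default 0.4.
#' @param p_max Exclusive p-value ceiling, default 0.05.
#' @return List with `hits` (data frame `ncrna_probe_id`, `gene_probe_id`,
#'   `gene_symbol`, `r`, `p_value`, ordered by decreasing |r|) and
#'   `skipped` (zero-variance row IDs).
#' @export
correlation_screen <- function(ncrna_mat, gene_mat, gene_symbols = NULL,
                               r_min = 0.4, p_max = 0.05) {
  stopifnot(is.matrix(ncrna_mat), is.matrix(gene_mat),
            ncol(ncrna_mat) == ncol(gene_mat), ncol(ncrna_mat) >= 3L)
  n <- ncol(ncrna_mat)
  rn <- if (is.null(rownames(ncrna_mat)))
    paste0("nc", seq_len(nrow(ncrna_mat))) else rownames(ncrna_mat)
  gn <- if (is.null(rownames(gene_mat)))
    paste0("g", seq_len(nrow(gene_mat))) else rownames(gene_mat)
  if (is.null(gene_symbols)) gene_symbols <- gn
  sd_nc <- apply(ncrna_mat, 1L, stats::sd)
  sd_g <- apply(gene_mat, 1L, stats::sd)
  skipped <- c(rn[sd_nc == 0], gn[sd_g == 0])
  keep_nc <- sd_nc > 0; keep_g <- sd_g > 0
  empty <- data.frame(ncrna_probe_id = character(),
                      gene_probe_id = character(),
                      gene_symbol = character(),
                      r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(keep_nc) || !any(keep_g)) {
    return(list(hits = empty, skipped = skipped))
  }
  r <- stats::cor(t(ncrna_mat[keep_nc, , drop = FALSE]),
                  t(gene_mat[keep_g, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tstat[abs(r) == 1] <- Inf * sign(r[abs(r) == 1])
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  hit <- abs(r) >= r_min & p < p_max
  ij <- which(hit, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(list(hits = empty, skipped = skipped))
  hits <- data.frame(
    ncrna_probe_id = rn[keep_nc][ij[, 1L]],
    gene_probe_id = gn[keep_g][ij[, 2L]],
    gene_symbol = gene_symbols[keep_g][ij[, 2L]],
    r = r[ij], p_value = p[ij],
    stringsAsFactors = FALSE)
  hits <- hits[order(-abs(hits$r)), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, skipped = skipped)
}
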