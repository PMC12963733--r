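#' Cis target genes by genomic window
#'
#' Pairs every lncRNA with every protein-coding gene on the same
#' chromosome whose span lies within `window` bp: overlapping spans have
#' distance 0, disjoint spans are separated by the coordinate gap between
#' the nearer span ends (`start2 - end1`), and the boundary is inclusive
#' (a gap of exactly `window` is retained). Strand is ignored.
#'
#' @param lncrnas,genes Tibbles with `transcript_id` (or `gene_id`),
#'   `chromosome`, `start`, `end` (1-based, inclusive).
#' @param window Window size in bp (default 100000).
#' @return Tibble: `lncrna_id`, `gene_id`, `mode = "cis"`, `distance` (bp).
#' @examples
#' l <- tibble::tibble(transcript_id = "lnc1", chromosome = "chr1",
#'                     start = 200000, end = 201000)
#' g <- tibble::tibble(transcript_id = "g1", chromosome = "chr1",
#'                     start = 99000, end = 100000)
#' cis_targets(l, g)$distance  # 100000, included at the boundary
#' @export
cis_targets <- function(lncrnas, genes, window = 100000) {
  id_of <- function(d) {
    if ("transcript_id" %in% names(d)) d$transcript_id else d$gene_id
  }
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  mode = character(), distance = double()))
  }
  gr <- function(d) {
    GenomicRanges::GRanges(
      seqnames = d$chromosome,
      ranges = IRanges::IRanges(start = d$start, end = d$end)
    )
  }
  gl <- gr(lncrnas); gg <- gr(genes)
  # findOverlaps maxgap counts intervening positions; our inclusive
  # coordinate gap start2 - end1 equals that plus one.
  hits <- GenomicRanges::findOverlaps(gl, gg, maxgap = max(0, window - 1),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  mode = character(), distance = double()))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap0 <- GenomicRanges::distance(gl[qi], gg[si])  # intervening bases
  dist <- ifelse(gap0 == 0 & overlapping_pairs(lncrnas[qi, ], genes[si, ]),
                 0, gap0 + 1)
  tibble(
    lncrna_id = id_of(lncrnas)[qi],
    gene_id = id_of(genes)[si],
    mode = "cis",
    distance = as.double(dist)
  ) |>
    dplyr::filter(.data$distance <= window) |>
    distinct() |>
    arrange(.data$lncrna_id, .data$gene_id)
}

overlapping_pairs <- function(a, b) {
  a$chromosome == b$chromosome & a$start <= b$end & b$start <= a$end
}

#' Trans target genes by expression correlation
#'
#' Screens every (lncRNA, gene) pair for strong co-expression: retained
#' iff `|r| > r_threshold` (strict) and `p < p_threshold`, with Pearson r
#' and the t-transform p-value computed across the shared samples.
#' Expression is log1p-transformed by default, the usual scale for
#' co-expression screening of RNA-seq abundances.
#'
#' @param lnc_expr,gene_expr Wide expression tibbles or matrices sharing
#'   identical sample columns (n >= 3).
#' @param r_threshold Absolute-correlation threshold (default 0.95).
#' @param p_threshold p-value threshold (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform Apply `log1p` before correlating (default TRUE).
#' @return Tibble: `lncrna_id`, `gene_id`, `mode = "trans"`, `r`,
#'   `p_value`. Pairs involving a constant vector are dropped.
#' @export
trans_targets <- function(lnc_expr, gene_expr, r_threshold = 0.95,
                          p_threshold = 0.05, method = "pearson",
                          log_transform = TRUE) {
  ml <- as_expr_matrix(lnc_expr, "lnc_expr")
  mg <- as_expr_matrix(gene_expr, "gene_expr")
  if (!setequal(colnames(ml), colnames(mg))) {
    abort("`lnc_expr` and `gene_expr` must cover the same samples.")
  }
  mg <- mg[, colnames(ml), drop = FALSE]
  if (log_transform) {
    ml <- log1p(ml); mg <- log1p(mg)
  }
  cm <- cor_matrix_with_p(ml, mg, method)
  idx <- which(!is.na(cm$r) & abs(cm$r) > r_threshold &
                 cm$p < p_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  mode = character(), r = double(), p_value = double()))
  }
  tibble(
    lncrna_id = rownames(cm$r)[idx[, 1]],
    gene_id = colnames(cm$r)[idx[, 2]],
    mode = "trans",
    r = cm$r[idx],
    p_value = cm$p[idx]
  ) |>
    arrange(.data$lncrna_id, .data$gene_id)
}
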