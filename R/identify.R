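#' Structural lncRNA filter
#'
#' Retains transcripts with at least two exons and a mature transcript
#' length (sum of exon lengths) strictly greater than 200 bp — the
#' standard structural definition of an lncRNA candidate. Row order is
#' preserved and the operation is idempotent.
#'
#' @param transcripts Transcript tibble with columns `n_exons` and
#'   `length` (as produced by [simulate_annotation()] or [read_gtf()]).
#' @param min_exons Minimum exon count (default 2).
#' @param min_length Length that must be strictly exceeded, bp (default 200).
#' @return The retained rows of `transcripts`.
#' @examples
#' tx <- tibble::tibble(transcript_id = c("a", "b"),
#'                      n_exons = c(1L, 3L), length = c(5000L, 250L))
#' filter_structural(tx)$transcript_id
#' @export
filter_structural <- function(transcripts, min_exons = 2L, min_length = 200L) {
  stopifnot(all(c("n_exons", "length") %in% names(transcripts)))
  dplyr::filter(transcripts,
                .data$n_exons >= min_exons, .data$length > min_length)
}

#' Consensus non-coding call across four tools
#'
#' A candidate survives only if all four coding-potential tools (CNCI,
#' CPC2, CPAT, PFAM) call it non-coding — the intersection rule. Every
#' candidate must carry a verdict from each tool.
#'
#' @param candidates Character vector of candidate transcript ids, or a
#'   tibble with a `transcript_id` column.
#' @param calls Long tibble of verdicts: `transcript_id`, `tool`,
#'   `verdict` (`"coding"` or `"noncoding"`).
#' @param tools Tool names that must all agree (default the four above).
#' @return Character vector of ids called non-coding by every tool, in
#'   candidate order.
#' @export
consensus_noncoding <- function(candidates, calls,
                                tools = c("CNCI", "CPC2", "CPAT", "PFAM")) {
  ids <- if (is.data.frame(candidates)) candidates$transcript_id else candidates
  if (length(ids) == 0) return(character(0))
  sub <- calls |>
    dplyr::filter(.data$transcript_id %in% ids, .data$tool %in% tools)
  got <- sub |> count(.data$transcript_id) |>
    dplyr::filter(.data$n == length(tools))
  missing <- setdiff(ids, got$transcript_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Incomplete coding-potential calls for %d candidate(s), e.g. %s.",
      length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  ok <- sub |>
    summarise(all_nc = all(.data$verdict == "noncoding"),
              .by = "transcript_id") |>
    dplyr::filter(.data$all_nc)
  ids[ids %in% ok$transcript_id]
}

#' Classify lncRNAs as known or novel
#'
#' Membership in a reference id list decides the split; the partition is
#' exhaustive and disjoint.
#'
#' @param lncrna_ids Character vector of identified lncRNA ids.
#' @param reference_ids Character vector of known lncRNA ids.
#' @return Tibble with columns `transcript_id`, `status`
#'   (`"known"`/`"novel"`).
#' @export
classify_novelty <- function(lncrna_ids, reference_ids = character(0)) {
  tibble(
    transcript_id = lncrna_ids,
    status = ifelse(lncrna_ids %in% reference_ids, "known", "novel")
  )
}

#' Identify lncRNAs from transcripts and coding-potential calls
#'
#' Convenience wrapper chaining [filter_structural()] and
#' [consensus_noncoding()], optionally labelling known vs novel.
#'
#' @inheritParams filter_structural
#' @inheritParams consensus_noncoding
#' @param reference_ids Optional known-lncRNA reference id list.
#' @return Tibble of retained transcripts with a `status` column.
#' @export
identify_lncrnas <- function(transcripts, calls,
                             reference_ids = character(0),
                             min_exons = 2L, min_length = 200L) {
  cand <- filter_structural(transcripts, min_exons, min_length)
  keep <- consensus_noncoding(cand$transcript_id, calls)
  cand |>
    dplyr::filter(.data$transcript_id %in% keep) |>
    left_join(classify_novelty(keep, reference_ids), by = "transcript_id")
}

#' Genomic characteristics per transcript class
#'
#' Computes, per class, the mean mature length, mean exon count and mean
#' and total ORF length, and (when expression is supplied) quartiles of
#' log1p-transformed expression — the descriptive panel usually shown to
#' contrast novel lncRNAs, known lncRNAs and mRNAs.
#'
#' @param transcripts Transcript tibble with `biotype` (or a `class`
#'   column), `length`, `n_exons`, `orf_length`.
#' @param expression Optional wide expression tibble/matrix (FPKM or
#'   counts) whose feature ids are a subset of the transcript ids.
#' @param classes Optional explicit class subset; requesting a class with
#'   no members is an error.
#' @return Tibble, one row per class present: `class`, `n`,
#'   `mean_length`, `mean_exons`, `mean_orf_length`, `total_orf_length`,
#'   and `expr_q25`/`expr_median`/`expr_q75` when expression is given.
#' @export
summarize_features <- function(transcripts, expression = NULL,
                               classes = NULL) {
  tx <- transcripts
  if (!"class" %in% names(tx)) {
    stopifnot("biotype" %in% names(tx))
    tx$class <- tx$biotype
  }
  if (!is.null(classes)) {
    absent <- setdiff(classes, unique(tx$class))
    if (length(absent) > 0) {
      abort(sprintf("Requested class(es) with no members: %s.",
                    paste(absent, collapse = ", ")))
    }
    tx <- dplyr::filter(tx, .data$class %in% classes)
  }
  out <- tx |>
    summarise(
      n = dplyr::n(),
      mean_length = mean(.data$length),
      mean_exons = mean(.data$n_exons),
      mean_orf_length = mean(.data$orf_length),
      total_orf_length = sum(.data$orf_length),
      .by = "class"
    )
  if (!is.null(expression)) {
    m <- as_expr_matrix(expression, "expression")
    if (!all(rownames(m) %in% tx$transcript_id)) {
      abort("Expression features must be a subset of transcript ids.")
    }
    lv <- log1p(rowMeans(m))
    eq <- tibble(transcript_id = rownames(m), expr = lv) |>
      left_join(select(tx, "transcript_id", "class"), by = "transcript_id") |>
      summarise(
        expr_q25 = quantile(.data$expr, 0.25),
        expr_median = median(.data$expr),
        expr_q75 = quantile(.data$expr, 0.75),
        .by = "class"
      )
    out <- left_join(out, eq, by = "class")
  }
  arrange(out, .data$class)
}
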