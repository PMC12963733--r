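#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` are marked, the probability of at least
#' `k` marked draws. This is the over-representation kernel shared by the
#' term-enrichment and shared-miRNA tests.
#'
#' @param N Universe size.
#' @param K Marked items in the universe.
#' @param n Draws.
#' @param k Observed marked draws.
#' @return Exact p-value in (0, 1]; `k = 0` gives 1.
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 4)  # 6/252
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) || K > N || n > N) {
    abort("Need 0 <= k <= min(K, n) <= N.")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation by the hypergeometric test
#'
#' For each term with at least one study hit, tests whether the study set
#' over-represents the term's genes against the background universe, and
#' assigns the two customary significance tiers (p < 0.05 significant,
#' p < 0.01 highly significant). p-values are raw by default; an optional
#' multiplicity correction is applied before tier assignment when
#' requested.
#'
#' @param study_genes Character vector; must be a subset of the background.
#' @param term_map Tibble with columns `term_id`, `gene_id`. Genes outside
#'   the background are dropped (count reported via the
#'   `n_dropped_genes` attribute, with a warning).
#' @param background_genes Universe; defaults to all genes in `term_map`.
#' @param tiers Two descending p cutoffs, default `c(0.05, 0.01)`.
#' @param correction A [stats::p.adjust()] method, default `"none"`.
#' @return Tibble sorted by p: `term_id`, `term_size`, `study_hits`,
#'   `study_size`, `background_size`, `p_value`, `tier`
#'   (`ns`/`significant`/`highly_significant`).
#' @export
enrich_terms <- function(study_genes, term_map, background_genes = NULL,
                         tiers = c(0.05, 0.01), correction = "none") {
  background_genes <- background_genes %||% unique(term_map$gene_id)
  if (length(study_genes) == 0) {
    return(tibble(term_id = character(), term_size = integer(),
                  study_hits = integer(), study_size = integer(),
                  background_size = integer(), p_value = double(),
                  tier = character()))
  }
  if (!all(study_genes %in% background_genes)) {
    abort("`study_genes` must be a subset of the background.")
  }
  n_all <- nrow(term_map)
  term_map <- dplyr::filter(term_map, .data$gene_id %in% background_genes)
  dropped <- n_all - nrow(term_map)
  if (dropped > 0) {
    warn(sprintf("Dropped %d term annotations outside the background.",
                 dropped))
  }
  study_genes <- unique(study_genes)
  N <- length(unique(background_genes))
  n <- length(study_genes)
  out <- term_map |>
    distinct(.data$term_id, .data$gene_id) |>
    summarise(
      term_size = dplyr::n(),
      study_hits = sum(.data$gene_id %in% study_genes),
      .by = "term_id"
    ) |>
    dplyr::filter(.data$study_hits > 0) |>
    mutate(
      study_size = n,
      background_size = N,
      p_value = purrr::map2_dbl(.data$term_size, .data$study_hits,
                                ~ hypergeom_upper_tail(N, .x, n, .y))
    )
  if (correction != "none") {
    out$p_value <- p.adjust(out$p_value, method = correction)
  }
  out |>
    mutate(tier = dplyr::case_when(
      .data$p_value < tiers[2] ~ "highly_significant",
      .data$p_value < tiers[1] ~ "significant",
      .default = "ns"
    )) |>
    arrange(.data$p_value, .data$term_id) |>
    structure(n_dropped_genes = dropped)
}
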