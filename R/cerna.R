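#' Shared-miRNA hypergeometric test
#'
#' Tests whether an lncRNA and an mRNA share more targeting miRNAs than
#' expected by chance: with a universe of `|universe|` miRNAs of which
#' `|lnc_mirna_set|` target the lncRNA, drawing the `|mrna_mirna_set|`
#' miRNAs that target the mRNA, the overlap `k` is referred to the
#' hypergeometric upper tail.
#'
#' @param lnc_mirna_set,mrna_mirna_set Character vectors of miRNA ids
#'   targeting the lncRNA / the mRNA; both subsets of `mirna_universe`.
#' @param mirna_universe Non-empty character vector of candidate miRNAs.
#' @return One-row tibble: `k` (shared miRNAs) and `p_value`.
#' @examples
#' shared_mirna_pvalue("mir-1", c("mir-1", "mir-2"), sprintf("mir-%d", 1:20))
#' @export
shared_mirna_pvalue <- function(lnc_mirna_set, mrna_mirna_set,
                                mirna_universe) {
  if (length(mirna_universe) == 0) abort("miRNA universe must be non-empty.")
  lnc_mirna_set <- unique(lnc_mirna_set)
  mrna_mirna_set <- unique(mrna_mirna_set)
  mirna_universe <- unique(mirna_universe)
  if (!all(c(lnc_mirna_set, mrna_mirna_set) %in% mirna_universe)) {
    abort("Both miRNA sets must be subsets of the universe.")
  }
  k <- length(intersect(lnc_mirna_set, mrna_mirna_set))
  tibble(k = k,
         p_value = hypergeom_upper_tail(length(mirna_universe),
                                        length(lnc_mirna_set),
                                        length(mrna_mirna_set), k))
}

#' ceRNA triad acceptance rule
#'
#' The decision kernel of the screen: a (lncRNA, miRNA, mRNA) triple is
#' accepted iff the miRNA is negatively correlated with both targets
#' (Spearman `<= scc_threshold` for each pair), the lncRNA and mRNA are
#' strongly positively correlated (Pearson strictly `> pcc_threshold`),
#' and the shared-miRNA hypergeometric p-value is `< hypergeom_threshold`.
#'
#' @param scc_lnc_mirna,scc_mrna_mirna Spearman correlations of the miRNA
#'   with the lncRNA / mRNA.
#' @param pcc_lnc_mrna Pearson correlation of lncRNA and mRNA.
#' @param hypergeom_p Shared-miRNA hypergeometric p-value.
#' @param scc_threshold,pcc_threshold,hypergeom_threshold The three
#'   cutoffs (defaults -0.7, 0.9, 0.05).
#' @return Logical (vectorized).
#' @examples
#' triad_passes(-0.8, -0.75, 0.95, 0.01)  # TRUE
#' triad_passes(-0.8, -0.75, 0.90, 0.01)  # FALSE: PCC must exceed 0.9
#' @export
triad_passes <- function(scc_lnc_mirna, scc_mrna_mirna, pcc_lnc_mrna,
                         hypergeom_p, scc_threshold = -0.7,
                         pcc_threshold = 0.9, hypergeom_threshold = 0.05) {
  !is.na(scc_lnc_mirna) & !is.na(scc_mrna_mirna) & !is.na(pcc_lnc_mrna) &
    scc_lnc_mirna <= scc_threshold &
    scc_mrna_mirna <= scc_threshold &
    pcc_lnc_mrna > pcc_threshold &
    hypergeom_p < hypergeom_threshold
}

#' Screen lncRNA-miRNA-mRNA triples into ceRNA triads
#'
#' Enumerates every triple in which one differentially expressed miRNA
#' has targeting links to both a differentially expressed lncRNA and a
#' differentially expressed mRNA, computes the pairwise correlation
#' statistics across the supplied samples and the shared-miRNA
#' hypergeometric p-value (universe: all DE miRNAs present in either
#' filtered interaction table), and keeps the triples accepted by
#' [triad_passes()].
#'
#' @param de_lncrnas,de_mirnas,de_mrnas Character vectors of
#'   differentially expressed feature ids (the comparison's DE calls).
#' @param interactions List with tibbles `mirna_lncrna` and `mirna_mrna`
#'   (`mirna_id`, `target_id`), as from [simulate_interactions()] or
#'   [read_interactions()].
#' @param expression A `cernet_expression` object, or a wide tibble /
#'   matrix containing all DE features.
#' @param sample_ids Optional sample subset to correlate over (e.g. the
#'   samples of one tissue comparison); default all columns.
#' @param scc_threshold,pcc_threshold,hypergeom_threshold Screen cutoffs.
#' @param log_transform Correlate on `log1p` expression (default TRUE;
#'   Spearman is unaffected, Pearson becomes a log-scale correlation).
#' @return Tibble of accepted triads, classed `cerna_triads`:
#'   `lncrna_id`, `mirna_id`, `mrna_id`, `scc_lnc_mirna`,
#'   `scc_mrna_mirna`, `pcc_lnc_mrna`, `shared_mirna_count`,
#'   `hypergeom_p`. The number of candidate triples is stored in the
#'   `n_candidates` attribute.
#' @export
build_triads <- function(de_lncrnas, de_mirnas, de_mrnas, interactions,
                         expression, sample_ids = NULL,
                         scc_threshold = -0.7, pcc_threshold = 0.9,
                         hypergeom_threshold = 0.05, log_transform = TRUE) {
  m <- combined_expression_matrix(expression)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(m))
    if (length(missing) > 0) {
      abort(sprintf("Samples absent from expression: %s.",
                    paste(head(missing, 3), collapse = ", ")))
    }
    m <- m[, sample_ids, drop = FALSE]
  }
  m2l <- interactions$mirna_lncrna |>
    dplyr::filter(.data$mirna_id %in% de_mirnas,
                  .data$target_id %in% de_lncrnas)
  m2m <- interactions$mirna_mrna |>
    dplyr::filter(.data$mirna_id %in% de_mirnas,
                  .data$target_id %in% de_mrnas)
  universe <- union(m2l$mirna_id, m2m$mirna_id)
  cand <- inner_join(rename(m2l, lncrna_id = "target_id"),
                     rename(m2m, mrna_id = "target_id"),
                     by = "mirna_id", relationship = "many-to-many")
  empty <- tibble(
    lncrna_id = character(), mirna_id = character(), mrna_id = character(),
    scc_lnc_mirna = double(), scc_mrna_mirna = double(),
    pcc_lnc_mrna = double(), shared_mirna_count = integer(),
    hypergeom_p = double()
  )
  if (nrow(cand) == 0) {
    return(structure(empty, class = c("cerna_triads", class(tibble())),
                     n_candidates = 0L))
  }
  feats <- unique(c(cand$lncrna_id, cand$mirna_id, cand$mrna_id))
  absent <- setdiff(feats, rownames(m))
  if (length(absent) > 0) {
    abort(sprintf("Features missing from expression: %s.",
                  paste(head(absent, 3), collapse = ", ")))
  }
  if (ncol(m) < 3) abort("Need >= 3 samples to correlate.")
  em <- m[feats, , drop = FALSE]
  if (log_transform) em <- log1p(em)
  # standardized value and rank rows; pairwise r is then a dot product
  zs <- standardize_rows(em)
  zr <- standardize_rows(t(apply(em, 1, rank)))
  rownames(zr) <- rownames(em)
  nn <- ncol(em) - 1
  pair_cor <- function(z, a, b) {
    unname(rowSums(z[a, , drop = FALSE] * z[b, , drop = FALSE]) / nn)
  }
  lnc_sets <- split(m2l$mirna_id, m2l$target_id)
  mrna_sets <- split(m2m$mirna_id, m2m$target_id)
  hyp <- cand |>
    distinct(.data$lncrna_id, .data$mrna_id) |>
    mutate(purrr::map2_dfr(.data$lncrna_id, .data$mrna_id, function(l, r) {
      shared_mirna_pvalue(lnc_sets[[l]], mrna_sets[[r]], universe)
    }))
  stats <- cand |>
    mutate(
      scc_lnc_mirna = pair_cor(zr, .data$lncrna_id, .data$mirna_id),
      scc_mrna_mirna = pair_cor(zr, .data$mrna_id, .data$mirna_id),
      pcc_lnc_mrna = pair_cor(zs, .data$lncrna_id, .data$mrna_id)
    ) |>
    left_join(hyp, by = c("lncrna_id", "mrna_id")) |>
    rename(shared_mirna_count = "k", hypergeom_p = "p_value")
  out <- stats |>
    dplyr::filter(triad_passes(
      .data$scc_lnc_mirna, .data$scc_mrna_mirna, .data$pcc_lnc_mrna,
      .data$hypergeom_p, scc_threshold, pcc_threshold, hypergeom_threshold
    )) |>
    select("lncrna_id", "mirna_id", "mrna_id", "scc_lnc_mirna",
           "scc_mrna_mirna", "pcc_lnc_mrna", "shared_mirna_count",
           "hypergeom_p") |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  structure(out, class = c("cerna_triads", class(tibble())),
            n_candidates = nrow(cand))
}

combined_expression_matrix <- function(expression) {
  if (inherits(expression, "cernet_expression")) {
    return(rbind(as_expr_matrix(expression$mrna),
                 as_expr_matrix(expression$lncrna),
                 as_expr_matrix(expression$mirna)))
  }
  as_expr_matrix(expression, "expression")
}

# rows scaled to mean 0, sd 1 (dividing by sd over n-1); constant rows
# become NaN and fail any correlation threshold downstream.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  cs <- m - mu
  s <- sqrt(rowSums(cs^2) / (ncol(m) - 1))
  cs / s
}

#' Assemble the ceRNA network from accepted triads
#'
#' Nodes are the union of triad members annotated with class and
#' differential-expression direction; edges are the two targeting links
#' of each triad (miRNA-lncRNA and miRNA-mRNA), deduplicated. No direct
#' lncRNA-mRNA edge is added: that relationship lives on the triad table.
#'
#' @param triads A [build_triads()] result.
#' @param de_direction_map Optional tibble (`feature_id`, `direction`) or
#'   named character vector giving each member's DE direction
#'   (`"up"`/`"down"`).
#' @param comparison Optional label recorded on the network.
#' @return List of class `cerna_network` with tibbles `nodes` (`id`,
#'   `class`, `regulation`) and `edges` (`source`, `interaction`,
#'   `target`), plus `comparison`.
#' @export
assemble_network <- function(triads, de_direction_map = NULL,
                             comparison = NA_character_) {
  dir_of <- function(ids) {
    if (is.null(de_direction_map)) return(rep(NA_character_, length(ids)))
    if (is.data.frame(de_direction_map)) {
      de_direction_map <- setNames(de_direction_map$direction,
                                   de_direction_map$feature_id)
    }
    unname(de_direction_map[ids])
  }
  nodes <- bind_rows(
    tibble(id = triads$lncrna_id, class = "lncRNA"),
    tibble(id = triads$mirna_id, class = "miRNA"),
    tibble(id = triads$mrna_id, class = "mRNA")
  ) |>
    distinct() |>
    mutate(regulation = dir_of(.data$id)) |>
    arrange(.data$class, .data$id)
  edges <- bind_rows(
    tibble(source = triads$mirna_id, interaction = "miRNA-lncRNA",
           target = triads$lncrna_id),
    tibble(source = triads$mirna_id, interaction = "miRNA-mRNA",
           target = triads$mrna_id)
  ) |>
    distinct() |>
    arrange(.data$interaction, .data$source, .data$target)
  structure(list(nodes = nodes, edges = edges, comparison = comparison),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes, %d edges", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.na(x$comparison)) cat(sprintf(" [%s]", x$comparison))
  cat("\n")
  invisible(x)
}

#' Summary statistics of a ceRNA network
#'
#' Node and edge counts, per-class composition split by regulation
#' direction, the full degree table, and the maximal-degree hub(s) of
#' each class (ties all reported).
#'
#' @param network A [assemble_network()] result.
#' @return List of class `cerna_network_stats`: `summary` (one-row
#'   tibble: `n_nodes`, `n_edges`), `classes` (`class`, `n`, `n_up`,
#'   `n_down`), `degree` (`id`, `class`, `degree`), `hubs`.
#' @export
network_stats <- function(network) {
  deg <- bind_rows(
    tibble(id = network$edges$source),
    tibble(id = network$edges$target)
  ) |>
    count(.data$id, name = "degree") |>
    right_join(network$nodes, by = "id") |>
    mutate(degree = tidyr::replace_na(.data$degree, 0L)) |>
    select("id", "class", "degree") |>
    arrange(desc(.data$degree), .data$id)
  classes <- network$nodes |>
    summarise(
      n = dplyr::n(),
      n_up = sum(.data$regulation == "up", na.rm = TRUE),
      n_down = sum(.data$regulation == "down", na.rm = TRUE),
      .by = "class"
    ) |>
    arrange(.data$class)
  hubs <- deg |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::slice_max(.data$degree, by = "class", with_ties = TRUE) |>
    arrange(.data$class, .data$id)
  structure(list(
    summary = tibble(n_nodes = nrow(network$nodes),
                     n_edges = nrow(network$edges)),
    classes = classes, degree = deg, hubs = hubs
  ), class = "cerna_network_stats")
}

#' @export
print.cerna_network_stats <- function(x, ...) {
  cat(sprintf("<cerna_network_stats> %d nodes, %d edges\n",
              x$summary$n_nodes, x$summary$n_edges))
  print(x$classes)
  invisible(x)
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes an edge table (`source`, `interaction`, `target`), a node
#' attribute table (`id`, `class`, `regulation`) and, for
#' `format = "sif"`, a SIF file. [read_network()] round-trips the TSV
#' export exactly.
#'
#' @param network A [assemble_network()] result.
#' @param dir Destination directory (created if needed).
#' @param format `"tsv"` (default) or `"sif"` (writes both).
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(network, dir, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", dir))
  }
  paths <- c(edges = file.path(dir, "edges.tsv"),
             nodes = file.path(dir, "nodes.tsv"))
  readr::write_tsv(network$edges, paths[["edges"]])
  readr::write_tsv(network$nodes, paths[["nodes"]])
  if (format == "sif") {
    sif <- file.path(dir, "network.sif")
    readr::write_delim(network$edges[, c("source", "interaction", "target")],
                       sif, delim = "\t", col_names = FALSE)
    paths <- c(paths, sif = sif)
  }
  invisible(paths)
}

#' Read back an exported ceRNA network
#'
#' @param dir Directory holding `edges.tsv` and `nodes.tsv` as written by
#'   [export_network()].
#' @param comparison Optional label to attach.
#' @return A `cerna_network` object.
#' @export
read_network <- function(dir, comparison = NA_character_) {
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           col_types = "ccc", progress = FALSE)
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"),
                           col_types = "ccc", progress = FALSE)
  structure(list(nodes = nodes, edges = edges, comparison = comparison),
            class = "cerna_network")
}
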