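#' Pipeline configuration
#'
#' Bundles every input path, threshold and the simulation block consumed
#' by [run_pipeline()]. All thresholds default to the study values:
#' differential expression p < 0.05 with |log2FC| >= 0.26, cis window
#' 100 kb, trans |r| > 0.95, ceRNA screen SCC <= -0.7, PCC > 0.9,
#' shared-miRNA hypergeometric p < 0.05, enrichment tiers 0.05 / 0.01.
#'
#' @param outdir Artifact directory.
#' @param seed Root seed; overrides the seed in `sim`.
#' @param sim A [sim_config()] block for the `simulate` stage.
#' @param comparisons Tibble of comparisons (`tissue`, `condition_a`,
#'   `condition_b`); defaults to laying vs broodiness in all three
#'   tissues.
#' @param lfc_threshold,p_threshold,lfc_boundary DE thresholds.
#' @param cis_window,trans_r,trans_p Target-assignment thresholds.
#' @param scc_threshold,pcc_threshold,hypergeom_threshold ceRNA screen
#'   thresholds.
#' @param enrichment_tiers Two descending p cutoffs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "cernet-run",
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            comparisons = NULL,
                            lfc_threshold = 0.26,
                            p_threshold = 0.05,
                            lfc_boundary = "ge",
                            cis_window = 100000,
                            trans_r = 0.95,
                            trans_p = 0.05,
                            scc_threshold = -0.7,
                            pcc_threshold = 0.9,
                            hypergeom_threshold = 0.05,
                            enrichment_tiers = c(0.05, 0.01)) {
  sim$seed <- as.integer(seed)
  comparisons <- comparisons %||% tibble(
    tissue = c("hypothalamus", "pituitary", "ovary"),
    condition_a = "laying", condition_b = "broodiness"
  )
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), sim = sim,
    comparisons = comparisons,
    lfc_threshold = lfc_threshold, p_threshold = p_threshold,
    lfc_boundary = lfc_boundary,
    cis_window = cis_window, trans_r = trans_r, trans_p = trans_p,
    scc_threshold = scc_threshold, pcc_threshold = pcc_threshold,
    hypergeom_threshold = hypergeom_threshold,
    enrichment_tiers = enrichment_tiers
  )
  thr <- c(cfg$lfc_threshold, cfg$p_threshold, cfg$cis_window, cfg$trans_r,
           cfg$trans_p, cfg$hypergeom_threshold, cfg$enrichment_tiers)
  if (any(thr <= 0)) abort("Thresholds must be positive.")
  if (cfg$trans_r > 1 || cfg$pcc_threshold > 1 || cfg$scc_threshold < -1) {
    abort("Correlation thresholds must lie in [-1, 1].")
  }
  validate_sim_config(sim)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- c("simulate", "identify", "de", "targets", "enrich",
                     "cerna")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> identify -> de -> targets -> enrich -> cerna), reading
#' and writing plain-text artifacts under `config$outdir` and recording a
#' manifest (`manifest.json`) with the configuration hash, seed, stage
#' list and per-file row counts. Re-running with an identical
#' configuration reproduces every artifact byte for byte. Progress and
#' timings go to stderr; nothing is printed to stdout.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the six stages (default all).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")
  res_dir <- file.path(out, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  need <- function(stage, paths) {
    miss <- paths[!file.exists(paths)]
    if (length(miss) > 0) {
      abort(sprintf(
        "Stage '%s' is missing upstream artifact(s): %s. Run the earlier stages first.",
        stage, paste(basename(miss), collapse = ", ")))
    }
  }
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    files <- fn()
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[cernet] stage %-8s %5.1fs  %d file(s)", name, dt,
                    length(files)))
    written <<- c(written, files)
  }

  data_files <- function() {
    file.path(data_dir, c(
      "annotation.gtf", "mrna_counts.tsv", "lncrna_counts.tsv",
      "mirna_counts.tsv", "samples.tsv", "coding_calls.tsv",
      "mirna_lncrna_interactions.tsv", "mirna_mrna_interactions.tsv"))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    ds <- simulate_dataset(config$sim)
    p <- write_dataset(ds, data_dir)
    tm_path <- file.path(data_dir, "term_map.tsv")
    tm <- simulate_term_map(
      ds$annotation$transcripts$transcript_id[
        ds$annotation$transcripts$biotype == "mRNA"],
      seed = config$seed)
    readr::write_tsv(tm, tm_path)
    c(unname(p), tm_path)
  })

  if ("identify" %in% stages) run_stage("identify", function() {
    need("identify", c(file.path(data_dir, "annotation.gtf"),
                       file.path(data_dir, "coding_calls.tsv")))
    tx <- read_gtf(file.path(data_dir, "annotation.gtf"))
    calls <- read_coding_calls(file.path(data_dir, "coding_calls.tsv"))
    lnc <- identify_lncrnas(tx, calls)
    f1 <- file.path(res_dir, "lncrna_ids.tsv")
    readr::write_tsv(select(lnc, "transcript_id", "status"), f1)
    counts <- bind_rows(
      read_expression(file.path(data_dir, "mrna_counts.tsv")),
      read_expression(file.path(data_dir, "lncrna_counts.tsv")))
    fpkm <- compute_fpkm(counts, setNames(tx$length, tx$transcript_id))
    summ <- summarize_features(tx, fpkm)
    f2 <- file.path(res_dir, "features_summary.tsv")
    readr::write_tsv(summ, f2)
    c(f1, f2)
  })

  de_path <- function(class, tissue) {
    file.path(res_dir, sprintf("de_%s_%s.tsv", class, tissue))
  }

  if ("de" %in% stages) run_stage("de", function() {
    need("de", data_files()[2:5])
    samples <- readr::read_tsv(file.path(data_dir, "samples.tsv"),
                               col_types = "ccci", progress = FALSE)
    files <- character(0)
    for (class in c("mrna", "lncrna", "mirna")) {
      counts <- read_expression(file.path(data_dir,
                                          paste0(class, "_counts.tsv")))
      for (i in seq_len(nrow(config$comparisons))) {
        cmp <- config$comparisons[i, ]
        res <- de_test(counts, samples, cmp$condition_a, cmp$condition_b,
                       tissue = cmp$tissue) |>
          call_de(config$lfc_threshold, config$p_threshold,
                  config$lfc_boundary)
        f <- de_path(class, cmp$tissue)
        readr::write_tsv(res, f)
        files <- c(files, f)
      }
    }
    files
  })

  if ("targets" %in% stages) run_stage("targets", function() {
    need("targets", c(file.path(data_dir, "annotation.gtf"),
                      file.path(res_dir, "lncrna_ids.tsv"),
                      de_path("lncrna", config$comparisons$tissue)))
    tx <- read_gtf(file.path(data_dir, "annotation.gtf"))
    lnc_ids <- readr::read_tsv(file.path(res_dir, "lncrna_ids.tsv"),
                               col_types = "cc", progress = FALSE)
    genes <- dplyr::filter(tx, .data$biotype == "mRNA")
    samples <- readr::read_tsv(file.path(data_dir, "samples.tsv"),
                               col_types = "ccci", progress = FALSE)
    lnc_counts <- read_expression(file.path(data_dir, "lncrna_counts.tsv"))
    mrna_counts <- read_expression(file.path(data_dir, "mrna_counts.tsv"))
    files <- character(0)
    for (i in seq_len(nrow(config$comparisons))) {
      tis <- config$comparisons$tissue[i]
      de_lnc <- readr::read_tsv(de_path("lncrna", tis),
                                col_types = readr::cols(), progress = FALSE)
      de_set <- intersect(de_lnc$feature_id[de_lnc$significant],
                          lnc_ids$transcript_id)
      lnc_tx <- dplyr::filter(tx, .data$transcript_id %in% de_set)
      cis <- cis_targets(lnc_tx, genes, config$cis_window)
      sel <- samples$sample_id[samples$tissue == tis]
      le <- as_expr_matrix(lnc_counts)[de_set, sel, drop = FALSE]
      ge <- as_expr_matrix(mrna_counts)[, sel, drop = FALSE]
      trans <- if (length(de_set) > 0) {
        trans_targets(le, ge, config$trans_r, config$trans_p)
      } else {
        trans_targets(matrix(0, 0, length(sel),
                             dimnames = list(NULL, sel)), ge,
                      config$trans_r, config$trans_p)
      }
      f <- file.path(res_dir, sprintf("targets_%s.tsv", tis))
      readr::write_tsv(bind_rows(cis, trans), f)
      files <- c(files, f)
    }
    files
  })

  if ("enrich" %in% stages) run_stage("enrich", function() {
    need("enrich", c(file.path(data_dir, "term_map.tsv"),
                     file.path(res_dir, sprintf("targets_%s.tsv",
                                                config$comparisons$tissue))))
    tm <- read_term_map(file.path(data_dir, "term_map.tsv"))
    files <- character(0)
    for (tis in config$comparisons$tissue) {
      tg <- readr::read_tsv(file.path(res_dir,
                                      sprintf("targets_%s.tsv", tis)),
                            col_types = readr::cols(), progress = FALSE)
      study <- intersect(unique(tg$gene_id[tg$mode == "cis"]),
                         unique(tm$gene_id))
      enr <- enrich_terms(study, tm, tiers = config$enrichment_tiers)
      f <- file.path(res_dir, sprintf("enrichment_%s.tsv", tis))
      readr::write_tsv(enr, f)
      files <- c(files, f)
    }
    files
  })

  if ("cerna" %in% stages) run_stage("cerna", function() {
    need("cerna", c(
      data_files()[c(2:5, 7, 8)],
      de_path("lncrna", config$comparisons$tissue),
      de_path("mrna", config$comparisons$tissue),
      de_path("mirna", config$comparisons$tissue)))
    samples <- readr::read_tsv(file.path(data_dir, "samples.tsv"),
                               col_types = "ccci", progress = FALSE)
    expr <- rbind(
      as_expr_matrix(read_expression(file.path(data_dir, "mrna_counts.tsv"))),
      as_expr_matrix(read_expression(file.path(data_dir, "lncrna_counts.tsv"))),
      as_expr_matrix(read_expression(file.path(data_dir, "mirna_counts.tsv"))))
    inter <- list(
      mirna_lncrna = read_interactions(
        file.path(data_dir, "mirna_lncrna_interactions.tsv")),
      mirna_mrna = read_interactions(
        file.path(data_dir, "mirna_mrna_interactions.tsv")))
    files <- character(0)
    for (tis in config$comparisons$tissue) {
      de_of <- function(class) {
        readr::read_tsv(de_path(class, tis), col_types = readr::cols(),
                        progress = FALSE)
      }
      de_l <- de_of("lncrna"); de_r <- de_of("mrna"); de_m <- de_of("mirna")
      sel <- samples$sample_id[samples$tissue == tis]
      triads <- build_triads(
        de_l$feature_id[de_l$significant],
        de_m$feature_id[de_m$significant],
        de_r$feature_id[de_r$significant],
        inter, expr, sample_ids = sel,
        scc_threshold = config$scc_threshold,
        pcc_threshold = config$pcc_threshold,
        hypergeom_threshold = config$hypergeom_threshold)
      f1 <- file.path(res_dir, sprintf("triads_%s.tsv", tis))
      readr::write_tsv(triads, f1)
      dir_map <- bind_rows(de_l, de_r, de_m) |>
        select("feature_id", "direction")
      net <- assemble_network(triads, dir_map, comparison = tis)
      net_dir <- file.path(res_dir, sprintf("network_%s", tis))
      p <- export_network(net, net_dir, format = "sif")
      st <- network_stats(net)
      f2 <- file.path(res_dir, sprintf("network_stats_%s.tsv", tis))
      readr::write_tsv(
        mutate(st$classes, n_nodes = st$summary$n_nodes,
               n_edges = st$summary$n_edges), f2)
      files <- c(files, f1, unname(p), f2)
    }
    files
  })

  manifest <- list(
    config_hash = rlang::hash(unclass(config)[
      setdiff(names(config), "outdir")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cernet")),
    stages = stages,
    files = lapply(
      setNames(written, sub(paste0("^", out, "/?"), "", written)),
      function(f) list(rows = count_data_rows(f))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# rows excluding a header line for tabular text; raw line count otherwise
count_data_rows <- function(path) {
  n <- length(readr::read_lines(path, progress = FALSE))
  if (grepl("\\.(tsv|gtf|sif)$", path)) {
    if (grepl("\\.tsv$", path)) max(0L, n - 1L) else n
  } else {
    n
  }
}
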