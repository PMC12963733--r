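#' Simulate a transcript annotation
#'
#' Draws mRNA and lncRNA transcript models on a synthetic genome. Mature
#' transcript length (the sum of exon lengths) and exon count are drawn
#' from the class-specific ranges in the configuration; introns are drawn
#' uniformly between 100 and 2000 bp, and each transcript is placed
#' uniformly on a random chromosome. mRNAs carry a substantial open
#' reading frame (ORF), lncRNAs a short one (both recorded in
#' nucleotides).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cernet_annotation` with elements
#'   `transcripts` (tibble: `transcript_id`, `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`, `biotype`, `n_exons`, `length`,
#'   `orf_length`, and an `exons` list-column of start/end tibbles) and
#'   `chrom_sizes` (tibble: `chromosome`, `length`).
#' @examples
#' ann <- simulate_annotation(sim_config(seed = 1, n_mrna = 5, n_lncrna = 3,
#'                                       n_mirna = 2, n_planted_triads = 0))
#' ann$transcripts$biotype
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  chrom_sizes <- tibble(
    chromosome = sprintf("chr%d", seq_len(config$n_chromosomes)),
    length = config$chromosome_length
  )
  n_total <- config$n_mrna + config$n_lncrna
  if (n_total == 0) {
    return(structure(
      list(transcripts = empty_transcripts(), chrom_sizes = chrom_sizes),
      class = "cernet_annotation"))
  }
  if (config$n_chromosomes == 0) {
    abort("Cannot place transcripts: `n_chromosomes` is 0.")
  }
  withr::with_seed(child_seed(config$seed, "annotation"), {
    mk <- function(n, prefix, len_range, exon_range, biotype) {
      if (n == 0) return(empty_transcripts())
      purrr::map_dfr(seq_len(n), function(i) {
        len <- sample(seq(len_range[1], len_range[2]), 1)
        k <- sample(seq(exon_range[1], exon_range[2]), 1)
        exon_len <- split_length(len, k)
        introns <- if (k > 1) sample(100:2000, k - 1, replace = TRUE) else integer(0)
        span <- len + sum(introns)
        if (span > config$chromosome_length) {
          abort(sprintf(
            "Chromosome length %g bp too short for a transcript span of %d bp.",
            config$chromosome_length, span))
        }
        chrom <- sample(chrom_sizes$chromosome, 1)
        start <- sample.int(as.integer(config$chromosome_length - span + 1), 1)
        exon_start <- start + cumsum(c(0L, exon_len[-k] + introns))
        exon_end <- exon_start + exon_len - 1L
        orf <- if (biotype == "mRNA") {
          max(150L, as.integer(round(runif(1, 0.3, 0.8) * len)))
        } else {
          sample(0:90, 1)
        }
        tibble(
          transcript_id = sprintf("%s%04d", prefix, i),
          gene_id = sprintf("gene-%s%04d", prefix, i),
          chromosome = chrom,
          strand = sample(c("+", "-"), 1),
          start = start,
          end = exon_end[k],
          biotype = biotype,
          n_exons = k,
          length = len,
          orf_length = orf,
          exons = list(tibble(start = exon_start, end = exon_end))
        )
      })
    }
    transcripts <- bind_rows(
      mk(config$n_mrna, "MRNA", config$mrna_length_range,
         config$mrna_exon_range, "mRNA"),
      mk(config$n_lncrna, "LNC", config$lncrna_length_range,
         config$lncrna_exon_range, "lncRNA")
    )
  })
  structure(list(transcripts = transcripts, chrom_sizes = chrom_sizes),
            class = "cernet_annotation")
}

empty_transcripts <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    chromosome = character(), strand = character(),
    start = integer(), end = integer(), biotype = character(),
    n_exons = integer(), length = integer(), orf_length = integer(),
    exons = list()
  )
}

# Integer composition of `total` into `k` parts, each >= 30 bp where
# possible, summing exactly to `total`.
split_length <- function(total, k) {
  if (k == 1) return(as.integer(total))
  m <- min(30L, total %/% k)
  free <- total - k * m
  w <- runif(k)
  raw <- floor(w / sum(w) * free)
  rem <- free - sum(raw)
  raw[seq_len(rem)] <- raw[seq_len(rem)] + 1
  as.integer(m + raw)
}

#' @export
print.cernet_annotation <- function(x, ...) {
  n <- table(factor(x$transcripts$biotype, levels = c("mRNA", "lncRNA")))
  cat(sprintf("<cernet_annotation> %d mRNA, %d lncRNA on %d chromosomes\n",
              n[["mRNA"]], n[["lncRNA"]], nrow(x$chrom_sizes)))
  invisible(x)
}

mirna_feature_ids <- function(config) {
  sprintf("mir-%04d", seq_len(config$n_mirna))
}

#' Plant ceRNA triads
#'
#' Selects disjoint (lncRNA, miRNA, mRNA) triples to act as ground-truth
#' competing endogenous RNA triads: each triad shares one latent factor in
#' the expression model and both of its targeting links are guaranteed to
#' appear in the simulated interaction tables.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param config A [sim_config()] object.
#' @return Tibble with `triad_id`, `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `latent_loading`, `direction` (the sign of the planted condition
#'   shift for the lncRNA/mRNA; the miRNA takes the opposite sign).
#' @export
plant_triads <- function(annotation, config) {
  validate_sim_config(config)
  tx <- annotation$transcripts
  lnc <- tx$transcript_id[tx$biotype == "lncRNA"]
  mrna <- tx$transcript_id[tx$biotype == "mRNA"]
  mir <- mirna_feature_ids(config)
  k <- config$n_planted_triads
  if (k > min(length(lnc), length(mrna), length(mir))) {
    abort("Not enough features of every class to plant the requested triads.")
  }
  if (k == 0) {
    return(tibble(triad_id = character(), lncrna_id = character(),
                  mirna_id = character(), mrna_id = character(),
                  latent_loading = double(), direction = integer()))
  }
  withr::with_seed(child_seed(config$seed, "triads"), {
    tibble(
      triad_id = sprintf("triad-%03d", seq_len(k)),
      lncrna_id = sample(lnc, k),
      mirna_id = sample(mir, k),
      mrna_id = sample(mrna, k),
      latent_loading = config$coupling_beta,
      direction = sample(c(-1L, 1L), k, replace = TRUE)
    )
  })
}

#' Simulate expression counts with planted ceRNA structure
#'
#' Draws negative-binomial counts for mRNAs, lncRNAs and miRNAs over a
#' 3-tissue x 2-condition x replicate design. Each feature has a constant
#' baseline natural-log mean; members of a planted triad additionally load
#' on a per-sample standard-normal latent factor `z_s` with loading
#' `+beta` (lncRNA, mRNA) or `-beta` (miRNA), which forces the
#' miRNA-vs-target anti-correlation and the lncRNA-mRNA co-expression that
#' the ceRNA screen tests. A condition effect of `+/- delta/2` log2 units
#' is applied to every triad member (coherently signed) and to a random
#' `de_fraction` of the remaining features, so differential-expression
#' truth exists and is orthogonal to the coupling.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param config A [sim_config()] object.
#' @param triads Planted triads from [plant_triads()] (may be empty).
#' @return List of class `cernet_expression`: `mrna`, `lncrna`, `mirna`
#'   (wide count tibbles, first column `feature_id`), `samples` (tibble:
#'   `sample_id`, `tissue`, `condition`, `replicate`) and `truth` (tibble:
#'   `feature_id`, `class`, `triad_id`, `triad_role`, `true_log2fc`,
#'   `baseline_log_mean`; `true_log2fc` is broodiness over laying).
#' @export
simulate_expression <- function(annotation, config, triads = NULL) {
  validate_sim_config(config)
  if (config$nb_dispersion_phi < 0) abort("`nb_dispersion_phi` must be >= 0.")
  tx <- annotation$transcripts
  triads <- triads %||% plant_triads(annotation, config)
  feats <- bind_rows(
    tibble(feature_id = tx$transcript_id[tx$biotype == "mRNA"], class = "mRNA"),
    tibble(feature_id = tx$transcript_id[tx$biotype == "lncRNA"], class = "lncRNA"),
    tibble(feature_id = mirna_feature_ids(config), class = "miRNA")
  )
  bad <- setdiff(c(triads$lncrna_id, triads$mirna_id, triads$mrna_id),
                 feats$feature_id)
  if (length(bad) > 0) {
    abort(sprintf("Planted triads reference unknown features: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  samples <- sample_sheet(config)
  n_s <- nrow(samples)
  n_f <- nrow(feats)
  phi <- config$nb_dispersion_phi
  ln2 <- log(2)

  withr::with_seed(child_seed(config$seed, "expression"), {
    a <- runif(n_f, config$baseline_log_mean_range[1],
               config$baseline_log_mean_range[2])
    # latent factors: one row per triad, one column per sample
    z <- if (nrow(triads) > 0) {
      matrix(rnorm(nrow(triads) * n_s), nrow = nrow(triads))
    } else {
      matrix(0, nrow = 0, ncol = n_s)
    }
    # triad membership and loading sign per feature
    load_sign <- numeric(n_f)
    triad_row <- rep(NA_integer_, n_f)
    triad_role <- rep(NA_character_, n_f)
    shift_sign <- integer(n_f)
    if (nrow(triads) > 0) {
      for (t in seq_len(nrow(triads))) {
        i_l <- match(triads$lncrna_id[t], feats$feature_id)
        i_m <- match(triads$mirna_id[t], feats$feature_id)
        i_r <- match(triads$mrna_id[t], feats$feature_id)
        load_sign[c(i_l, i_r)] <- 1
        load_sign[i_m] <- -1
        triad_row[c(i_l, i_m, i_r)] <- t
        triad_role[c(i_l, i_m, i_r)] <- c("lncRNA", "miRNA", "mRNA")
        shift_sign[c(i_l, i_r)] <- triads$direction[t]
        shift_sign[i_m] <- -triads$direction[t]
      }
    }
    free <- which(is.na(triad_row))
    hit <- free[runif(length(free)) < config$de_fraction]
    shift_sign[hit] <- sample(c(-1L, 1L), length(hit), replace = TRUE)

    cond_sign <- ifelse(samples$condition == "broodiness", 1, -1)
    logmu <- matrix(a, nrow = n_f, ncol = n_s)
    for (i in seq_len(n_f)) {
      if (!is.na(triad_row[i])) {
        logmu[i, ] <- logmu[i, ] +
          load_sign[i] * config$coupling_beta * z[triad_row[i], ]
      }
      if (shift_sign[i] != 0) {
        logmu[i, ] <- logmu[i, ] +
          shift_sign[i] * (config$condition_shift_delta / 2) * ln2 * cond_sign
      }
    }
    mu <- exp(logmu)
    counts <- if (phi == 0) {
      matrix(rpois(n_f * n_s, lambda = mu), nrow = n_f)
    } else {
      matrix(rnbinom(n_f * n_s, mu = mu, size = 1 / phi), nrow = n_f)
    }
    dimnames(counts) <- list(feats$feature_id, samples$sample_id)
  })

  truth <- feats |>
    mutate(
      triad_id = ifelse(is.na(triad_row), NA_character_,
                        triads$triad_id[triad_row]),
      triad_role = triad_role,
      true_log2fc = shift_sign * config$condition_shift_delta,
      baseline_log_mean = a
    )
  out <- list(
    mrna = expr_tibble(counts[feats$class == "mRNA", , drop = FALSE]),
    lncrna = expr_tibble(counts[feats$class == "lncRNA", , drop = FALSE]),
    mirna = expr_tibble(counts[feats$class == "miRNA", , drop = FALSE]),
    samples = samples,
    truth = truth
  )
  class(out) <- "cernet_expression"
  out
}

sample_sheet <- function(config) {
  tissues <- c(hypothalamus = "H", pituitary = "P", ovary = "O")
  conditions <- c(laying = "L", broodiness = "B")
  tidyr::expand_grid(
    tissue = names(tissues),
    condition = names(conditions),
    replicate = seq_len(config$n_replicates_per_condition)
  ) |>
    mutate(sample_id = paste0(conditions[.data$condition],
                              tissues[.data$tissue], .data$replicate)) |>
    select("sample_id", "tissue", "condition", "replicate")
}

#' @export
print.cernet_expression <- function(x, ...) {
  cat(sprintf(
    "<cernet_expression> %d mRNA, %d lncRNA, %d miRNA features x %d samples\n",
    nrow(x$mrna), nrow(x$lncrna), nrow(x$mirna), nrow(x$samples)))
  invisible(x)
}

#' Simulate coding-potential verdicts
#'
#' Emulates the four coding-potential assessment tools (CNCI, CPC2, CPAT,
#' PFAM) as independent noisy readouts of the true biotype: each tool
#' reports `coding` for an mRNA and `noncoding` for an lncRNA with
#' probability `1 - coding_call_flip_rate`, and the opposite verdict
#' otherwise, independently across tools and transcripts.
#'
#' @inheritParams plant_triads
#' @return Tibble with columns `transcript_id`, `tool`, `verdict`
#'   (long format; four rows per transcript).
#' @export
simulate_coding_calls <- function(annotation, config) {
  validate_sim_config(config)
  tx <- annotation$transcripts
  tools <- c("CNCI", "CPC2", "CPAT", "PFAM")
  if (nrow(tx) == 0) {
    return(tibble(transcript_id = character(), tool = character(),
                  verdict = character()))
  }
  truth <- ifelse(tx$biotype == "mRNA", "coding", "noncoding")
  withr::with_seed(child_seed(config$seed, "coding"), {
    tidyr::expand_grid(transcript_id = tx$transcript_id, tool = tools) |>
      mutate(
        truth = rep(truth, each = length(tools)),
        flip = runif(dplyr::n()) < config$coding_call_flip_rate,
        verdict = ifelse(.data$flip == (.data$truth == "coding"),
                         "noncoding", "coding")
      ) |>
      select("transcript_id", "tool", "verdict")
  })
}

#' Simulate miRNA-target interaction tables
#'
#' Builds the two targeting tables the ceRNA screen consumes. Every
#' planted triad contributes its miRNA-to-lncRNA and miRNA-to-mRNA link;
#' every other (miRNA, target) pair is included independently with
#' probability `background_interaction_rate`.
#'
#' @inheritParams plant_triads
#' @param triads Planted triads from [plant_triads()].
#' @return List with tibbles `mirna_lncrna` and `mirna_mrna`, each with
#'   columns `mirna_id`, `target_id`.
#' @export
simulate_interactions <- function(annotation, triads, config) {
  validate_sim_config(config)
  tx <- annotation$transcripts
  mir <- mirna_feature_ids(config)
  draw <- function(targets, planted) {
    grid <- tidyr::expand_grid(mirna_id = mir, target_id = targets)
    keep <- runif(nrow(grid)) < config$background_interaction_rate
    if (nrow(planted) > 0) {
      keep <- keep | (paste(grid$mirna_id, grid$target_id) %in%
                        paste(planted$mirna_id, planted$target_id))
    }
    grid[keep, ]
  }
  withr::with_seed(child_seed(config$seed, "interactions"), {
    list(
      mirna_lncrna = draw(
        tx$transcript_id[tx$biotype == "lncRNA"],
        tibble(mirna_id = triads$mirna_id, target_id = triads$lncrna_id)),
      mirna_mrna = draw(
        tx$transcript_id[tx$biotype == "mRNA"],
        tibble(mirna_id = triads$mirna_id, target_id = triads$mrna_id))
    )
  })
}

#' Simulate a term-to-gene annotation map
#'
#' Utility for exercising the enrichment stage without external GO/KEGG
#' downloads: assigns genes to `n_terms` synthetic terms by sampling
#' without replacement per term.
#'
#' @param gene_ids Character vector of gene identifiers (the background).
#' @param n_terms Number of terms.
#' @param term_size_range Genes per term (pair).
#' @param seed Integer seed.
#' @return Tibble with columns `term_id`, `gene_id`.
#' @export
simulate_term_map <- function(gene_ids, n_terms = 20,
                              term_size_range = c(5, 25), seed = 1L) {
  withr::with_seed(child_seed(seed, "terms"), {
    purrr::map_dfr(seq_len(n_terms), function(i) {
      k <- sample(seq(term_size_range[1],
                      min(term_size_range[2], length(gene_ids))), 1)
      tibble(term_id = sprintf("TERM:%04d", i),
             gene_id = sample(gene_ids, k))
    })
  })
}

#' Simulate a complete study dataset
#'
#' Runs every generator under one root seed and returns all components.
#'
#' @param config A [sim_config()] object.
#' @return List of class `cernet_dataset`: `config`, `annotation`,
#'   `triads`, `expression`, `coding_calls`, `interactions`.
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 1, n_mrna = 30, n_lncrna = 15,
#'                                   n_mirna = 10, n_planted_triads = 3))
#' ds$triads
#' @export
simulate_dataset <- function(config) {
  annotation <- simulate_annotation(config)
  triads <- plant_triads(annotation, config)
  structure(list(
    config = config,
    annotation = annotation,
    triads = triads,
    expression = simulate_expression(annotation, config, triads),
    coding_calls = simulate_coding_calls(annotation, config),
    interactions = simulate_interactions(annotation, triads, config)
  ), class = "cernet_dataset")
}

#' @export
print.cernet_dataset <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d planted triads; %d + %d interaction links\n",
              nrow(x$triads), nrow(x$interactions$mirna_lncrna),
              nrow(x$interactions$mirna_mrna)))
  invisible(x)
}
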