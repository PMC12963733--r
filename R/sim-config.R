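#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' synthetic-data generators. The simulated design mirrors a two-condition
#' (laying vs broodiness), three-tissue (hypothalamus, pituitary, ovary)
#' RNA-seq study with a configurable number of replicates per
#' tissue-condition cell. Counts are negative binomial with variance
#' `mean + phi * mean^2`; planted ceRNA triads couple one lncRNA, one miRNA
#' and one mRNA through a shared per-sample latent factor so that the
#' miRNA is anti-correlated with both targets while the lncRNA and mRNA
#' are positively correlated.
#'
#' @param seed Integer root seed; every generator derives its own child
#'   seed from it, so stages are independently reproducible.
#' @param n_chromosomes,chromosome_length Genome layout; lengths in bp.
#' @param n_mrna,n_lncrna,n_mirna Number of features of each class.
#' @param n_replicates_per_condition Replicates per tissue x condition
#'   cell (3 at study scale).
#' @param n_planted_triads Number of planted (lncRNA, miRNA, mRNA) triads;
#'   features belong to at most one triad.
#' @param coupling_beta Latent-factor loading on the natural-log mean.
#' @param condition_shift_delta Condition effect in log2 units; shifted
#'   features move by `+/- delta/2` per condition so the between-condition
#'   log2 fold change equals `delta`.
#' @param de_fraction Fraction of non-triad features (per class) that
#'   receive the condition shift; triad members always receive it, with
#'   coherent signs (lncRNA and mRNA together, miRNA opposite).
#' @param nb_dispersion_phi NB dispersion `phi >= 0`; `phi = 0` degenerates
#'   to Poisson.
#' @param baseline_log_mean_range Natural-log range the per-feature
#'   baseline mean is drawn from.
#' @param background_interaction_rate Probability that a non-planted
#'   (miRNA, target) pair appears in the interaction tables.
#' @param coding_call_flip_rate Per-tool probability that a coding-potential
#'   verdict contradicts the true biotype.
#' @param lncrna_length_range,mrna_length_range Mature (summed-exon)
#'   transcript length ranges, bp.
#' @param lncrna_exon_range,mrna_exon_range Exon-count ranges.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_mrna = 50, n_lncrna = 20, n_mirna = 10,
#'                   n_planted_triads = 5)
#' cfg$n_mrna
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       chromosome_length = 5e6,
                       n_mrna = 300L,
                       n_lncrna = 150L,
                       n_mirna = 150L,
                       n_replicates_per_condition = 3L,
                       n_planted_triads = 50L,
                       coupling_beta = 1.5,
                       condition_shift_delta = 2,
                       de_fraction = 0.1,
                       nb_dispersion_phi = 0.1,
                       baseline_log_mean_range = c(log(20), log(500)),
                       background_interaction_rate = 0.02,
                       coding_call_flip_rate = 0.1,
                       lncrna_length_range = c(300L, 5000L),
                       mrna_length_range = c(500L, 9000L),
                       lncrna_exon_range = c(2L, 5L),
                       mrna_exon_range = c(4L, 16L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    n_mrna = as.integer(n_mrna),
    n_lncrna = as.integer(n_lncrna),
    n_mirna = as.integer(n_mirna),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    n_planted_triads = as.integer(n_planted_triads),
    coupling_beta = as.numeric(coupling_beta),
    condition_shift_delta = as.numeric(condition_shift_delta),
    de_fraction = as.numeric(de_fraction),
    nb_dispersion_phi = as.numeric(nb_dispersion_phi),
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    background_interaction_rate = as.numeric(background_interaction_rate),
    coding_call_flip_rate = as.numeric(coding_call_flip_rate),
    lncrna_length_range = as.integer(lncrna_length_range),
    mrna_length_range = as.integer(mrna_length_range),
    lncrna_exon_range = as.integer(lncrna_exon_range),
    mrna_exon_range = as.integer(mrna_exon_range)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "n_mrna", "n_lncrna", "n_mirna",
              "n_replicates_per_condition", "n_planted_triads")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(sprintf("`%s` must be a non-negative integer.", f))
    }
  }
  if (cfg$n_replicates_per_condition < 1) {
    abort("`n_replicates_per_condition` must be >= 1.")
  }
  rates <- c("de_fraction", "background_interaction_rate",
             "coding_call_flip_rate")
  for (f in rates) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f))
    }
  }
  if (cfg$nb_dispersion_phi < 0) {
    abort("`nb_dispersion_phi` must be >= 0.")
  }
  lim <- min(cfg$n_lncrna, cfg$n_mirna, cfg$n_mrna)
  if (cfg$n_planted_triads > lim) {
    abort(sprintf(
      "`n_planted_triads` (%d) exceeds min(n_lncrna, n_mirna, n_mrna) = %d.",
      cfg$n_planted_triads, lim))
  }
  for (f in c("lncrna_length_range", "mrna_length_range",
              "lncrna_exon_range", "mrna_exon_range",
              "baseline_log_mean_range")) {
    rng <- cfg[[f]]
    if (length(rng) != 2 || any(is.na(rng)) || rng[1] > rng[2]) {
      abort(sprintf("`%s` must be an ordered pair.", f))
    }
  }
  if (cfg$lncrna_exon_range[1] < 1 || cfg$mrna_exon_range[1] < 1) {
    abort("Exon-count ranges must start at >= 1.")
  }
  if (cfg$chromosome_length <= 0) abort("`chromosome_length` must be > 0.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  features: %d mRNA, %d lncRNA, %d miRNA on %d chromosomes\n",
              x$n_mrna, x$n_lncrna, x$n_mirna, x$n_chromosomes))
  cat(sprintf("  design: 3 tissues x 2 conditions x %d replicates\n",
              x$n_replicates_per_condition))
  cat(sprintf("  triads: %d planted (beta = %.2f), phi = %.3g, delta = %.2f log2\n",
              x$n_planted_triads, x$coupling_beta, x$nb_dispersion_phi,
              x$condition_shift_delta))
  invisible(x)
}
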