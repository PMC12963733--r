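test_that("annotation generation respects counts, bounds and structure", {
  cfg <- sim_config(seed = 1, n_mrna = 50, n_lncrna = 20, n_mirna = 5,
                    n_planted_triads = 0)
  ann <- simulate_annotation(cfg)
  tx <- ann$transcripts
  expect_equal(sum(tx$biotype == "mRNA"), 50)
  expect_equal(sum(tx$biotype == "lncRNA"), 20)
  expect_true(all(tx$start >= 1))
  expect_true(all(tx$end <= cfg$chromosome_length))
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))  # disjoint, sorted
    expect_gte(min(ex$start), tx$start[i])
    expect_lte(max(ex$end), tx$end[i])
    expect_equal(sum(ex$end - ex$start + 1), tx$length[i])
    expect_equal(nrow(ex), tx$n_exons[i])
  }
  expect_true(all(tx$orf_length[tx$biotype == "mRNA"] > 0))
  expect_true(all(tx$orf_length[tx$biotype == "lncRNA"] <= 90))
})

test_that("annotation generation handles the empty and infeasible cases", {
  empty <- simulate_annotation(sim_config(n_mrna = 0, n_lncrna = 0,
                                          n_mirna = 1, n_planted_triads = 0))
  expect_equal(nrow(empty$transcripts), 0)
  expect_error(
    simulate_annotation(sim_config(n_mrna = 1, n_lncrna = 0, n_mirna = 1,
                                   n_planted_triads = 0,
                                   chromosome_length = 500)),
    "too short")
})

test_that("the whole dataset is deterministic in the seed, field for field", {
  a <- simulate_dataset(tiny_config(seed = 7))
  b <- simulate_dataset(tiny_config(seed = 7))
  c <- simulate_dataset(tiny_config(seed = 8))
  for (part in c("annotation", "triads", "coding_calls", "interactions")) {
    expect_identical(a[[part]], b[[part]])
  }
  expect_identical(a$expression$mrna, b$expression$mrna)
  expect_identical(a$expression$truth, b$expression$truth)
  expect_false(identical(a$annotation, c$annotation))
  expect_false(identical(a$expression$mrna, c$expression$mrna))
})

test_that("expression matrices have the design-forced shapes and metadata", {
  cfg <- tiny_config(seed = 2, n_replicates_per_condition = 4)
  ds <- simulate_dataset(cfg)
  n_s <- 3 * 2 * 4
  expect_equal(dim(ds$expression$mrna), c(40, n_s + 1))
  expect_equal(dim(ds$expression$lncrna), c(20, n_s + 1))
  expect_equal(dim(ds$expression$mirna), c(15, n_s + 1))
  expect_setequal(names(ds$expression$samples),
                  c("sample_id", "tissue", "condition", "replicate"))
  expect_equal(nrow(ds$expression$samples), n_s)
  expect_equal(sort(unique(ds$expression$samples$tissue)),
               sort(c("hypothalamus", "pituitary", "ovary")))
})

test_that("with no signal and phi = 0 every feature fluctuates around its mean", {
  cfg <- sim_config(seed = 3, n_mrna = 40, n_lncrna = 0, n_mirna = 0,
                    n_planted_triads = 0, coupling_beta = 0,
                    condition_shift_delta = 0, de_fraction = 0,
                    nb_dispersion_phi = 0, n_replicates_per_condition = 5)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  m <- as.matrix(ex$mrna[, -1])
  mu <- exp(ex$truth$baseline_log_mean)
  z <- (rowMeans(m) - mu) / sqrt(mu / ncol(m))
  expect_lt(max(abs(z)), 5)  # Poisson means recovered within sampling error
})

test_that("planted triads force the ceRNA correlation signs at large n", {
  cfg <- sim_config(seed = 4, n_mrna = 3, n_lncrna = 3, n_mirna = 3,
                    n_planted_triads = 1, coupling_beta = 1.5,
                    n_replicates_per_condition = 40)
  ds <- simulate_dataset(cfg)
  ex <- ds$expression
  tr <- ds$triads
  m <- rbind(as.matrix(tibble::column_to_rownames(ex$mrna, "feature_id")),
             as.matrix(tibble::column_to_rownames(ex$lncrna, "feature_id")),
             as.matrix(tibble::column_to_rownames(ex$mirna, "feature_id")))
  expect_lt(cor(m[tr$mirna_id, ], m[tr$mrna_id, ], method = "spearman"), 0)
  expect_lt(cor(m[tr$mirna_id, ], m[tr$lncrna_id, ], method = "spearman"), 0)
  expect_gt(cor(m[tr$lncrna_id, ], m[tr$mrna_id, ]), 0)
})

test_that("NB marginal moments match mean + phi * mean^2 at n = 10000", {
  cfg <- sim_config(seed = 5, n_mrna = 1, n_lncrna = 0, n_mirna = 0,
                    n_planted_triads = 0, coupling_beta = 0,
                    condition_shift_delta = 0, de_fraction = 0,
                    nb_dispersion_phi = 0.5,
                    n_replicates_per_condition = 1667)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  x <- as.numeric(as.matrix(ex$mrna[, -1]))
  mu <- exp(ex$truth$baseline_log_mean[1])
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + 0.5 * mu^2, tolerance = 0.15)
})

test_that("coding-call noise hits its configured flip rate", {
  base <- function(rate, n = 40) {
    cfg <- sim_config(seed = 6, n_mrna = n, n_lncrna = n, n_mirna = 1,
                      n_planted_triads = 0, coding_call_flip_rate = rate)
    ds_ann <- simulate_annotation(cfg)
    calls <- simulate_coding_calls(ds_ann, cfg)
    truth <- ifelse(ds_ann$transcripts$biotype == "mRNA", "coding",
                    "noncoding")
    names(truth) <- ds_ann$transcripts$transcript_id
    dplyr::mutate(calls, agree = verdict == truth[transcript_id])
  }
  expect_true(all(base(0)$agree))
  expect_false(any(base(1)$agree))
  big <- base(0.1, n = 1000)
  per_tool <- dplyr::summarise(big, err = mean(!agree), .by = tool)
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_true(all(abs(per_tool$err - 0.1) < 3 * se))
})

test_that("interaction tables contain planted links plus background at rate", {
  cfg0 <- tiny_config(seed = 9, background_interaction_rate = 0)
  ds0 <- simulate_dataset(cfg0)
  expect_equal(nrow(ds0$interactions$mirna_lncrna), 4)
  expect_equal(nrow(ds0$interactions$mirna_mrna), 4)
  expect_setequal(
    paste(ds0$interactions$mirna_lncrna$mirna_id,
          ds0$interactions$mirna_lncrna$target_id),
    paste(ds0$triads$mirna_id, ds0$triads$lncrna_id))

  cfg1 <- tiny_config(seed = 9, background_interaction_rate = 1)
  ds1 <- simulate_dataset(cfg1)
  expect_equal(nrow(ds1$interactions$mirna_lncrna), 15 * 20)
  expect_equal(nrow(ds1$interactions$mirna_mrna), 15 * 40)

  cfg <- sim_config(seed = 10, n_mrna = 1, n_lncrna = 100, n_mirna = 100,
                    n_planted_triads = 0, background_interaction_rate = 0.05)
  ds <- simulate_dataset(cfg)
  n <- nrow(ds$interactions$mirna_lncrna)
  se <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n - 500), 3 * se)
})

test_that("every planted triad is recoverable in principle", {
  ds <- simulate_dataset(tiny_config(seed = 11))
  links_l <- paste(ds$interactions$mirna_lncrna$mirna_id,
                   ds$interactions$mirna_lncrna$target_id)
  links_m <- paste(ds$interactions$mirna_mrna$mirna_id,
                   ds$interactions$mirna_mrna$target_id)
  expect_true(all(paste(ds$triads$mirna_id, ds$triads$lncrna_id) %in% links_l))
  expect_true(all(paste(ds$triads$mirna_id, ds$triads$mrna_id) %in% links_m))
  expect_true(all(ds$triads$latent_loading != 0))
})
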