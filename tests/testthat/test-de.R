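test_that("FPKM follows its defining identity and scaling laws", {
  counts <- tibble::tibble(feature_id = c("a", "b"), s1 = c(10, 0))
  f <- compute_fpkm(counts, c(a = 1000, b = 500),
                    library_sizes = c(s1 = 1e6))
  expect_equal(f$s1, c(10, 0))
  # doubling the library size halves every FPKM in that sample
  half <- compute_fpkm(counts, c(a = 1000, b = 500),
                       library_sizes = c(s1 = 2e6))
  expect_equal(half$s1, f$s1 / 2)
  # column sums scale exactly inversely with library size
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  lens <- setNames(rep(1000, 10), rownames(m))
  libs <- c(s1 = 1e6, s2 = 2e6, s3 = 4e6, s4 = 8e6)
  fp <- as.matrix(compute_fpkm(m, lens, libs)[, -1])
  expect_equal(colSums(fp) * libs / 1e9, colSums(m / 1000),
               ignore_attr = TRUE)
  expect_error(compute_fpkm(counts, c(a = 0, b = 500), c(s1 = 1)), "> 0")
  expect_error(compute_fpkm(counts, c(a = 10, b = 500), c(s1 = 0)), "> 0")
})

test_that("log2 fold change handles equality, doubling and double zeros", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(10, 20, pseudocount = 1e-9), 1,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(0, 0, pseudocount = 1), 0)
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "> 0")
})

test_that("method-of-moments dispersion recovers known truth", {
  grp <- rep(c("A", "B"), each = 10)
  withr::with_seed(1, {
    pois <- matrix(rpois(2000 * 20, 100), ncol = 20)
  })
  rownames(pois) <- paste0("g", 1:2000)
  expect_lte(estimate_common_dispersion(pois, grp), 0.02)

  withr::with_seed(2, {
    nb <- matrix(rnbinom(2000 * 20, mu = 100, size = 5), ncol = 20)
  })
  rownames(nb) <- paste0("g", 1:2000)
  est <- estimate_common_dispersion(nb, grp)
  expect_equal(est, 0.2, tolerance = 0.25)
  # robust variant agrees on clean data
  expect_equal(estimate_common_dispersion(nb, grp, robust = TRUE), 0.2,
               tolerance = 0.25)

  const <- matrix(7, 10, 4, dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(estimate_common_dispersion(const, rep(c("A", "B"), 2)), 0)
  zeros <- matrix(0, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(estimate_common_dispersion(zeros, rep(c("A", "B"), 2)),
               "All-zero")
})

test_that("NB exact test matches enumeration and binomial oracles", {
  expect_equal(nb_exact_test(30, 30, 3, 3, 0.1), 1)  # balanced split
  expect_equal(nb_exact_test(0, 0, 3, 3, 0.1), 1)    # no information

  withr::with_seed(3, {
    cases <- tibble::tibble(
      sum_a = sample(0:120, 40, replace = TRUE),
      sum_b = sample(0:80, 40, replace = TRUE),
      n_a = sample(1:5, 40, replace = TRUE),
      n_b = sample(1:5, 40, replace = TRUE),
      phi = sample(c(0, 0.05, 0.2, 1), 40, replace = TRUE)
    )
  })
  for (i in seq_len(nrow(cases))) {
    c0 <- cases[i, ]
    got <- nb_exact_test(c0$sum_a, c0$sum_b, c0$n_a, c0$n_b, c0$phi)
    want <- oracle_nb_conditional(c0$sum_a, c0$sum_b, c0$n_a, c0$n_b, c0$phi)
    expect_equal(got, want, tolerance = 1e-12)
    # symmetry under swapping the groups
    expect_equal(got, nb_exact_test(c0$sum_b, c0$sum_a, c0$n_b, c0$n_a,
                                    c0$phi), tolerance = 1e-12)
    expect_gt(got, 0); expect_lte(got, 1)
  }
  # phi = 0 with equal group sizes is the conditional binomial(t, 1/2) test
  for (t in c(1, 7, 30, 101)) {
    for (a in unique(c(0, 1, t %/% 3, t))) {
      expect_equal(nb_exact_test(a, t - a, 4, 4, 0),
                   oracle_binom_minlike(a, t), tolerance = 1e-10)
    }
  }
  expect_error(nb_exact_test(1, 1, 0, 1, 0.1), ">= 1")
  expect_error(nb_exact_test(1, 1, 1, 1, -0.1), ">= 0")
})

test_that("DE calling applies the study thresholds with the >= boundary", {
  res <- tibble::tibble(
    feature_id = c("sig_up", "p_fail", "at_boundary", "sig_down"),
    log2_fc = c(0.30, 2.0, 0.26, -0.5),
    p_value = c(0.04, 0.06, 0.01, 0.001)
  )
  called <- call_de(res)
  expect_equal(called$significant, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(called$direction, c("up", "none", "up", "down"))
  strict <- call_de(res, lfc_boundary = "gt")
  expect_false(strict$significant[strict$feature_id == "at_boundary"])
  g <- glance(called)
  expect_equal(g$n_significant, 3)
  expect_equal(g$n_up, 2)
  expect_equal(g$n_down, 1)
})

test_that("raising either threshold never adds a significant feature", {
  withr::with_seed(4, {
    res <- tibble::tibble(
      feature_id = paste0("f", 1:200),
      log2_fc = rnorm(200),
      p_value = runif(200)
    )
  })
  base <- call_de(res)
  for (lfc in c(0.5, 1, 2)) {
    for (p in c(0.01, 0.03)) {
      tighter <- call_de(res, lfc_threshold = lfc, p_threshold = p)
      expect_true(all(res$feature_id[tighter$significant] %in%
                        res$feature_id[base$significant]))
    }
  }
})

test_that("de_test ties normalization, dispersion and the exact test together", {
  cfg <- sim_config(seed = 5, n_mrna = 60, n_lncrna = 0, n_mirna = 0,
                    n_planted_triads = 0, condition_shift_delta = 3,
                    de_fraction = 0.3, n_replicates_per_condition = 6)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  de <- call_de(de_test(ex$mrna, ex$samples, "laying", "broodiness",
                        tissue = "ovary"))
  truth <- ex$truth
  # every planted shift is recovered, with the orientation B over A
  joined <- dplyr::inner_join(as_tibble(de), truth, by = "feature_id")
  shifted <- joined[joined$true_log2fc != 0, ]
  expect_gt(mean(shifted$significant), 0.95)
  expect_true(all(sign(shifted$log2_fc) == sign(shifted$true_log2fc)))
  expect_equal(shifted$log2_fc, shifted$true_log2fc, tolerance = 0.35)
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_equal(attr(de, "phi"), 0.1, tolerance = 0.5)
})

test_that("ddCt relative quantification follows 2^-ddCt", {
  expect_equal(relative_expression_ddct(20, 18, 21, 19), 1)
  expect_equal(relative_expression_ddct(20, 18, 22, 19), 2)
  expect_equal(relative_expression_ddct(24, 19, 22, 19), 0.25)
  expect_error(relative_expression_ddct(Inf, 1, 1, 1), "finite")
})
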