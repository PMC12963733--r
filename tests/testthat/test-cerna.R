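# Crafted screen fixture: one miRNA targeting one lncRNA and two mRNAs,
# with exact sample correlations, plus background miRNAs that only
# enlarge the miRNA universe (they target a dummy lncRNA).
crafted_screen <- function(n_bg_mirna = 30) {
  x <- c(3, 9, 1, 14, 6, 11, 4, 8)
  noise <- c(0.4, -1.2, 0.8, 0.3, -0.6, 1.1, -0.9, 0.2)
  expr <- rbind(
    lnc1 = x,
    mir1 = -x,
    mrna1 = make_correlated(x, 0.95, noise),
    mrna2 = make_correlated(x, 0.85, noise)  # below the PCC bar
  )
  colnames(expr) <- paste0("s", 1:8)
  bg <- if (n_bg_mirna > 0) paste0("mir-bg", seq_len(n_bg_mirna)) else character(0)
  inter <- list(
    mirna_lncrna = dplyr::bind_rows(
      tibble::tibble(mirna_id = "mir1", target_id = "lnc1"),
      tibble::tibble(mirna_id = bg, target_id = "lncD")),
    mirna_mrna = tibble::tibble(mirna_id = "mir1",
                                target_id = c("mrna1", "mrna2"))
  )
  list(expr = expr,
       inter = inter,
       de_lnc = c("lnc1", "lncD"),
       de_mir = c("mir1", bg),
       de_mrna = c("mrna1", "mrna2"))
}

test_that("shared-miRNA test reduces to the hypergeometric kernel", {
  u <- paste0("m", 1:20)
  got <- shared_mirna_pvalue(u[1:5], u[3:8], u)
  expect_equal(got$k, 3)
  expect_equal(got$p_value, oracle_hypergeom_upper(20, 5, 6, 3),
               tolerance = 1e-12)
  disjoint <- shared_mirna_pvalue(u[1:3], u[10:12], u)
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$p_value, 1)
  full <- shared_mirna_pvalue(u, u, u)
  expect_equal(full$k, 20)
  expect_equal(full$p_value, 1)  # forced full overlap is uninformative
  expect_error(shared_mirna_pvalue("m1", "m2", character(0)), "non-empty")
  expect_error(shared_mirna_pvalue("zzz", u[1], u), "subsets")
})

test_that("triad acceptance enforces every threshold at its boundary", {
  expect_true(triad_passes(-0.8, -0.75, 0.95, 0.01))
  expect_true(triad_passes(-0.7, -0.7, 0.95, 0.01))    # SCC <= -0.7 inclusive
  expect_false(triad_passes(-0.65, -0.75, 0.95, 0.01)) # lnc pair too weak
  expect_false(triad_passes(-0.8, -0.65, 0.95, 0.01))  # mRNA pair too weak
  expect_false(triad_passes(-0.8, -0.75, 0.90, 0.01))  # PCC strictly > 0.9
  expect_false(triad_passes(-0.8, -0.75, 0.95, 0.05))  # p strictly < 0.05
  expect_false(triad_passes(NA, -0.75, 0.95, 0.01))
})

test_that("the screen accepts exactly the correlation-qualified triple", {
  fx <- crafted_screen()
  got <- build_triads(fx$de_lnc, fx$de_mir, fx$de_mrna, fx$inter, fx$expr,
                      log_transform = FALSE)
  expect_equal(nrow(got), 1)
  expect_equal(got$mrna_id, "mrna1")
  expect_equal(attr(got, "n_candidates"), 2L)
  expect_equal(got$pcc_lnc_mrna, 0.95, tolerance = 1e-12)
  expect_equal(got$shared_mirna_count, 1L)
  expect_equal(got$hypergeom_p, 1 / 31, tolerance = 1e-12)
  # recorded statistics reproduce exactly from the expression matrix
  expect_equal(got$scc_lnc_mirna,
               cor(rank(fx$expr["lnc1", ]), rank(fx$expr["mir1", ])),
               tolerance = 1e-12)
  expect_equal(got$scc_mrna_mirna,
               cor(rank(fx$expr["mrna1", ]), rank(fx$expr["mir1", ])),
               tolerance = 1e-12)
  expect_equal(got$pcc_lnc_mrna,
               cor(fx$expr["lnc1", ], fx$expr["mrna1", ]),
               tolerance = 1e-12)
})

test_that("a singleton miRNA universe can never clear the hypergeometric bar", {
  fx <- crafted_screen(n_bg_mirna = 0)
  got <- build_triads(fx$de_lnc, fx$de_mir, fx$de_mrna, fx$inter, fx$expr,
                      log_transform = FALSE)
  expect_equal(nrow(got), 0)  # p = 1 with one candidate miRNA in total
})

test_that("screen errors name missing expression features", {
  fx <- crafted_screen()
  expect_error(
    build_triads(fx$de_lnc, fx$de_mir, fx$de_mrna, fx$inter,
                 fx$expr[c("lnc1", "mir1", "mrna2"), ]),
    "missing from expression")
})

test_that("correlation arms recover planted triads once members pass DE", {
  cfg <- sim_config(seed = 1, n_replicates_per_condition = 15)
  ds <- simulate_dataset(cfg)
  ex <- ds$expression
  sel <- ex$samples$sample_id[ex$samples$tissue == "ovary"]
  sig <- function(m) {
    d <- call_de(de_test(m, ex$samples, "laying", "broodiness",
                         tissue = "ovary"))
    d$feature_id[d$significant]
  }
  de_l <- sig(ex$lncrna); de_m <- sig(ex$mirna); de_r <- sig(ex$mrna)
  got <- build_triads(de_l, de_m, de_r, ds$interactions, ex,
                      sample_ids = sel, hypergeom_threshold = 1.01)
  tr <- ds$triads
  all_de <- tr$lncrna_id %in% de_l & tr$mirna_id %in% de_m &
    tr$mrna_id %in% de_r
  expect_gt(mean(all_de), 0.5)  # DE arm passes most planted members
  cond_sens <- mean(triad_key(tr[all_de, ]) %in% triad_key(got))
  precision <- mean(triad_key(got) %in% triad_key(tr))
  expect_gte(cond_sens, 0.9)
  expect_gte(precision, 0.9)
})

test_that("network assembly deduplicates and never links lncRNA to mRNA", {
  one <- tibble::tibble(lncrna_id = "l1", mirna_id = "m1", mrna_id = "r1")
  net1 <- assemble_network(one)
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 2)
  expect_false(any(net1$edges$source %in% c("l1", "r1") &
                     net1$edges$target %in% c("l1", "r1")))
  two <- dplyr::bind_rows(one,
                          tibble::tibble(lncrna_id = "l2", mirna_id = "m1",
                                         mrna_id = "r2"))
  net2 <- assemble_network(two)
  expect_equal(nrow(net2$nodes), 5)
  expect_equal(nrow(net2$edges), 4)
  empty <- assemble_network(one[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
  dirs <- tibble::tibble(feature_id = c("l1", "m1", "r1"),
                         direction = c("down", "up", "down"))
  reg <- assemble_network(one, dirs)$nodes
  expect_equal(reg$regulation[reg$id == "m1"], "up")
})

test_that("network statistics report degrees, composition and hubs", {
  one <- tibble::tibble(lncrna_id = "l1", mirna_id = "m1", mrna_id = "r1")
  st1 <- network_stats(assemble_network(one))
  expect_equal(st1$summary$n_nodes, 3)
  expect_equal(st1$summary$n_edges, 2)
  expect_equal(sort(st1$degree$degree), c(1, 1, 2))

  star <- tidyr::expand_grid(lncrna_id = paste0("l", 1:5),
                             mrna_id = paste0("r", 1:5)) |>
    dplyr::mutate(mirna_id = "hub")
  st <- network_stats(assemble_network(star))
  expect_equal(st$summary$n_nodes, 11)
  expect_equal(st$summary$n_edges, 10)
  expect_equal(st$degree$degree[st$degree$id == "hub"], 10)
  expect_equal(st$hubs$id[st$hubs$class == "miRNA"], "hub")

  # bookkeeping matches a directly computed truth table
  withr::with_seed(5, {
    tri <- tibble::tibble(
      lncrna_id = sample(paste0("l", 1:8), 12, replace = TRUE),
      mirna_id = sample(paste0("m", 1:4), 12, replace = TRUE),
      mrna_id = sample(paste0("r", 1:8), 12, replace = TRUE)
    )
  })
  net <- assemble_network(tri)
  st2 <- network_stats(net)
  expect_equal(st2$summary$n_nodes,
               dplyr::n_distinct(c(tri$lncrna_id, tri$mirna_id, tri$mrna_id)))
  expect_equal(st2$summary$n_edges,
               dplyr::n_distinct(paste(tri$mirna_id, tri$lncrna_id)) +
                 dplyr::n_distinct(paste(tri$mirna_id, tri$mrna_id)))
})

test_that("network export round-trips exactly and supports SIF", {
  one <- tibble::tibble(lncrna_id = "l1", mirna_id = "m1", mrna_id = "r1")
  dirs <- tibble::tibble(feature_id = c("l1", "m1", "r1"),
                         direction = c("down", "up", "down"))
  net <- assemble_network(one, dirs)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir, format = "sif")
  back <- read_network(dir)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  sif <- readr::read_lines(paths[["sif"]])
  expect_length(sif, 2)

  empty_dir <- withr::local_tempdir()
  export_network(assemble_network(one[0, ]), empty_dir)
  expect_length(readr::read_lines(file.path(empty_dir, "edges.tsv")), 1)
  back0 <- read_network(empty_dir)
  expect_equal(nrow(back0$edges), 0)
})
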