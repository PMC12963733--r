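# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths (and where possible the base
# functions) used by the implementation.

# Hypergeometric upper tail by direct enumeration of the pmf.
oracle_hypergeom_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson r and t-transform p from the raw sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Average ranks computed from sorted positions, without base rank().
oracle_avg_rank <- function(x) {
  o <- order(x)
  rk <- numeric(length(x))
  pos <- 1
  while (pos <= length(x)) {
    run <- which(x[o] == x[o[pos]])
    rk[o[run]] <- mean(run)
    pos <- max(run) + 1
  }
  rk
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

# Conditional binomial(t, 1/2) exact test, two-sided by the minlike rule.
oracle_binom_minlike <- function(a, t) {
  pr <- stats::dbinom(0:t, t, 0.5)
  sum(pr[pr <= pr[a + 1] * (1 + 1e-07)])
}

# Brute-force enumeration of the conditional NB split distribution in
# probability space (no log-space machinery).
oracle_nb_conditional <- function(sum_a, sum_b, n_a, n_b, phi) {
  t <- sum_a + sum_b
  if (t == 0) return(1)
  mu <- t / (n_a + n_b)
  f <- function(x, n) {
    if (phi == 0) stats::dpois(x, n * mu) else {
      stats::dnbinom(x, mu = n * mu, size = n / phi)
    }
  }
  w <- f(0:t, n_a) * f(t - (0:t), n_b)
  w <- w / sum(w)
  min(1, sum(w[w <= w[sum_a + 1] * (1 + 1e-07)]))
}

# A vector e with exact sample correlation `r` to x (Gram-Schmidt).
make_correlated <- function(x, r, noise) {
  cx <- x - mean(x)
  ce <- noise - mean(noise)
  ce <- ce - sum(ce * cx) / sum(cx * cx) * cx  # orthogonal to x
  y <- r * cx / sqrt(sum(cx^2)) + sqrt(1 - r^2) * ce / sqrt(sum(ce^2))
  as.numeric(y)
}

# Small simulated dataset shared by several tests.
tiny_config <- function(seed = 1L, n_replicates_per_condition = 3, ...) {
  sim_config(seed = seed, n_mrna = 40, n_lncrna = 20, n_mirna = 15,
             n_planted_triads = 4,
             n_replicates_per_condition = n_replicates_per_condition,
             n_chromosomes = 3, chromosome_length = 2e6, ...)
}

triad_key <- function(t) paste(t$lncrna_id, t$mirna_id, t$mrna_id)
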