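#' FPKM from raw counts
#'
#' `fpkm = counts * 1e9 / (length_bp * library_size)` — fragments per
#' kilobase of exon model per million mapped fragments.
#'
#' @param counts Wide count tibble (first column feature id) or matrix.
#' @param transcript_lengths Named numeric vector (bp) or tibble with
#'   columns `transcript_id`/`feature_id` and `length`, covering every
#'   feature in `counts`.
#' @param library_sizes Optional named per-sample totals; defaults to the
#'   column sums of `counts`. Must be strictly positive.
#' @return Wide FPKM tibble with the shape of `counts`.
#' @examples
#' m <- tibble::tibble(feature_id = "tx1", s1 = 10)
#' compute_fpkm(m, c(tx1 = 1000), library_sizes = c(s1 = 1e6))  # FPKM = 10
#' @export
compute_fpkm <- function(counts, transcript_lengths, library_sizes = NULL) {
  m <- as_expr_matrix(counts, "counts")
  len <- if (is.data.frame(transcript_lengths)) {
    idcol <- intersect(c("feature_id", "transcript_id"),
                       names(transcript_lengths))[1]
    setNames(transcript_lengths$length, transcript_lengths[[idcol]])
  } else {
    transcript_lengths
  }
  if (!all(rownames(m) %in% names(len))) {
    abort("Every counted feature needs a transcript length.")
  }
  len <- len[rownames(m)]
  lib <- library_sizes %||% colSums(m)
  if (!is.null(names(lib))) lib <- lib[colnames(m)]
  if (any(len <= 0)) abort("Transcript lengths must be > 0.")
  if (any(lib <= 0)) abort("Library sizes must be > 0.")
  fpkm <- sweep(m / len, 2, lib, "/") * 1e9
  expr_tibble(fpkm)
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`; orientation is
#' group B over group A.
#'
#' @param mean_a,mean_b Non-negative group means (vectorized).
#' @param pseudocount Positive stabilizer added to both means.
#' @return Log2 fold change(s).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  if (any(mean_a < 0 | mean_b < 0)) abort("Means must be >= 0.")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Total-count normalization
#'
#' Scales every sample to the geometric mean of the library sizes
#' (total counts), the normalization used ahead of the NB exact test.
#'
#' @param counts Wide count tibble or matrix.
#' @return Matrix of normalized counts (not rounded).
#' @export
normalize_counts <- function(counts) {
  m <- as_expr_matrix(counts, "counts")
  lib <- colSums(m)
  if (any(lib <= 0)) abort("Every sample must have positive total counts.")
  target <- exp(mean(log(lib)))
  sweep(m, 2, target / lib, "*")
}

#' Method-of-moments common dispersion
#'
#' Estimates one NB dispersion `phi` shared across features from
#' normalized counts: per feature, the within-group variance `s2` is
#' pooled across groups and combined with the grand mean `m` as
#' `(s2 - m) / m^2`; the estimate is the mean over informative features,
#' floored at zero. Under `var = mean + phi * mean^2` this is consistent
#' as features accumulate. With `robust = TRUE` the median over features
#' replaces the mean, so a minority of genuinely hyper-variable features
#' (for instance genes under strong latent regulation) cannot inflate
#' the common value — the same motivation as the robust dispersion
#' options of the established empirical-Bayes DE tools.
#'
#' @param counts Wide count tibble or matrix (normalized or raw).
#' @param groups Character/factor of length `ncol`, with at least two
#'   samples per group.
#' @param robust Use the median over features instead of the mean
#'   (default `FALSE`).
#' @return Scalar `phi >= 0`.
#' @export
estimate_common_dispersion <- function(counts, groups, robust = FALSE) {
  m <- as_expr_matrix(counts, "counts")
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("`groups` must match the sample columns.")
  if (any(table(groups) < 2)) abort("Need >= 2 samples per group.")
  if (all(m == 0)) abort("All-zero count matrix: dispersion undefined.")
  gl <- unique(groups)
  nS <- vapply(gl, function(g) sum(groups == g), integer(1))
  s2 <- 0
  for (g in gl) {
    sub <- m[, groups == g, drop = FALSE]
    s2 <- s2 + apply(sub, 1, var) * (ncol(sub) - 1)
  }
  s2 <- s2 / (ncol(m) - length(gl))
  mu <- rowMeans(m)
  ok <- mu > 0
  est <- if (robust) median else mean
  max(0, est((s2[ok] - mu[ok]) / mu[ok]^2))
}

#' Conditional negative-binomial exact test
#'
#' Tests whether two groups of NB counts share a mean, conditional on the
#' total. With per-sample null mean `mu = t / (n_a + n_b)` where
#' `t = sum_a + sum_b`, the group sums are treated as
#' `NB(n_a * mu, phi / n_a)` and `NB(n_b * mu, phi / n_b)` (group sums of
#' i.i.d. NB counts with common dispersion), the conditional distribution
#' of the group-A sum given `t` is enumerated over `0..t`, and the
#' two-sided p-value sums all outcomes no more probable than the observed
#' split (the "minlike" rule). At `phi = 0` the NB degenerates to Poisson
#' and the test reduces to the conditional binomial exact test.
#'
#' @param sum_a,sum_b Non-negative integer group sums of counts
#'   pre-normalized to equal effective library sizes.
#' @param n_a,n_b Replicate counts (>= 1).
#' @param phi Common NB dispersion (>= 0).
#' @return p-value in (0, 1]; `t = 0` returns 1 by convention.
#' @examples
#' nb_exact_test(30, 30, 3, 3, phi = 0.1)  # balanced split -> 1
#' @export
nb_exact_test <- function(sum_a, sum_b, n_a, n_b, phi) {
  if (sum_a < 0 || sum_b < 0) abort("Group sums must be >= 0.")
  if (n_a < 1 || n_b < 1) abort("Replicate counts must be >= 1.")
  if (phi < 0) abort("`phi` must be >= 0.")
  sum_a <- round(sum_a); sum_b <- round(sum_b)
  t <- sum_a + sum_b
  if (t == 0) return(1)
  mu <- t / (n_a + n_b)
  a <- 0:t
  if (phi == 0) {
    lp <- dpois(a, lambda = n_a * mu, log = TRUE) +
      dpois(t - a, lambda = n_b * mu, log = TRUE)
  } else {
    lp <- dnbinom(a, mu = n_a * mu, size = n_a / phi, log = TRUE) +
      dnbinom(t - a, mu = n_b * mu, size = n_b / phi, log = TRUE)
  }
  lp <- lp - log_sum_exp(lp)
  lobs <- lp[sum_a + 1]
  p <- sum(exp(lp[lp <= lobs + 1e-7]))
  min(1, max(p, exp(lobs)))
}

#' Per-feature differential expression between two conditions
#'
#' Normalizes counts by total count to the geometric-mean library size,
#' estimates a common dispersion, and applies [nb_exact_test()] to every
#' feature; fold changes are computed on normalized group means with a
#' pseudocount.
#'
#' @param counts Wide count tibble or matrix.
#' @param samples Sample sheet with `sample_id` and `condition` (and
#'   optionally `tissue`).
#' @param condition_a,condition_b The two condition labels; fold change is
#'   B over A.
#' @param tissue Optional tissue to restrict samples to.
#' @param pseudocount Pseudocount for the fold change (normalized counts).
#' @param phi Optional fixed dispersion; when `NULL`, estimated robustly
#'   (median method-of-moments, see [estimate_common_dispersion()]).
#' @return Tibble: `feature_id`, `base_mean_a`, `base_mean_b`, `log2_fc`,
#'   `p_value`; dispersion and orientation stored as attributes
#'   `phi` and `comparison`.
#' @export
de_test <- function(counts, samples, condition_a, condition_b,
                    tissue = NULL, pseudocount = 1, phi = NULL) {
  if (!is.null(tissue)) {
    samples <- dplyr::filter(samples, .data$tissue == !!tissue)
  }
  samples <- dplyr::filter(samples,
                           .data$condition %in% c(condition_a, condition_b))
  m <- as_expr_matrix(counts, "counts")
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("Samples absent from counts: %s.",
                  paste(head(missing, 3), collapse = ", ")))
  }
  m <- m[, samples$sample_id, drop = FALSE]
  grp <- samples$condition
  if (sum(grp == condition_a) < 1 || sum(grp == condition_b) < 1) {
    abort("Both conditions need at least one sample.")
  }
  norm <- normalize_counts(m)
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(norm, grp, robust = TRUE)
  }
  ia <- grp == condition_a
  ib <- grp == condition_b
  n_a <- sum(ia); n_b <- sum(ib)
  sum_a <- round(rowSums(norm[, ia, drop = FALSE]))
  sum_b <- round(rowSums(norm[, ib, drop = FALSE]))
  mean_a <- unname(rowMeans(norm[, ia, drop = FALSE]))
  mean_b <- unname(rowMeans(norm[, ib, drop = FALSE]))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    nb_exact_test(sum_a[i], sum_b[i], n_a, n_b, phi)
  }, numeric(1))
  out <- tibble(
    feature_id = rownames(norm),
    base_mean_a = mean_a,
    base_mean_b = mean_b,
    log2_fc = log2_fold_change(mean_a, mean_b, pseudocount),
    p_value = p
  )
  attr(out, "phi") <- phi
  attr(out, "comparison") <- c(a = condition_a, b = condition_b)
  out
}

#' Flag differentially expressed features
#'
#' Applies the study thresholds: significant iff `p < p_threshold` and
#' `|log2FC|` at least (or strictly above, see `lfc_boundary`) the fold
#' change threshold. Direction follows the sign of the fold change.
#'
#' @param results A [de_test()] result (columns `log2_fc`, `p_value`).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 0.26).
#' @param p_threshold p-value threshold (default 0.05, strict `<`).
#' @param lfc_boundary `"ge"` (default) counts `|log2FC|` equal to the
#'   threshold as passing; `"gt"` requires strict excess.
#' @return Input tibble with `direction` (`up`/`down`/`none`) and
#'   `significant` columns, classed `cernet_de`; up/down totals are
#'   available via [glance()].
#' @examples
#' res <- tibble::tibble(feature_id = "f", log2_fc = 0.3, p_value = 0.04)
#' call_de(res)$significant
#' @export
call_de <- function(results, lfc_threshold = 0.26, p_threshold = 0.05,
                    lfc_boundary = c("ge", "gt")) {
  lfc_boundary <- match.arg(lfc_boundary)
  if (lfc_threshold <= 0 || p_threshold <= 0) abort("Thresholds must be > 0.")
  pass_lfc <- if (lfc_boundary == "ge") {
    abs(results$log2_fc) >= lfc_threshold
  } else {
    abs(results$log2_fc) > lfc_threshold
  }
  out <- results |>
    mutate(
      significant = .data$p_value < p_threshold & pass_lfc,
      direction = dplyr::case_when(
        !.data$significant ~ "none",
        .data$log2_fc > 0 ~ "up",
        .default = "down"
      )
    )
  class(out) <- c("cernet_de", class(tibble()))
  attr(out, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold)
  attr(out, "phi") <- attr(results, "phi")
  attr(out, "comparison") <- attr(results, "comparison")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard qPCR relative quantification: the target gene's Ct is
#' normalized to a reference gene within the sample and within a
#' calibrator sample, and the difference of differences is exponentiated,
#' `RQ = 2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the test sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator.
#' @return Relative quantity (vectorized).
#' @examples
#' relative_expression_ddct(20, 18, 22, 19)  # ddCt = -1 -> RQ = 2
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample,
            ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(vals))) abort("Ct values must be finite.")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
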