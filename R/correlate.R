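#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with the textbook two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `|r| = 1` yields `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p_value`, `n`.
#' @examples
#' cor_pearson(1:6, 2 * (1:6) + 1)$estimate  # exactly 1
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  cor_t_pvalue(product_moment_r(x, y), length(x))
}

# Direct product-moment formula; exact +-1 on perfectly linear input
# (unlike the scaled updating algorithm inside stats::cor).
product_moment_r <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

#' Spearman rank correlation with t-based p-value
#'
#' Pearson correlation of average-ranked data (ties receive their mean
#' rank), with the same t transform as [cor_pearson()] applied to rho.
#'
#' @inheritParams cor_pearson
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p_value`, `n`.
#' @examples
#' cor_spearman(1:6, exp(1:6))$estimate  # monotone -> exactly 1
#' @export
cor_spearman <- function(x, y) {
  check_cor_input(x, y)
  cor_t_pvalue(product_moment_r(rank(x), rank(y)), length(x))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need n >= 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant vector.")
  }
  invisible(TRUE)
}

cor_t_pvalue <- function(r, n) {
  r <- min(1, max(-1, r))
  df <- n - 2
  if (abs(r) == 1) {
    stat <- sign(r) * Inf
    p <- 0
  } else {
    stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(stat), df)
  }
  tibble(estimate = r, statistic = stat, df = df, p_value = p, n = n)
}

# Row-wise correlation of two expression matrices over shared samples,
# with the t-transform p-value; returns the full r and p matrices.
cor_matrix_with_p <- function(mx, my, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(colnames(mx), colnames(my))) {
    abort("Expression matrices must share identical sample columns.")
  }
  n <- ncol(mx)
  if (n < 3) abort("Need n >= 3 shared samples.")
  tx <- t(mx); ty <- t(my)
  if (method == "spearman") {
    tx <- apply(tx, 2, rank)
    ty <- apply(ty, 2, rank)
  }
  r <- suppressWarnings(cor(tx, ty))
  r[] <- pmin(1, pmax(-1, r))
  df <- n - 2
  stat <- r * sqrt(df / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(stat), df)
  p[abs(r) == 1] <- 0
  list(r = r, p = p, n = n)
}
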