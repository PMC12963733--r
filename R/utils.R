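# Internal helpers shared across modules.

# Convert a wide expression tibble (feature_id, <sample columns>) or a
# numeric matrix into a numeric matrix with feature rownames.
as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(sprintf("`%s` matrix must have feature rownames.", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame or a matrix.", arg))
  }
  if (ncol(x) < 2) {
    abort(sprintf("`%s` must have a feature-id column plus sample columns.", arg))
  }
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Wide tibble from a matrix, first column `feature_id`.
expr_tibble <- function(m) {
  bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

log_sum_exp <- function(lx) {
  mx <- max(lx)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(lx - mx)))
}

# Deterministic per-stage child seeds derived from one root seed, kept
# within 32-bit integer range.
child_seed <- function(seed, stage) {
  offs <- c(
    annotation = 11L, triads = 13L, expression = 23L, coding = 37L,
    interactions = 41L, terms = 53L, other = 71L
  )
  k <- offs[stage]
  if (is.na(k)) k <- offs[["other"]]
  as.integer((as.double(seed) * 7919 + k) %% 2147483647)
}

`%||%` <- rlang::`%||%`
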