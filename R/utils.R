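# Internal numeric helpers shared across modules.

#' Coerce input to a cells-by-features numeric matrix
#'
#' Accepts a numeric matrix, or a data frame whose first column may hold cell
#' identifiers (any non-numeric first column is treated as row names). Used by
#' every user-facing function so that tibbles read from disk can be piped in
#' directly.
#'
#' @param x A numeric matrix or a data frame.
#' @return A numeric matrix with optional `rownames` (cell ids) and
#'   `colnames` (feature ids).
#' @export
as_cell_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!is.numeric(x)) abort("matrix input must be numeric")
    m <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) >= 1 && !is.numeric(x[[1]])) {
      ids <- as.character(x[[1]])
      m <- as.matrix(x[, -1, drop = FALSE])
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
    }
    if (!is.numeric(m)) abort("all feature columns must be numeric")
  } else {
    abort("input must be a numeric matrix or data frame")
  }
  if (anyNA(m)) abort("input contains missing values")
  if (nrow(m) < 2) abort("need at least 2 cells (rows)")
  if (ncol(m) < 1) abort("need at least 1 feature (column)")
  rn <- rownames(m)
  if (!is.null(rn) && anyDuplicated(rn)) abort("cell identifiers must be unique")
  cn <- colnames(m)
  if (!is.null(cn) && anyDuplicated(cn)) abort("feature identifiers must be unique")
  storage.mode(m) <- "double"
  m
}

# Squared Euclidean distances between rows of x (and rows of y when given),
# via the Gram-matrix identity; clamped at zero against rounding.
pairwise_sq_dists <- function(x, y = NULL) {
  if (is.null(y)) {
    g <- tcrossprod(x)
    sq <- diag(g)
    d2 <- outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) - 2 * g
  } else {
    g <- tcrossprod(x, y)
    sqx <- rowSums(x^2)
    sqy <- rowSums(y^2)
    d2 <- outer(sqx, rep(1, length(sqy))) + outer(rep(1, length(sqx)), sqy) - 2 * g
  }
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest neighbours of each row (self excluded), one row
# per point, nearest first. Ties broken by lowest index (order() is stable).
knn_indices <- function(x, k) {
  d2 <- pairwise_sq_dists(x)
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

# Evaluate expr under a fixed RNG state when seed is given, without
# disturbing the caller's RNG; otherwise evaluate as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
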