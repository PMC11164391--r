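#' Denoise a data matrix by local averaging
#'
#' Replaces each cell's profile with the arithmetic mean of its `k1` nearest
#' neighbours under Euclidean distance, the point itself included as its own
#' zero-distance neighbour. Local averaging is a simple denoiser that is well
#' suited to manifold-plus-noise data and is the first stage of the
#' path-metric pipeline.
#'
#' With `k1 = 1` the output equals the input. Neighbour ties are broken by
#' lowest row index, so the operation is deterministic.
#'
#' @param x A cells-by-features numeric matrix or data frame
#'   (see [as_cell_matrix()]).
#' @param k1 Neighbourhood size (default 12), `1 <= k1 <= n`.
#' @return A numeric matrix of the same shape and dimnames as the input.
#' @examples
#' x <- matrix(c(0, 1, 10, 11), ncol = 1)
#' local_average(x, k1 = 2)  # rows become 0.5, 0.5, 10.5, 10.5
#' @export
local_average <- function(x, k1 = 12) {
  x <- as_cell_matrix(x)
  n <- nrow(x)
  k1 <- check_count(k1, "k1")
  if (k1 > n) abort(sprintf("`k1` (%d) cannot exceed the number of cells (%d)", k1, n))
  if (k1 == 1) return(x)

  d2 <- pairwise_sq_dists(x)
  # force self to sort first even among exact duplicates
  diag(d2) <- -1
  out <- x
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k1)]
    out[i, ] <- colMeans(x[nb, , drop = FALSE])
  }
  out
}
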