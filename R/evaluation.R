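#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table under the permutation model. Equals 1 for identical
#' partitions (up to relabeling) and has expectation ~0 for independent
#' ones.
#'
#' @param truth,pred Label vectors of equal length (any atomic type;
#'   [pm_clusters][constrained_kmeans()] objects are accepted).
#' @return A single number.
#' @export
adjusted_rand_index <- function(truth, pred) {
  truth <- label_vector(truth)
  pred <- label_vector(pred)
  if (length(truth) != length(pred)) abort("label vectors must have equal length")
  n <- length(truth)
  tab <- table(truth, pred)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

label_vector <- function(x) {
  if (inherits(x, "pm_clusters")) x$labels else as.vector(x)
}

#' Entropy of cluster purity and accuracy
#'
#' ECP is the mean over predicted clusters of the Shannon entropy of the
#' true-label distribution within the cluster; ECA is the mean over true
#' classes of the entropy of the predicted-label distribution within the
#' class. Both are zero exactly when the partitions refine each other
#' perfectly in the respective direction; lower is better.
#'
#' @inheritParams adjusted_rand_index
#' @param base Logarithm base for the entropies (default natural log).
#' @param weighted If `TRUE`, clusters/classes are weighted by their size
#'   instead of averaged uniformly.
#' @return A one-row tibble with columns `ecp` and `eca`.
#' @export
entropy_metrics <- function(truth, pred, base = exp(1), weighted = FALSE) {
  truth <- label_vector(truth)
  pred <- label_vector(pred)
  if (length(truth) != length(pred)) abort("label vectors must have equal length")
  tibble::tibble(
    ecp = group_entropy(split(truth, pred), base, weighted),
    eca = group_entropy(split(pred, truth), base, weighted)
  )
}

group_entropy <- function(groups, base, weighted) {
  ent <- vapply(groups, function(g) {
    p <- table(g) / length(g)
    -sum(p * log(p, base = base))
  }, numeric(1))
  if (weighted) {
    w <- vapply(groups, length, numeric(1))
    sum(w * ent) / sum(w)
  } else {
    mean(ent)
  }
}

#' Geometric perturbation of an embedding
#'
#' Measures how well an embedding preserves the global layout of the
#' clusters. Cluster means are computed with the ground-truth labels in the
#' original space `X` and in the embedding `Y`; the between-mean distance
#' matrices are compared after an optimal uniform rescaling:
#' `pi = min_c ||D_X - c D_Y||_F^2 / ||D_X||_F^2`, with the closed form
#' `c* = <D_X, D_Y> / ||D_Y||_F^2`. Here `D_.(i,j)` is the distance between
#' the means of the clusters of cells `i` and `j`; the computation uses the
#' equivalent cluster-level form with cluster-pair-count weights, so memory
#' stays linear in `n`. `pi` is zero iff the two mean configurations are
#' proportional, and is invariant to rotation, translation and uniform
#' scaling of either space.
#'
#' @param x Original data (matrix or data frame).
#' @param y Embedding: a `pm_embedding`, matrix, or data frame.
#' @param truth Ground-truth labels (vector or `pm_clusters`).
#' @return An object of class `pm_perturbation`: list with `pi` and the
#'   optimal scale `c_star`.
#' @export
geometric_perturbation <- function(x, y, truth) {
  x <- as_cell_matrix(x)
  y <- coords_matrix(y)
  truth <- label_vector(truth)
  if (length(truth) != nrow(x) || nrow(x) != nrow(y)) {
    abort("`x`, `y` and `truth` must agree on the number of cells")
  }
  labels <- relabel_consecutive(as.integer(factor(truth)))
  k <- max(labels)
  if (k < 2) abort("need at least 2 clusters")
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0)) abort("every cluster must be non-empty")

  mx <- cluster_means(x, labels)
  my <- cluster_means(y, labels)
  dx <- sqrt(pairwise_sq_dists(mx))
  dy <- sqrt(pairwise_sq_dists(my))
  w <- outer(sizes, sizes) # pair counts of the implicit n x n construction

  dy_norm <- sum(w * dy^2)
  if (dy_norm == 0) {
    abort("all cluster means coincide in the embedding; the perturbation is undefined (as for concentric clusters sharing a mean)")
  }
  dx_norm <- sum(w * dx^2)
  if (dx_norm == 0) {
    abort("all cluster means coincide in the original space; the perturbation is undefined")
  }
  c_star <- sum(w * dx * dy) / dy_norm
  pi_val <- sum(w * (dx - c_star * dy)^2) / dx_norm
  structure(list(pi = pi_val, c_star = c_star), class = "pm_perturbation")
}

#' @export
print.pm_perturbation <- function(x, ...) {
  cat(sprintf("<pm_perturbation> pi = %.6g (c* = %.6g)\n", x$pi, x$c_star))
  invisible(x)
}

#' Elongation score of a data set
#'
#' Sample skewness of the k-th nearest-neighbour distances, with
#' `k = round(10 * log(n))` (natural log, clamped to `[1, n - 1]`):
#' `G1 = n / ((n - 1)(n - 2)) * sum(((d_i - mean) / s)^3)`, where `s` is the
#' sample standard deviation. Elongated or anisotropic data leave a
#' right-skewed tail of large neighbour distances, so larger `G1` indicates
#' stronger elongation; it is fully unsupervised and can guide the choice
#' of the path-metric power `p`.
#'
#' @param x Data matrix or data frame, `n >= 3` rows.
#' @param k_nn Override for the neighbour index `k` (default
#'   `round(10 * log(n))`).
#' @return An object of class `pm_elongation`: list with `g1`, `k_nn`,
#'   `mean_dist`, `sd_dist`, and the vector `knn_dist` of the `n` k-th
#'   neighbour distances.
#' @export
elongation_score <- function(x, k_nn = NULL) {
  x <- as_cell_matrix(x)
  n <- nrow(x)
  if (n < 3) abort("need at least 3 cells")
  if (is.null(k_nn)) k_nn <- round(10 * log(n))
  k_nn <- max(1L, min(as.integer(k_nn), n - 1L))

  d2 <- pairwise_sq_dists(x)
  diag(d2) <- Inf
  dk <- apply(d2, 1, function(r) sqrt(sort(r, partial = k_nn)[k_nn]))
  m <- mean(dk)
  s <- stats::sd(dk)
  if (s == 0) {
    warn("all k-th neighbour distances are equal; G1 set to 0")
    g1 <- 0
  } else {
    g1 <- n / ((n - 1) * (n - 2)) * sum(((dk - m) / s)^3)
  }
  structure(
    list(g1 = g1, k_nn = k_nn, mean_dist = m, sd_dist = s, knn_dist = dk),
    class = "pm_elongation"
  )
}

#' @export
print.pm_elongation <- function(x, ...) {
  cat(sprintf("<pm_elongation> G1 = %.4f (k = %d, mean = %.4g, sd = %.4g)\n",
              x$g1, x$k_nn, x$mean_dist, x$sd_dist))
  invisible(x)
}

#' All clustering-quality metrics at once
#'
#' Convenience wrapper returning ARI, ECP and ECA in one tidy row.
#'
#' @inheritParams entropy_metrics
#' @return A one-row tibble with columns `ari`, `ecp`, `eca`.
#' @export
evaluate_clustering <- function(truth, pred, base = exp(1), weighted = FALSE) {
  em <- entropy_metrics(truth, pred, base = base, weighted = weighted)
  dplyr::bind_cols(tibble::tibble(ari = adjusted_rand_index(truth, pred)), em)
}
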