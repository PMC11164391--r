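#' Size-constrained k-means
#'
#' Runs k-means with multiple random (k-means++) initializations, keeping
#' the best inertia, and enforces a minimum cluster size: while any cluster
#' is smaller than `min_size`, the number of fitted clusters is increased by
#' one, the fit repeated, and each tiny cluster merged into the non-tiny
#' cluster with the nearest centroid, until exactly `k` clusters all meet
#' `min_size` or a retry cap (10) is reached. This prevents outliers from
#' claiming singleton clusters while still allowing them to be absorbed by
#' their nearest population.
#'
#' @param y A `pm_embedding` or a numeric matrix of coordinates.
#' @param k Target number of clusters, `k >= 2`.
#' @param replicates Number of random initializations (default 20).
#' @param min_size Minimum cluster size. Default `ceiling(sqrt(n) / 2)`.
#'   Set to `0` (or `"none"`) for plain unconstrained k-means, useful when
#'   genuinely small clusters are expected.
#' @param seed Optional integer seed; fixing it makes the labels
#'   reproducible.
#' @return An object of class `pm_clusters`: integer `labels` in `1..k`,
#'   `k`, the `centers` matrix, cluster `sizes`, the within-cluster sum of
#'   squares `inertia`, and `source = "estimated"`.
#' @export
constrained_kmeans <- function(y, k, replicates = 20, min_size = NULL, seed = NULL) {
  y <- coords_matrix(y)
  n <- nrow(y)
  k <- check_count(k, "k", min = 2L)
  replicates <- check_count(replicates, "replicates")
  if (n < 2 * k) abort(sprintf("need at least 2k observations (n = %d, k = %d)", n, k))
  if (is.null(min_size)) min_size <- ceiling(sqrt(n) / 2)
  if (identical(min_size, "none")) min_size <- 0L
  min_size <- check_count(min_size, "min_size", min = 0L)
  if (k * max(min_size, 1L) > n) {
    abort(sprintf("infeasible: k * min_size = %d exceeds n = %d", k * min_size, n))
  }

  with_seed_if(seed, {
    fit <- kmeans_replicated(y, k, replicates)
    labels <- fit$cluster
    centers <- fit$centers
    if (min_size > 0) {
      k_try <- k
      attempts <- 0L
      repeat {
        merged <- merge_tiny(labels, centers, min_size)
        # an incremented fit can come back with every cluster already large;
        # fold the smallest into its nearest neighbour to land on exactly k
        while (nrow(merged$centers) > k) {
          merged <- merge_smallest(merged$labels, merged$centers)
        }
        labels <- merged$labels
        centers <- merged$centers
        sizes <- tabulate(labels, nbins = nrow(centers))
        if (length(sizes) == k && all(sizes >= min_size)) break
        attempts <- attempts + 1L
        if (attempts >= 10L) {
          warn("cluster-size constraint not satisfiable in 10 attempts; returning best labels")
          break
        }
        k_try <- k_try + 1L
        if (k_try * min_size > n || n < 2 * k_try) {
          warn("cannot increase k further under the size constraint; returning best labels")
          break
        }
        fit <- kmeans_replicated(y, k_try, replicates)
        labels <- fit$cluster
        centers <- fit$centers
      }
    }
    new_pm_clusters(labels, y)
  })
}

coords_matrix <- function(y) {
  if (inherits(y, "pm_embedding")) y$coordinates
  else if (is.matrix(y) && is.numeric(y)) y
  else if (is.data.frame(y)) as_cell_matrix(y)
  else abort("`y` must be a pm_embedding or a numeric matrix")
}

new_pm_clusters <- function(labels, y, source = "estimated") {
  labels <- relabel_consecutive(labels)
  k <- max(labels)
  centers <- cluster_means(y, labels)
  inertia <- sum((y - centers[labels, , drop = FALSE])^2)
  structure(
    list(labels = labels, k = k, centers = centers,
         sizes = tabulate(labels, nbins = k), inertia = inertia,
         source = source),
    class = "pm_clusters"
  )
}

#' @export
print.pm_clusters <- function(x, ...) {
  cat(sprintf("<pm_clusters> %d cells in %d clusters (%s); sizes: %s\n",
              length(x$labels), x$k, x$source, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

relabel_consecutive <- function(labels) {
  as.integer(factor(labels, levels = sort(unique(labels))))
}

cluster_means <- function(y, labels) {
  ks <- sort(unique(labels))
  m <- t(vapply(ks, function(g) colMeans(y[labels == g, , drop = FALSE]),
                numeric(ncol(y))))
  if (ncol(y) == 1) m <- matrix(m, ncol = 1)
  rownames(m) <- ks
  m
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(y, k) {
  n <- nrow(y)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- pairwise_sq_dists(y, y[centers[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L)) {
    tot <- sum(d2)
    centers[j + 1L] <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2 / tot)
    d2 <- pmin(d2, pairwise_sq_dists(y, y[centers[j + 1L], , drop = FALSE])[, 1])
  }
  y[centers, , drop = FALSE]
}

kmeans_replicated <- function(y, k, replicates) {
  best <- NULL
  for (rep in seq_len(replicates)) {
    init <- kmeanspp_centers(y, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(y, centers = init, iter.max = 100L)),
      error = function(e) suppressWarnings(stats::kmeans(y, centers = k, iter.max = 100L))
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# Merge every cluster below min_size into the nearest (by centroid) cluster
# meeting the threshold; ties broken by lowest cluster index.
merge_tiny <- function(labels, centers, min_size) {
  sizes <- tabulate(labels, nbins = nrow(centers))
  tiny <- which(sizes < min_size)
  big <- which(sizes >= min_size)
  if (length(tiny) == 0 || length(big) == 0) {
    return(list(labels = relabel_consecutive(labels), centers = centers))
  }
  for (tc in tiny) {
    d2 <- pairwise_sq_dists(centers[tc, , drop = FALSE], centers[big, , drop = FALSE])[1, ]
    target <- big[which.min(d2)] # which.min takes the first (lowest index) on ties
    labels[labels == tc] <- target
  }
  keep <- sort(unique(labels))
  list(labels = relabel_consecutive(labels),
       centers = centers[keep, , drop = FALSE])
}

merge_smallest <- function(labels, centers) {
  sizes <- tabulate(labels, nbins = nrow(centers))
  tc <- which.min(sizes)
  others <- setdiff(seq_len(nrow(centers)), tc)
  d2 <- pairwise_sq_dists(centers[tc, , drop = FALSE], centers[others, , drop = FALSE])[1, ]
  labels[labels == tc] <- others[which.min(d2)]
  keep <- sort(unique(labels))
  list(labels = relabel_consecutive(labels),
       centers = centers[keep, , drop = FALSE])
}

#' Choose the number of clusters by the silhouette criterion
#'
#' Runs [constrained_kmeans()] for each candidate `k` and returns the one
#' maximizing the mean silhouette width in the embedding coordinates
#' (Euclidean distance).
#'
#' @inheritParams constrained_kmeans
#' @param k_candidates Integer vector of candidate cluster counts, each
#'   `>= 2` (a singleton candidate is returned as-is).
#' @return The selected `k` (integer) with attribute `"silhouette"`: a
#'   tibble of candidates and their mean silhouette widths.
#' @export
select_k_silhouette <- function(y, k_candidates, replicates = 20,
                                min_size = NULL, seed = NULL) {
  y <- coords_matrix(y)
  if (length(k_candidates) == 0) abort("`k_candidates` must be non-empty")
  k_candidates <- vapply(k_candidates, check_count, integer(1), name = "k_candidates", min = 2L)
  if (length(k_candidates) == 1) {
    out <- k_candidates[[1]]
    attr(out, "silhouette") <- tibble::tibble(k = out, mean_silhouette = NA_real_)
    return(out)
  }
  dy <- stats::dist(y)
  widths <- vapply(seq_along(k_candidates), function(i) {
    cl <- constrained_kmeans(y, k_candidates[i], replicates = replicates,
                             min_size = min_size,
                             seed = if (is.null(seed)) NULL else seed + i - 1L)
    if (cl$k < 2) return(-Inf)
    sil <- cluster::silhouette(cl$labels, dy)
    mean(sil[, "sil_width"])
  }, numeric(1))
  out <- k_candidates[which.max(widths)]
  attr(out, "silhouette") <- tibble::tibble(k = k_candidates, mean_silhouette = widths)
  out
}
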