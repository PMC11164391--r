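#' Path-metric profiling: embed and cluster in one call
#'
#' Runs the full pipeline: local-averaging denoising, power-weighted
#' K-nearest-neighbour graph, all-pairs (or landmark) path distances,
#' classical MDS with eigenratio dimension selection, and size-constrained
#' k-means. Defaults follow the standard parameterization: `k1 = 12`,
#' `k2 = min(n, 500)`, `r_min = 3`, `r_max = 39`, `tau = 0.01`, 20 k-means
#' replicates.
#'
#' @param x Cells-by-features matrix or data frame (already normalized), or
#'   a `pm_dataset`.
#' @param k Number of clusters, or `"auto"` to select by the silhouette
#'   criterion over `k_candidates`.
#' @param p Path-metric power (default 2). Moderate values balance density
#'   sensitivity against geometry preservation; raise `p` for strongly
#'   elongated data.
#' @param k1 Denoising neighbourhood size (default 12).
#' @param k2 Graph neighbourhood size (default `min(n - 1, 500)`).
#' @param r Embedding dimension; `NULL` (default) selects it from the
#'   spectrum.
#' @param r_min,r_max,tau Dimension-selection parameters.
#' @param replicates k-means replicates (default 20).
#' @param min_size Minimum cluster size (default `ceiling(sqrt(n) / 2)`;
#'   `0` disables the constraint).
#' @param landmarks Number of landmarks for the quasi-linear approximation;
#'   `NULL` (default) computes all pairwise distances.
#' @param scaling Eigenvector scaling for the embedding, see [mds_embed()].
#' @param k_candidates Candidate cluster counts when `k = "auto"`
#'   (default `2:9`).
#' @param seed Optional integer seed covering landmark selection and
#'   k-means.
#' @return An object of class `pm_fit`: list with `embedding`
#'   (`pm_embedding`), `clusters` (`pm_clusters`), and `report` (resolved
#'   parameters, selected `r` and `k`, connectivity, stage timings in
#'   seconds).
#' @examples
#' \donttest{
#' toy <- simulate_balls(n = 120, seed = 1)
#' fit <- pm_profile(toy, k = 3, seed = 1)
#' adjusted_rand_index(toy$labels, fit$clusters)
#' }
#' @export
pm_profile <- function(x, k, p = 2, k1 = 12, k2 = NULL, r = NULL,
                       r_min = 3, r_max = 39, tau = 0.01, replicates = 20,
                       min_size = NULL, landmarks = NULL,
                       scaling = c("sqrt_eigenvalue", "eigenvalue"),
                       k_candidates = 2:9, seed = NULL) {
  scaling <- match.arg(scaling)
  if (inherits(x, "pm_dataset")) x <- x$x
  x <- as_cell_matrix(x)
  n <- nrow(x)
  auto_k <- identical(k, "auto")
  if (!auto_k) k <- check_count(k, "k", min = 2L)

  timings <- c()
  tick <- function(label, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[label]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }

  denoised <- tick("denoise", local_average(x, k1 = k1))
  if (is.null(landmarks)) {
    g <- tick("graph", knn_graph(denoised, k2 = k2, p = p))
    d <- tick("path_distances", path_distances(g))
    if (!d$connected) {
      abort("path-metric graph is disconnected; increase `k2` or inspect the input")
    }
    emb <- tick("mds", mds_embed(d, r = r, r_min = r_min, r_max = r_max,
                                 tau = tau, scaling = scaling))
  } else {
    q <- check_count(landmarks, "landmarks")
    d <- tick("path_distances",
              landmark_path_distances(denoised, q = q, k2 = k2, p = p, seed = seed))
    if (!d$connected) {
      abort("path-metric graph is disconnected; increase `k2` or inspect the input")
    }
    emb <- tick("mds", landmark_mds_embed(d, r = r, r_min = r_min, r_max = r_max,
                                          tau = tau, scaling = scaling))
  }

  if (auto_k) {
    k <- tick("select_k",
              as.integer(select_k_silhouette(emb, k_candidates,
                                             replicates = replicates,
                                             min_size = min_size, seed = seed)))
  }
  cl <- tick("kmeans", constrained_kmeans(emb, k = k, replicates = replicates,
                                          min_size = min_size, seed = seed))

  structure(
    list(
      embedding = emb,
      clusters = cl,
      report = list(
        n = n, d = ncol(x), p = p, k1 = k1,
        k2 = d$k2, r = emb$r, k = k,
        landmarks = if (is.null(landmarks)) NA_integer_ else length(d$landmarks),
        scaling = scaling, connected = d$connected,
        min_size = if (is.null(min_size)) ceiling(sqrt(n) / 2) else min_size,
        seed = seed, timings = unlist(timings)
      )
    ),
    class = "pm_fit"
  )
}

#' @export
print.pm_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pm_fit> n = %d, d = %d | p = %g, k1 = %d, k2 = %d%s\n  embedding: r = %d (%s)\n  clusters: k = %d, sizes %s\n  total time: %.1fs\n",
    r$n, r$d, r$p, r$k1, r$k2,
    if (is.na(r$landmarks)) "" else sprintf(", %d landmarks", r$landmarks),
    r$r, r$scaling, r$k, paste(x$clusters$sizes, collapse = ", "),
    sum(r$timings)
  ))
  invisible(x)
}
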