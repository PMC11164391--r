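#' Build the power-weighted K-nearest-neighbour graph
#'
#' Constructs the undirected graph underlying the p-power path metric: nodes
#' are cells, and an edge joins `i` and `j` whenever `i` is among the `k2`
#' nearest neighbours of `j` or vice versa (symmetrized union). Each edge
#' carries weight `||x_i - x_j||^p`, so that shortest paths on the graph
#' compute the discrete p-power path metric. `p = 1` recovers plain graph
#' (approximate geodesic) distances; large `p` approaches the bottleneck
#' distance.
#'
#' @param x A cells-by-features numeric matrix or data frame.
#' @param k2 Neighbourhood size; default `min(n - 1, 500)`. Values `>= n`
#'   are clamped to `n - 1` with a warning.
#' @param p Path-metric power, `p >= 1` (default 2).
#' @return An object of class `pm_graph`: a list with the `igraph` graph
#'   (edge attribute `weight` holding the powered lengths), `n`, `p`, `k2`,
#'   and the cell ids.
#' @seealso [path_distances()], [landmark_path_distances()]
#' @export
knn_graph <- function(x, k2 = NULL, p = 2) {
  x <- as_cell_matrix(x)
  n <- nrow(x)
  if (is.null(k2)) k2 <- min(n - 1L, 500L)
  k2 <- check_count(k2, "k2")
  if (k2 >= n) {
    warn(sprintf("`k2` (%d) >= n (%d); clamping to n - 1", k2, n))
    k2 <- n - 1L
  }
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 1) {
    abort("`p` must be a single number >= 1")
  }

  d2 <- pairwise_sq_dists(x)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k2)]))
  edges <- cbind(rep(seq_len(n), each = k2), as.vector(t(nn)))
  w <- d2[edges]^(p / 2) # ||x_i - x_j||^p

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  # the union symmetrization duplicates mutual-NN edges; weights identical
  g <- igraph::simplify(g, edge.attr.comb = "min")

  structure(
    list(graph = g, n = n, p = p, k2 = k2, cell_ids = rownames(x)),
    class = "pm_graph"
  )
}

#' @export
print.pm_graph <- function(x, ...) {
  cat(sprintf(
    "<pm_graph> %d nodes, %d edges (k2 = %d, p = %g)\n",
    x$n, igraph::ecount(x$graph), x$k2, x$p
  ))
  invisible(x)
}

new_pm_dist <- function(values, p, k2, landmarks = NULL) {
  connected <- all(is.finite(values))
  structure(
    list(values = values, p = p, k2 = k2, connected = connected,
         landmarks = landmarks),
    class = "pm_dist"
  )
}

#' @export
print.pm_dist <- function(x, ...) {
  cat(sprintf(
    "<pm_dist> %d x %d path distances (p = %g, k2 = %d, %s)%s\n",
    nrow(x$values), ncol(x$values), x$p, x$k2,
    if (x$connected) "connected" else "DISCONNECTED",
    if (is.null(x$landmarks)) "" else sprintf(" [%d landmarks]", length(x$landmarks))
  ))
  invisible(x)
}

#' All-pairs path-metric distances
#'
#' Runs Dijkstra's algorithm from every node of a power-weighted KNN graph
#' and takes the 1/p root of the summed powered edge lengths, yielding the
#' discrete p-power path metric between all pairs of cells.
#'
#' @param g A `pm_graph` from [knn_graph()].
#' @return An object of class `pm_dist` holding the symmetric `n x n`
#'   distance matrix `values`, the parameters `p` and `k2`, and a
#'   `connected` flag. Unreachable pairs are `Inf` and `connected` is set to
#'   `FALSE` with a warning naming the number of components; downstream MDS
#'   refuses such input.
#' @export
path_distances <- function(g) {
  stopifnot(inherits(g, "pm_graph"))
  d <- igraph::distances(g$graph, algorithm = "dijkstra")
  d <- d^(1 / g$p)
  dimnames(d) <- list(g$cell_ids, g$cell_ids)
  res <- new_pm_dist(d, p = g$p, k2 = g$k2)
  if (!res$connected) {
    nc <- igraph::components(g$graph)$no
    warn(sprintf("KNN graph is disconnected (%d components); some path distances are infinite", nc))
  }
  res
}

#' Path distances from a random set of landmarks
#'
#' The quasi-linear fast path: instead of all `n` single-source searches,
#' Dijkstra is run only from `q` landmark cells drawn uniformly without
#' replacement, on the same symmetrized KNN graph of the full data. Each row
#' of the result is exactly the corresponding row of the full path-distance
#' matrix.
#'
#' @inheritParams knn_graph
#' @param q Number of landmarks, `1 <= q <= n`.
#' @param seed Optional integer seed for the landmark draw.
#' @return A `pm_dist` whose `values` is `q x n`, with `landmarks` holding
#'   the drawn row indices.
#' @export
landmark_path_distances <- function(x, q, k2 = NULL, p = 2, seed = NULL) {
  x <- as_cell_matrix(x)
  n <- nrow(x)
  q <- check_count(q, "q")
  if (q > n) abort(sprintf("`q` (%d) cannot exceed the number of cells (%d)", q, n))
  g <- knn_graph(x, k2 = k2, p = p)
  landmarks <- with_seed_if(seed, sort(sample.int(n, q)))
  d <- igraph::distances(g$graph, v = landmarks, algorithm = "dijkstra")
  d <- d^(1 / g$p)
  dimnames(d) <- list(g$cell_ids[landmarks], g$cell_ids)
  res <- new_pm_dist(d, p = g$p, k2 = g$k2, landmarks = landmarks)
  if (!res$connected) {
    nc <- igraph::components(g$graph)$no
    warn(sprintf("KNN graph is disconnected (%d components); some path distances are infinite", nc))
  }
  res
}

#' Export a path-distance matrix as CSV
#'
#' Writes the distance matrix with cell identifiers as header and first
#' column.
#'
#' @param d A `pm_dist`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_path_distances <- function(d, path) {
  stopifnot(inherits(d, "pm_dist"))
  v <- d$values
  ids_row <- rownames(v) %||% as.character(seq_len(nrow(v)))
  ids_col <- colnames(v) %||% as.character(seq_len(ncol(v)))
  df <- as.data.frame(v)
  names(df) <- ids_col
  df <- cbind(cell_id = ids_row, df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
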