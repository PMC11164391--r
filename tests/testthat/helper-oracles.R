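# Independent brute-force oracles used to verify the fast implementations.

# All-simple-paths p-power path metric between every pair, by exhaustive
# depth-first enumeration on an explicit edge list. Exponential; for tiny n.
brute_force_path_metric <- function(x, edges, p) {
  n <- nrow(x)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  edge_cost <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))^p
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(node, target, visited, cost) {
    if (cost >= best[start, target]) return(invisible())
    if (node == target) {
      best[start, target] <<- cost
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        dfs(nb, target, visited, cost + edge_cost(node, nb))
        visited[nb] <- FALSE
      }
    }
  }
  for (start in seq_len(n)) {
    for (target in seq_len(n)) {
      if (start != target) {
        visited <- rep(FALSE, n)
        visited[start] <- TRUE
        dfs(start, target, visited, 0)
      }
    }
  }
  best^(1 / p)
}

# Minimax (bottleneck) distance: minimal over paths of the maximal single
# Euclidean edge length, by exhaustive enumeration.
brute_force_bottleneck <- function(x, edges) {
  n <- nrow(x)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  edge_len <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(node, target, visited, worst) {
    if (worst >= best[start, target]) return(invisible())
    if (node == target) {
      best[start, target] <<- worst
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        dfs(nb, target, visited, max(worst, edge_len(node, nb)))
        visited[nb] <- FALSE
      }
    }
  }
  for (start in seq_len(n)) {
    for (target in seq_len(n)) {
      if (start != target) {
        visited <- rep(FALSE, n)
        visited[start] <- TRUE
        dfs(start, target, visited, 0)
      }
    }
  }
  best
}

# Edge list of a pm_graph as a two-column matrix of node indices.
graph_edges <- function(g) igraph::as_edgelist(g$graph, names = FALSE)

# ARI by direct pair counting over all n(n-1)/2 pairs: agreements under the
# permutation-model correction, independent of the contingency-table form.
brute_force_ari <- function(truth, pred) {
  n <- length(truth)
  same_t <- outer(truth, truth, "==")[upper.tri(diag(n))]
  same_p <- outer(pred, pred, "==")[upper.tri(diag(n))]
  n11 <- sum(same_t & same_p)
  n00 <- sum(!same_t & !same_p)
  n10 <- sum(same_t & !same_p)
  n01 <- sum(!same_t & same_p)
  # Hubert-Arabie closed form on the four pair counts
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# Gaussian blobs around given centers; returns list(x, labels).
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
    }))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# Residual after optimal rigid alignment (rotation + translation + scale)
# of configuration b onto a.
procrustes_residual <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  rot <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(b^2)
  sqrt(sum((a - scl * b %*% rot)^2) / sum(a^2))
}
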