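# Seeded generators for the benchmark suites: four manifold toys with known
# cluster structure, and a simulated droplet-style count matrix. Every shape
# parameter is an argument with a fixed, documented default, so the default
# call reproduces the benchmark conditions and nothing is hard-coded.

new_pm_dataset <- function(x, labels, spec) {
  rownames(x) <- sprintf("cell%d", seq_len(nrow(x)))
  colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  structure(
    list(x = x, labels = as.integer(labels), spec = spec),
    class = "pm_dataset"
  )
}

#' @export
print.pm_dataset <- function(x, ...) {
  cat(sprintf("<pm_dataset> %s: %d cells x %d features, %d clusters (sizes %s)\n",
              x$spec$name, nrow(x$x), ncol(x$x), length(unique(x$labels)),
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}

# round-robin split of n into k parts (first parts get the remainder)
split_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Three overlapping uniform balls
#'
#' Planar benchmark with good geometric but no density separation: points
#' are sampled uniformly from three unit disks whose centers sit at mutual
#' distance 1.95, so the supports pairwise overlap and the Bayes-optimal ARI
#' is below 1.
#'
#' @param n Total number of points (default 1200, split evenly).
#' @param radius Disk radius (default 1).
#' @param center_dist Mutual distance between disk centers (default 1.95).
#' @param seed Optional integer seed.
#' @return A `pm_dataset`: list with the `n x 2` matrix `x`, integer
#'   `labels` (ball of origin), and the resolved `spec`.
#' @export
simulate_balls <- function(n = 1200, radius = 1, center_dist = 1.95, seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  centers <- center_dist * rbind(
    c(0, 0),
    c(1, 0),
    c(0.5, sqrt(3) / 2)
  ) # equilateral triangle, side center_dist
  sizes <- split_sizes(n, 3L)
  with_seed_if(seed, {
    pts <- lapply(1:3, function(j) {
      r <- radius * sqrt(runif(sizes[j]))
      th <- runif(sizes[j], 0, 2 * pi)
      cbind(centers[j, 1] + r * cos(th), centers[j, 2] + r * sin(th))
    })
    x <- do.call(rbind, pts)
    labels <- rep(1:3, sizes)
    new_pm_dataset(x, labels, list(
      name = "balls", n = n, d = 2L, k = 3L, radius = radius,
      center_dist = center_dist, seed = seed
    ))
  })
}

#' Elongated Gaussians with a bridge
#'
#' Three strongly anisotropic Gaussian clusters, elongated along a common
#' axis, plus a thin uniform bridge of points connecting two of them. The
#' elongation defeats plain k-means (which cuts across the long axis) and
#' the bridge defeats purely density-based methods; bridge points carry the
#' label of the nearer bridged cluster.
#'
#' @param n Total number of points including the bridge (default 620).
#' @param n_bridge Number of bridge points (default 20; 0 gives a plain
#'   mixture).
#' @param sd_long,sd_short Standard deviations along/across the long axis
#'   (defaults 12 and 0.6; axis ratio 20:1).
#' @param cluster_gap Distance between the parallel cluster axes
#'   (default 12).
#' @param bridge_sd Lateral jitter of the bridge points (default 0.15).
#' @param seed Optional integer seed.
#' @return A `pm_dataset` with `n x 2` coordinates and labels 1..3.
#' @export
simulate_ewb <- function(n = 620, n_bridge = 20, sd_long = 12, sd_short = 0.6,
                         cluster_gap = 12, bridge_sd = 0.15, seed = NULL) {
  n <- check_count(n, "n", min = 6L)
  n_bridge <- check_count(n_bridge, "n_bridge", min = 0L)
  if (n_bridge >= n) abort("`n_bridge` must be smaller than `n`")
  sizes <- split_sizes(n - n_bridge, 3L)
  centers_y <- cluster_gap * (0:2)
  with_seed_if(seed, {
    pts <- lapply(1:3, function(j) {
      cbind(rnorm(sizes[j], 0, sd_long), rnorm(sizes[j], centers_y[j], sd_short))
    })
    labels <- rep(1:3, sizes)
    if (n_bridge > 0) {
      # straight bridge between clusters 1 and 2 at x = 0
      by <- seq(0, cluster_gap, length.out = n_bridge + 2)[-c(1, n_bridge + 2)]
      bx <- rnorm(n_bridge, 0, bridge_sd)
      pts <- c(pts, list(cbind(bx, by)))
      labels <- c(labels, ifelse(by < cluster_gap / 2, 1L, 2L))
    }
    x <- do.call(rbind, pts)
    new_pm_dataset(x, labels, list(
      name = "ewb", n = n, d = 2L, k = 3L, n_bridge = n_bridge,
      sd_long = sd_long, sd_short = sd_short, cluster_gap = cluster_gap,
      bridge_sd = bridge_sd, seed = seed
    ))
  })
}

#' Swiss roll with three angular bands
#'
#' Uniform sampling from three disjoint angular regions of the standard
#' Swiss-roll surface `(t cos t, h, t sin t)`, with isotropic Gaussian noise
#' added in all three coordinates. The bands are intertwined geometrically
#' but separated by density gaps along the roll parameter.
#'
#' @param n Total points (default 1275, split evenly over the bands).
#' @param noise_sd Isotropic noise standard deviation (default 0.75).
#' @param t_range Range of the roll parameter (default `c(1.5, 4.5) * pi`).
#' @param gap Gap in the roll parameter between consecutive bands
#'   (default 1.0).
#' @param height Height of the roll (default 21).
#' @param seed Optional integer seed.
#' @return A `pm_dataset` with `n x 3` coordinates and band labels 1..3.
#' @export
simulate_swiss_roll <- function(n = 1275, noise_sd = 0.75,
                                t_range = c(1.5 * pi, 4.5 * pi), gap = 1.0,
                                height = 21, seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  span <- diff(t_range)
  width <- (span - 2 * gap) / 3
  if (width <= 0) abort("`gap` too large for `t_range`")
  starts <- t_range[1] + (0:2) * (width + gap)
  sizes <- split_sizes(n, 3L)
  with_seed_if(seed, {
    pts <- lapply(1:3, function(j) {
      t <- runif(sizes[j], starts[j], starts[j] + width)
      h <- runif(sizes[j], 0, height)
      cbind(t * cos(t), h, t * sin(t))
    })
    x <- do.call(rbind, pts)
    if (noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x))
    labels <- rep(1:3, sizes)
    new_pm_dataset(x, labels, list(
      name = "swiss_roll", n = n, d = 3L, k = 3L, noise_sd = noise_sd,
      t_range = t_range, gap = gap, height = height, seed = seed
    ))
  })
}

# Default eigenvalue triples for the rotation-orbit benchmark. All three
# share trace 6, so every orbit has mean 2*I and linear projections show no
# cluster separation (k-means on the raw data fails). Each triple has a
# repeated eigenvalue, so its conjugation orbit is a 2-sphere that 1000
# samples cover densely, while the minimal distance between two orbits --
# the Euclidean distance between their sorted spectra -- stays large
# (sqrt(6), sqrt(6), sqrt(18) pairwise): the clusters are separated by
# density, not by their first two moments.
so3_default_triples <- function() {
  rbind(c(1, 1, 4), c(0, 3, 3), c(0, 0, 6))
}

#' Rotation orbits of symmetric matrices in high dimension
#'
#' For each cluster a fixed eigenvalue triple `D_i` is conjugated by random
#' rotations `V` in SO(3); the `3 x 3` symmetric matrices `V D_i V'` are
#' flattened to 9 coordinates, embedded isometrically into `d` dimensions,
#' and perturbed by uniform noise of standard deviation `noise_sd` in every
#' dimension. The default triples share their trace, so all clusters share
#' the same mean and linear methods see no separation, while the orbits lie
#' on well-separated spheres and are density-separated.
#'
#' @param n Total points (default 3000, split evenly over 3 orbits).
#' @param d Ambient dimension (default 1000).
#' @param noise_sd Uniform noise standard deviation (default 0.0075).
#' @param triples A `3 x 3` matrix of eigenvalue triples, one row per
#'   cluster (default [so3_default_triples()]).
#' @param seed Optional integer seed.
#' @return A `pm_dataset` with `n x d` coordinates and orbit labels 1..3.
#' @export
simulate_so3 <- function(n = 3000, d = 1000, noise_sd = 0.0075,
                         triples = so3_default_triples(), seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  d <- check_count(d, "d", min = 9L)
  triples <- as.matrix(triples)
  stopifnot(nrow(triples) == 3, ncol(triples) == 3)
  sizes <- split_sizes(n, 3L)
  with_seed_if(seed, {
    x <- matrix(0, n, d)
    row <- 0L
    for (j in 1:3) {
      dj <- diag(triples[j, ])
      for (i in seq_len(sizes[j])) {
        v <- random_rotation3()
        m <- v %*% dj %*% t(v)
        x[row + i, 1:9] <- as.vector(m)
      }
      row <- row + sizes[j]
    }
    if (noise_sd > 0) {
      a <- noise_sd * sqrt(3) # uniform on [-a, a] has sd a/sqrt(3)
      x <- x + matrix(runif(n * d, -a, a), n, d)
    }
    labels <- rep(1:3, sizes)
    new_pm_dataset(x, labels, list(
      name = "so3", n = n, d = d, k = 3L, noise_sd = noise_sd,
      triples = triples, seed = seed
    ))
  })
}

# Haar-ish random rotation: QR of a Gaussian matrix with the sign convention
# fixed and determinant forced to +1.
random_rotation3 <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulated marker-gene count matrix with dropout
#'
#' A droplet-style count benchmark: a base mean-expression profile is drawn
#' per gene (log-normal, standing in for a homogeneous reference cell
#' population), a fraction of genes is designated as markers and split
#' evenly across `k` clusters, the marker means are scaled up in their
#' cluster, each cell's mean vector is multiplied by a capture-efficiency
#' constant drawn from `Gamma(shape = 10, rate = 100)` (mean 0.1), and final
#' counts are Poisson-sampled.
#'
#' @param n Number of cells (default 473).
#' @param d Number of genes (default 2279).
#' @param k Number of clusters (default 3).
#' @param marker_fraction Fraction of genes acting as markers (default 0.1).
#' @param scale_up Multiplier for marker means in their cluster (default 3;
#'   values `<= 1` warn, as the clusters become unidentifiable).
#' @param efficiency_shape,efficiency_rate Gamma parameters of the per-cell
#'   efficiency-loss constant (defaults 10 and 100).
#' @param base_meanlog,base_sdlog Log-normal parameters of the base gene
#'   means (defaults 0 and 1.2).
#' @param seed Optional integer seed.
#' @return A `pm_dataset` whose `x` is an `n x d` nonnegative integer count
#'   matrix; `spec$marker_genes` records the marker assignment.
#' @export
simulate_beta_counts <- function(n = 473, d = 2279, k = 3,
                                 marker_fraction = 0.1, scale_up = 3,
                                 efficiency_shape = 10, efficiency_rate = 100,
                                 base_meanlog = 0, base_sdlog = 1.2,
                                 seed = NULL) {
  n <- check_count(n, "n", min = 3L)
  d <- check_count(d, "d", min = 1L)
  k <- check_count(k, "k", min = 2L)
  if (scale_up <= 1) warn("`scale_up` <= 1: marker genes do not distinguish the clusters")
  with_seed_if(seed, {
    base_mean <- stats::rlnorm(d, base_meanlog, base_sdlog)
    n_marker <- round(marker_fraction * d)
    markers <- sample.int(d, n_marker)
    marker_groups <- split(markers, rep(seq_len(k), length.out = n_marker))
    sizes <- split_sizes(n, k)
    labels <- rep(seq_len(k), sizes)
    s <- matrix(base_mean, n, d, byrow = TRUE)
    for (j in seq_len(k)) {
      s[labels == j, marker_groups[[j]]] <- s[labels == j, marker_groups[[j]]] * scale_up
    }
    eff <- rgamma(n, shape = efficiency_shape, rate = efficiency_rate)
    s <- s * eff
    x <- matrix(rpois(n * d, as.vector(s)), n, d)
    new_pm_dataset(x, labels, list(
      name = "sim_beta", n = n, d = d, k = k,
      marker_fraction = marker_fraction, scale_up = scale_up,
      efficiency_shape = efficiency_shape, efficiency_rate = efficiency_rate,
      base_meanlog = base_meanlog, base_sdlog = base_sdlog,
      marker_genes = marker_groups, efficiency = eff, seed = seed
    ))
  })
}

#' Generate a named benchmark data set
#'
#' Dispatcher over the individual generators, convenient for scripted runs.
#'
#' @param benchmark One of `"balls"`, `"ewb"`, `"swiss_roll"`, `"so3"`,
#'   `"sim_beta"`. (The argument is deliberately not named `name` so that
#'   generator arguments like `n` passed through `...` cannot partially
#'   match it.)
#' @param seed Optional integer seed.
#' @param ... Passed to the specific generator.
#' @return A `pm_dataset`.
#' @export
simulate_benchmark <- function(benchmark = c("balls", "ewb", "swiss_roll", "so3", "sim_beta"),
                               seed = NULL, ...) {
  name <- match.arg(benchmark)
  fn <- switch(name,
    balls = simulate_balls,
    ewb = simulate_ewb,
    swiss_roll = simulate_swiss_roll,
    so3 = simulate_so3,
    sim_beta = simulate_beta_counts
  )
  fn(seed = seed, ...)
}
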