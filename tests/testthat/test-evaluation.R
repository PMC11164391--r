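test_that("ARI handles perfect agreement, relabeling, and the hand oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # contingency-table hand computation for (1,1,2,2) vs (1,2,1,2):
  # all pair counts agree on 0 of 2 same-pairs -> ARI = -1/2 from the formula
  truth <- c(1, 1, 2, 2); pred <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(truth, pred), brute_force_ari(truth, pred))
})

test_that("ARI agrees with pair counting and mclust on random partitions", {
  for (s in 1:20) {
    withr::with_seed(s, {
      truth <- sample(1:4, 50, replace = TRUE)
      pred <- sample(1:3, 50, replace = TRUE)
    })
    ours <- adjusted_rand_index(truth, pred)
    expect_equal(ours, brute_force_ari(truth, pred), tolerance = 1e-12)
  }
  skip_if_not_installed("mclust")
  withr::with_seed(101, {
    truth <- sample(1:5, 200, replace = TRUE)
    pred <- sample(1:4, 200, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(truth, pred),
               mclust::adjustedRandIndex(truth, pred), tolerance = 1e-12)
})

test_that("ARI and entropies are invariant to label permutation", {
  withr::with_seed(12, {
    truth <- sample(1:3, 60, replace = TRUE)
    pred <- sample(1:4, 60, replace = TRUE)
  })
  perm_t <- c(3, 1, 2)[truth]
  perm_p <- c(4, 3, 1, 2)[pred]
  expect_equal(adjusted_rand_index(truth, pred), adjusted_rand_index(perm_t, perm_p))
  expect_equal(entropy_metrics(truth, pred), entropy_metrics(perm_t, perm_p))
})

test_that("entropy metrics match direct computations", {
  expect_equal(as.numeric(entropy_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2))), c(0, 0))

  # one predicted cluster holding two equal-sized true classes: entropy ln 2
  truth <- c(1, 1, 2, 2); pred <- c(1, 1, 1, 1)
  em <- entropy_metrics(truth, pred)
  expect_equal(em$ecp, log(2))
  expect_equal(em$eca, 0) # each class maps to one cluster

  # all-singleton prediction: pure clusters, scattered classes
  truth <- c(1, 1, 2, 2)
  em2 <- entropy_metrics(truth, seq_along(truth))
  expect_equal(em2$ecp, 0)
  expect_gt(em2$eca, 0)

  # base and weighting options
  em3 <- entropy_metrics(truth, pred, base = 2)
  expect_equal(em3$ecp, 1)
  h <- -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3))
  em4 <- entropy_metrics(c(1, 1, 2, 3), c(1, 1, 1, 2))
  expect_equal(em4$ecp, h / 2, tolerance = 1e-12)
  em5 <- entropy_metrics(c(1, 1, 2, 3), c(1, 1, 1, 2), weighted = TRUE)
  expect_equal(em5$ecp, 3 * h / 4, tolerance = 1e-12)
})

test_that("geometric perturbation is zero under identity and pure scaling", {
  blobs <- make_blobs(rbind(c(0, 0), c(5, 0), c(0, 5)), n_per = 20, seed = 5)
  gp <- geometric_perturbation(blobs$x, blobs$x, blobs$labels)
  expect_equal(gp$pi, 0, tolerance = 1e-12)
  expect_equal(gp$c_star, 1, tolerance = 1e-12)

  gp5 <- geometric_perturbation(blobs$x, 5 * blobs$x, blobs$labels)
  expect_equal(gp5$pi, 0, tolerance = 1e-12)
  expect_equal(gp5$c_star, 0.2, tolerance = 1e-12)
})

test_that("geometric perturbation matches a grid-search oracle on collinear means", {
  # three tight clusters with means at 0, 1, 2 in x; embedding means 0, 1, 3
  x <- matrix(c(rep(0, 5), rep(1, 5), rep(2, 5)), ncol = 1)
  y <- matrix(c(rep(0, 5), rep(1, 5), rep(3, 5)), ncol = 1)
  lab <- rep(1:3, each = 5)
  gp <- geometric_perturbation(x, y, lab)
  # independent 1-parameter grid minimization on the n x n construction
  mx <- c(0, 1, 2); my <- c(0, 1, 3)
  sizes <- rep(5, 3)
  w <- outer(sizes, sizes)
  dmx <- abs(outer(mx, mx, "-")); dmy <- abs(outer(my, my, "-"))
  cs <- seq(0, 2, by = 1e-5)
  obj <- vapply(cs, function(c) sum(w * (dmx - c * dmy)^2), numeric(1))
  expect_equal(gp$pi, min(obj) / sum(w * dmx^2), tolerance = 1e-6)
  expect_equal(gp$c_star, cs[which.min(obj)], tolerance = 1e-4)
})

test_that("geometric perturbation is invariant to rigid motion and scale of the embedding", {
  blobs <- make_blobs(rbind(c(0, 0), c(6, 1), c(2, 7)), n_per = 15, seed = 9)
  withr::with_seed(10, {
    theta <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    shift <- matrix(rnorm(2, sd = 10), 15 * 3, 2, byrow = TRUE)
    scl <- runif(1, 0.1, 10)
  })
  y0 <- blobs$x %*% rot
  base <- geometric_perturbation(blobs$x, blobs$x, blobs$labels)$pi
  moved <- geometric_perturbation(blobs$x, scl * y0 + shift, blobs$labels)$pi
  expect_equal(moved, base, tolerance = 1e-10)
})

test_that("geometric perturbation rejects degenerate inputs", {
  x <- matrix(rnorm(20), 10, 2)
  lab <- rep(1:2, each = 5)
  expect_error(geometric_perturbation(x, matrix(1, 10, 2), lab), "coincide")
  expect_error(geometric_perturbation(x, x, rep(1, 10)), "2 clusters")
})

test_that("elongation score matches a hand computation and sign conventions", {
  # 5-point set on a line; k_nn = round(10 * log(5)) = 16 clamps to 4
  x <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
  es <- elongation_score(x)
  expect_equal(es$k_nn, 4L)
  dk <- vapply(1:5, function(i) sort(abs(x[i, 1] - x[-i, 1]))[4], numeric(1))
  m <- mean(dk); s <- sd(dk)
  expect_equal(es$g1, 5 / (4 * 3) * sum(((dk - m) / s)^3), tolerance = 1e-12)

  # symmetric 3-point configuration: equal neighbour distances, zero skew
  expect_warning(
    es3 <- elongation_score(matrix(c(0, 1, 2), ncol = 1), k_nn = 1),
    "equal"
  )
  expect_equal(es3$g1, 0)

  # interior of a regular grid: near-uniform neighbour distances
  grid <- as.matrix(expand.grid(1:20, 1:20))
  es_grid <- elongation_score(grid)
  # long low-density tail: right-skewed kth-NN distances
  withr::with_seed(15, {
    dense <- matrix(rnorm(400, sd = 0.5), 200, 2)
    tail_pts <- cbind(runif(20, 5, 40), runif(20, 5, 40))
  })
  es_tail <- elongation_score(rbind(dense, tail_pts))
  expect_gt(es_tail$g1, 1)
  expect_lt(abs(es_grid$g1), abs(es_tail$g1))
})

test_that("constant neighbour distances give G1 = 0 with a warning", {
  # unit-square corners: every 1-NN distance is exactly 1
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_warning(es <- elongation_score(sq, k_nn = 1), "equal")
  expect_equal(es$g1, 0)
})

test_that("evaluate_clustering returns one tidy row", {
  out <- evaluate_clustering(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_s3_class(out, "tbl_df")
  expect_equal(unlist(out), c(ari = 1, ecp = 0, eca = 0))
})
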