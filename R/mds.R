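#' Double-center a squared distance matrix
#'
#' Computes the Torgerson matrix `B = -1/2 J D^(2) J` where `J` is the
#' centering matrix and `D^(2)` the entrywise square of the distance matrix.
#' For Euclidean distances of a centered point set, `B` is the Gram matrix
#' of the coordinates.
#'
#' @param d A `pm_dist` (full mode) or a symmetric numeric distance matrix
#'   with zero diagonal.
#' @return A symmetric matrix whose rows and columns sum to zero.
#' @export
double_center <- function(d) {
  m <- if (inherits(d, "pm_dist")) d$values else as.matrix(d)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square (full mode)")
  if (any(!is.finite(m))) {
    abort("distance matrix has non-finite entries: the KNN graph was disconnected; increase k2 or check the input")
  }
  m2 <- m^2
  rm_ <- rowMeans(m2)
  gm <- mean(m2)
  b <- -0.5 * (m2 - outer(rm_, rep(1, ncol(m2))) - outer(rep(1, nrow(m2)), colMeans(m2)) + gm)
  (b + t(b)) / 2
}

#' Select the embedding dimension by the eigenratio rule
#'
#' Picks the index `i` maximizing the consecutive eigenvalue ratio
#' `lambda_i / lambda_{i+1}`, restricted to `r_min <= i <= r_max` and to
#' "large" eigenvalues `lambda_i / lambda_1 >= tau`. Ties are broken by the
#' smallest index. When no index is admissible the rule falls back to
#' `r_min` with a warning.
#'
#' @param eigenvalues Numeric vector sorted in descending order, at least
#'   `r_min + 1` entries.
#' @param r_min,r_max Admissible index range (defaults 3 and 39; `r_max` is
#'   additionally capped at `length(eigenvalues) - 1`).
#' @param tau Relative eigenvalue floor (default 0.01).
#' @return The selected dimension as a single integer.
#' @examples
#' select_dimension(c(100, 90, 80, 70, 0.7, 0.6, 0.5)) # 4
#' @export
select_dimension <- function(eigenvalues, r_min = 3, r_max = 39, tau = 0.01) {
  lam <- as.numeric(eigenvalues)
  if (is.unsorted(rev(lam))) abort("`eigenvalues` must be sorted in descending order")
  r_min <- check_count(r_min, "r_min")
  r_max <- check_count(r_max, "r_max")
  r_max <- min(r_max, length(lam) - 1L)
  if (length(lam) < r_min + 1) abort("need at least r_min + 1 eigenvalues")
  idx <- seq.int(r_min, r_max)
  admissible <- lam[idx] / lam[1] >= tau
  if (!any(admissible)) {
    warn(sprintf("no index with lambda_i/lambda_1 >= %g in [%d, %d]; falling back to r = %d",
                 tau, r_min, r_max, r_min))
    return(r_min)
  }
  idx <- idx[admissible]
  ratio <- lam[idx] / lam[idx + 1]
  ratio[is.nan(ratio)] <- -Inf # 0/0 or degenerate tails are never selected
  idx[which.max(ratio)]
}

new_pm_embedding <- function(coordinates, eigenvalues, r, scaling, landmarks = NULL) {
  structure(
    list(coordinates = coordinates, eigenvalues = eigenvalues, r = r,
         scaling = scaling, landmarks = landmarks),
    class = "pm_embedding"
  )
}

#' @export
print.pm_embedding <- function(x, ...) {
  cat(sprintf(
    "<pm_embedding> %d cells in %d dimensions (%s scaling%s)\n",
    nrow(x$coordinates), x$r, x$scaling,
    if (is.null(x$landmarks)) "" else sprintf(", %d landmarks", length(x$landmarks))
  ))
  invisible(x)
}

# Sign convention: flip each eigenvector so its largest-magnitude entry is
# positive, making the embedding deterministic across LAPACK builds.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

scale_columns <- function(v, lam, scaling) {
  s <- switch(scaling,
    sqrt_eigenvalue = sqrt(pmax(lam, 0)),
    eigenvalue = pmax(lam, 0),
    abort("`scaling` must be 'sqrt_eigenvalue' or 'eigenvalue'")
  )
  sweep(v, 2, s, `*`)
}

#' Classical MDS embedding of path distances
#'
#' Embeds a full path-distance matrix by classical (Torgerson) MDS: the
#' squared distances are double-centered, the top eigenpairs extracted, and
#' coordinates formed as scaled eigenvectors. The embedding dimension is
#' chosen by [select_dimension()] unless given.
#'
#' The default `sqrt_eigenvalue` scaling (`sqrt(lambda_i) v_i`) reproduces
#' the input distances exactly when they are Euclidean; the `eigenvalue`
#' mode (`lambda_i v_i`) stretches each axis by a further `sqrt(lambda_i)`
#' and is provided for strict reproducibility of pipelines that scale by the
#' eigenvalue itself. Negative eigenvalues among the selected ones are
#' clipped to zero with a warning.
#'
#' @param d A `pm_dist` (full mode) or symmetric distance matrix.
#' @param r Embedding dimension; `NULL` (default) selects it from the
#'   spectrum.
#' @param r_min,r_max,tau Dimension-selection parameters, see
#'   [select_dimension()].
#' @param scaling `"sqrt_eigenvalue"` (default) or `"eigenvalue"`.
#' @return A `pm_embedding` with the `n x r` `coordinates`, the full
#'   descending `eigenvalues` of the Torgerson matrix, the selected `r`, and
#'   the scaling mode.
#' @export
mds_embed <- function(d, r = NULL, r_min = 3, r_max = 39, tau = 0.01,
                      scaling = c("sqrt_eigenvalue", "eigenvalue")) {
  scaling <- match.arg(scaling)
  b <- double_center(d)
  e <- eigen(b, symmetric = TRUE)
  lam <- e$values
  if (is.null(r)) {
    r <- select_dimension(lam, r_min = r_min, r_max = r_max, tau = tau)
  } else {
    r <- check_count(r, "r")
    if (r > nrow(b)) abort("`r` cannot exceed n")
  }
  npos <- sum(lam > 1e-12 * max(abs(lam), 1))
  if (r > npos) {
    warn(sprintf("requested %d dimensions but only %d positive eigenvalues; reducing r", r, npos))
    r <- max(npos, 1L)
  }
  if (any(lam[seq_len(r)] < 0)) {
    warn("negative eigenvalues among the selected dimensions; clipped to zero")
  }
  v <- fix_signs(e$vectors[, seq_len(r), drop = FALSE])
  y <- scale_columns(v, lam[seq_len(r)], scaling)
  rownames(y) <- rownames(b) %||% (if (inherits(d, "pm_dist")) rownames(d$values) else NULL)
  new_pm_embedding(y, eigenvalues = lam, r = r, scaling = scaling)
}

#' Landmark MDS embedding
#'
#' Quasi-linear classical MDS: the `q x q` landmark block is embedded by
#' full MDS, and every remaining cell is placed by distance-based
#' triangulation against the landmark coordinates. On Euclidean input with
#' `q = n` the result matches full MDS up to a rigid motion.
#'
#' @param d A `pm_dist` in landmark mode (`q x n`, from
#'   [landmark_path_distances()]).
#' @inheritParams mds_embed
#' @return A `pm_embedding` for all `n` cells; `eigenvalues` is the spectrum
#'   of the landmark Torgerson matrix.
#' @export
landmark_mds_embed <- function(d, r = NULL, r_min = 3, r_max = 39, tau = 0.01,
                               scaling = c("sqrt_eigenvalue", "eigenvalue")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(d, "pm_dist"))
  if (is.null(d$landmarks)) abort("`d` is not a landmark distance matrix")
  if (!d$connected) abort("distance matrix has non-finite entries: the KNN graph was disconnected")
  dl <- d$values
  q <- nrow(dl)
  n <- ncol(dl)
  dqq <- dl[, d$landmarks, drop = FALSE] # q x q block, rows/cols in landmark order
  b <- double_center(dqq)
  e <- eigen(b, symmetric = TRUE)
  lam <- e$values
  if (is.null(r)) {
    r <- select_dimension(lam, r_min = r_min, r_max = r_max, tau = tau)
  } else {
    r <- check_count(r, "r")
  }
  if (q <= r) abort(sprintf("need more landmarks than embedding dimensions (q = %d, r = %d)", q, r))
  npos <- sum(lam > 1e-12 * max(abs(lam)))
  if (r > npos) {
    warn(sprintf("requested %d dimensions but only %d positive eigenvalues; reducing r", r, npos))
    r <- max(npos, 1L)
  }
  v <- fix_signs(e$vectors[, seq_len(r), drop = FALSE])
  lam_r <- lam[seq_len(r)]
  lmk <- sweep(v, 2, sqrt(lam_r), `*`) # landmark coordinates, sqrt scaling

  # Triangulation: y_a = -1/2 Lambda^{-1/2} V' (delta2_a - delta2_mean)
  delta2 <- dl^2               # q x n squared distances to landmarks
  mu <- rowMeans(dqq^2)        # mean squared distance within landmark block
  pseudo <- sweep(v, 2, sqrt(lam_r), `/`) # q x r
  y <- -0.5 * t(crossprod(pseudo, delta2 - mu)) # n x r
  # exact for the landmarks themselves; overwrite to avoid rounding drift
  y[d$landmarks, ] <- lmk
  if (scaling == "eigenvalue") y <- sweep(y, 2, sqrt(lam_r), `*`)
  rownames(y) <- colnames(dl)
  new_pm_embedding(y, eigenvalues = lam, r = r, scaling = scaling,
                   landmarks = d$landmarks)
}

#' Export embedding coordinates as CSV
#'
#' @param embedding A `pm_embedding`.
#' @param path Output file; one row per cell, columns `cell_id`,
#'   `PM1..PMr`.
#' @param spectrum_path Optional path for a one-column CSV of the eigenvalue
#'   spectrum.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, spectrum_path = NULL) {
  stopifnot(inherits(embedding, "pm_embedding"))
  y <- embedding$coordinates
  df <- tibble::as_tibble(y, .name_repair = ~ paste0("PM", seq_along(.x)))
  df <- dplyr::bind_cols(
    tibble::tibble(cell_id = rownames(y) %||% as.character(seq_len(nrow(y)))),
    df
  )
  readr::write_csv(df, path)
  if (!is.null(spectrum_path)) {
    readr::write_csv(tibble::tibble(eigenvalue = embedding$eigenvalues), spectrum_path)
  }
  invisible(path)
}
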