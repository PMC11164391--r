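# broom-style accessors: tidy() returns per-cell rows, glance() a one-row
# model summary, so fits drop straight into dplyr pipelines.

#' @describeIn pm_profile Per-cell tibble: `cell_id`, embedding coordinates
#'   `PM1..PMr`, and `cluster`.
#' @param x A `pm_fit`.
#' @param ... Unused.
#' @export
tidy.pm_fit <- function(x, ...) {
  out <- tidy(x$embedding)
  out$cluster <- factor(x$clusters$labels)
  out
}

#' @export
tidy.pm_embedding <- function(x, ...) {
  y <- x$coordinates
  out <- tibble::as_tibble(y, .name_repair = ~ paste0("PM", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(cell_id = rownames(y) %||% as.character(seq_len(nrow(y)))),
    out
  )
}

#' @export
tidy.pm_clusters <- function(x, ...) {
  tibble::tibble(
    cell = seq_along(x$labels),
    cluster = factor(x$labels)
  )
}

#' @describeIn pm_profile One-row summary of the fitted pipeline.
#' @export
glance.pm_fit <- function(x, ...) {
  rp <- x$report
  tibble::tibble(
    n = rp$n, d = rp$d, p = rp$p, k1 = rp$k1, k2 = rp$k2,
    r = rp$r, k = rp$k, landmarks = rp$landmarks,
    connected = rp$connected, inertia = x$clusters$inertia,
    elapsed = sum(rp$timings)
  )
}

#' @export
glance.pm_embedding <- function(x, ...) {
  lam <- x$eigenvalues
  tibble::tibble(
    n = nrow(x$coordinates), r = x$r, scaling = x$scaling,
    lambda_1 = lam[1],
    eigenratio = lam[x$r] / lam[x$r + 1],
    positive_fraction = mean(lam > 0)
  )
}
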