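# ggplot2 views of the result objects.

#' @export
autoplot.pm_fit <- function(object, dims = c(1, 2), ...) {
  df <- tidy(object)
  cols <- paste0("PM", dims)
  ggplot2::ggplot(df, ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]],
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(
      title = sprintf("Path-metric embedding (p = %g, r = %d, k = %d)",
                      object$report$p, object$report$r, object$report$k),
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pm_embedding <- function(object, n_eigen = 40, ...) {
  lam <- object$eigenvalues[seq_len(min(n_eigen, length(object$eigenvalues)))]
  df <- tibble::tibble(index = seq_along(lam), eigenvalue = lam)
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$r + 0.5, linetype = "dashed") +
    ggplot2::labs(title = sprintf("MDS spectrum (selected r = %d)", object$r),
                  x = "component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a benchmark data set
#'
#' First two coordinates of a `pm_dataset`, coloured by the planted labels.
#'
#' @param object A `pm_dataset`.
#' @param ... Unused.
#' @export
autoplot.pm_dataset <- function(object, ...) {
  df <- tibble::tibble(
    x = object$x[, 1], y = object$x[, 2],
    label = factor(object$labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(title = object$spec$name, colour = "cluster") +
    ggplot2::theme_minimal()
}
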