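# ggplot2 views of the two fitted-object types.

#' Rose diagram of cluster phases
#'
#' Circular histogram of member phases for the largest clusters, one facet
#' per cluster, on the 24 h clock face.
#'
#' @param object A `phase_clusters` object.
#' @param top_n Number of largest clusters to show.
#' @param binwidth Histogram bin width in hours.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_clusters
#' @export
autoplot.phase_clusters <- function(object, top_n = 6, binwidth = 1, ...) {
  keep <- utils::head(object$clusters$cluster, top_n)
  df <- object$members |>
    dplyr::filter(.data$cluster %in% keep) |>
    dplyr::mutate(cluster = factor(.data$cluster, levels = keep,
                                   labels = paste("cluster", keep)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#3B6EA5", colour = "white",
                            linewidth = 0.2) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 18, by = 6)) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "circadian phase (h)", y = "gene-reaction nodes") +
    ggplot2::theme_minimal()
}

#' Data and fitted curve of a cosinor fit
#'
#' @param object A `cosine_fit` from [fit_cosine()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cosine_fit
#' @export
autoplot.cosine_fit <- function(object, ...) {
  df <- attr(object, "data")
  grid <- tibble::tibble(
    t = seq(min(df$t), max(df$t), length.out = 200)
  )
  grid$y <- object$mesor + object$amplitude *
    cos(2 * pi * (grid$t - object$acrophase) / object$period)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line(data = grid, colour = "#B0413E") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (h)", y = "intensity",
      subtitle = sprintf("period %.1f h, acrophase %.1f h, p = %.3g",
                         object$period, object$acrophase, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_cosine One-row tibble of fit statistics.
#' @param x A `cosine_fit`.
#' @param ... Unused.
#' @method glance cosine_fit
#' @export
glance.cosine_fit <- function(x, ...) {
  out <- x
  attr(out, "data") <- NULL
  class(out) <- class(tibble::tibble())
  out
}
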