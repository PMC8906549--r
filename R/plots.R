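#' Cumulative TSS-distance curve
#'
#' Step plot of the cumulative fraction of read 5' ends by signed distance
#' to the closest annotated TSS (negative = upstream), optionally one curve
#' per treatment group.
#'
#' @param distances Tibble with `signed_distance` and optionally `group`.
#' @param xlim Distance axis limits.
#' @return A ggplot object.
#' @export
plot_tss_distance_cdf <- function(distances, xlim = c(-1000, 1000)) {
  d <- distances[!is.na(distances$signed_distance), ]
  if (!"group" %in% names(d)) d$group <- "reads"
  d <- d |>
    group_by(.data$group) |>
    arrange(.data$signed_distance, .by_group = TRUE) |>
    mutate(cum_frac = row_number() / n()) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$signed_distance, .data$cum_frac,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(
      x = "distance of read 5' end to closest annotated TSS (nt)",
      y = "cumulative fraction of reads", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Poly(A)-site distance histogram
#'
#' Distribution of scaffold 3'-end distances to the nearest annotated
#' poly(A) site, with the acceptance window marked by dashed lines.
#'
#' @param distances Numeric vector of signed distances.
#' @param window Window bounds drawn as dashed lines.
#' @param binwidth Histogram bin width in nt.
#' @return A ggplot object.
#' @export
plot_polya_distance <- function(distances, window = c(-60, 10), binwidth = 10) {
  df <- tibble(distance = distances[!is.na(distances)])
  ggplot2::ggplot(df, ggplot2::aes(.data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = window, linetype = "dashed") +
    ggplot2::labs(
      x = "3' end distance to annotated poly(A) site (nt)",
      y = "reads"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Funnel plot of scaffold stages
#'
#' @param object A `scaffold_calls` object.
#' @param ... Unused.
#' @return A ggplot bar chart of read counts surviving each stage.
#' @export
autoplot.scaffold_calls <- function(object, ...) {
  funnel <- object$funnel |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(funnel, ggplot2::aes(.data$stage, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads surviving") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.scaffold_calls
#' @param object An `nrceq_result`.
#' @export
autoplot.nrceq_result <- function(object, ...) {
  autoplot(object$scaffolds, ...)
}
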