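#' Plot chase time courses of relative quantities
#'
#' One panel per condition, points and thin per-series lines coloured by
#' compartment, log-scaled y axis — the standard view of a
#' transcription-arrest decay experiment.
#'
#' @param rq Relative-quantity tibble from [delta_delta_ct()].
#' @return A ggplot object.
#' @export
plot_chase_curves <- function(rq) {
  ggplot2::ggplot(rq, ggplot2::aes(
    x = .data$time_min, y = .data$rq,
    colour = .data$compartment, group = .data$series
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "time after transcription arrest (min)",
                  y = "relative quantity")
}

#' Plot clustered 3'-end positions
#'
#' Positions as a rug with the clustered spans overlaid as segments —
#' the one-dimensional summary of mapped RNA 3' ends along the 5' UTR.
#'
#' @param positions Integer vector of end positions.
#' @param clusters Tibble from [cluster_end_positions()]; computed from
#'   `positions` with default gap if omitted.
#' @return A ggplot object.
#' @export
plot_end_clusters <- function(positions,
                              clusters = cluster_end_positions(positions)) {
  pos_tbl <- tibble::tibble(position = positions)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = clusters,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 1, yend = 1),
      linewidth = 3, colour = "steelblue"
    ) +
    ggplot2::geom_rug(
      data = pos_tbl,
      ggplot2::aes(x = .data$position), sides = "b"
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "nt downstream of TSS")
}
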