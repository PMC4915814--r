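#' Plot a spatiotemporal polarity map
#'
#' Heat map of a binned polarity measure (time on y, AP coordinate on x),
#' with non-significant grid squares optionally masked.
#'
#' @param map Output of [polarity_maps()].
#' @param mask_nonsignificant Blank squares whose mean is not significantly
#'   different from zero.
#' @return A ggplot.
#' @export
plot_polarity_map <- function(map, mask_nonsignificant = FALSE) {
  df <- map
  if (mask_nonsignificant) df$mean[!df$significant] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ap_mid, y = .data$time_mid,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#00a651", mid = "black",
                                  high = "#ec008c", na.value = "white") +
    ggplot2::labs(x = "AP position", y = "time (min)", fill = "polarity (pp)")
}

#' Plot a tissue frame
#'
#' Draws cell polygons, optionally coloured by stripe identity, with
#' interface intensities as line colour when painted.
#'
#' @param tissue A [tracked_tissue()].
#' @param frame Frame number.
#' @param colour_by `"stripe"`, `"parasegment"` or `"none"`.
#' @return A ggplot.
#' @export
plot_tissue <- function(tissue, frame = tissue$times$frame[1],
                        colour_by = c("stripe", "parasegment", "none")) {
  colour_by <- match.arg(colour_by)
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  polys <- lapply(seq_len(nrow(cs)), function(k) {
    vv <- cs$vertices[[k]]
    idx <- match(vv, vs$vertex_id)
    tibble::tibble(cell_id = cs$cell_id[k], x = vs$x[idx], y = vs$y[idx],
                   stripe = cs$stripe[k], parasegment = cs$parasegment[k])
  })
  df <- dplyr::bind_rows(polys)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$cell_id))
  p <- if (colour_by == "none") {
    p + ggplot2::geom_polygon(fill = "grey90", colour = "grey30",
                              linewidth = 0.3)
  } else {
    p + ggplot2::geom_polygon(ggplot2::aes(fill = .data[[colour_by]]),
                              colour = "grey20", linewidth = 0.3)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "AP (µm)", y = "DV (µm)")
}

#' Plot co-alignment over time
#'
#' Proportion of interfaces oriented 60--90 degrees to AP per class, with
#' the LOWESS smooth.
#'
#' @param coal Output of [coalignment()].
#' @return A ggplot.
#' @export
plot_coalignment <- function(coal) {
  ggplot2::ggplot(coal$proportion,
                  ggplot2::aes(x = .data$time, colour = .data$class)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop), alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), linewidth = 0.9) +
    ggplot2::labs(x = "time (min)", y = "proportion DV-oriented (60-90°)")
}

#' Plot the energy trace of a simulation run
#' @param run A `vm_run`.
#' @return A ggplot.
#' @export
plot_energy <- function(run) {
  ggplot2::ggplot(run$energy, ggplot2::aes(x = .data$time,
                                           y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation time", y = "free energy U")
}

#' Plot a robustness-score search histogram
#' @param search Output of [search_patterns()].
#' @return A ggplot.
#' @export
plot_score_histogram <- function(search) {
  ggplot2::ggplot(search$histogram,
                  ggplot2::aes(x = .data$score, y = .data$count)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_vline(xintercept = search$best_score, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "robustness score (grey boxes)", y = "configurations")
}
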