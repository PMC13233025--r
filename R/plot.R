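# ggplot2 visualisation helpers

raster_df <- function(m, value = "value") {
  df <- expand.grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot a phase map or raster
#'
#' @param x a [phase_map()], `ground_truth`, [hologram()] or plain matrix.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_raster <- function(x, title = NULL) {
  m <- if (inherits(x, "phase_map")) x$data
       else if (inherits(x, "ground_truth")) x$thickness_um
       else if (inherits(x, "hologram")) x$intensity
       else x
  lab <- if (inherits(x, "phase_map")) "phase (rad)"
         else if (inherits(x, "ground_truth")) "thickness (um)"
         else if (inherits(x, "hologram")) "intensity"
         else "value"
  ggplot2::ggplot(raster_df(m), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "px", y = "px") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.phase_map <- function(object, ...) {
  plot_raster(object, title = paste0("phase map (", object$state, ")"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ground_truth <- function(object, ...) {
  plot_raster(object,
              title = sprintf("%s phantom, V = %.1f um^3", object$kind,
                              object$volume_um3))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hologram <- function(object, ...) {
  plot_raster(object, title = "hologram")
}

#' Plot a volume time series with stage labels
#'
#' Volume trajectories per track with interval midpoints colored by the
#' slow/rapid stage classification.
#'
#' @param series a `volume_series` from [analyze_series()].
#' @return a ggplot object.
#' @export
plot_volume_series <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  p <- ggplot2::ggplot(series$tracks,
                       ggplot2::aes(.data$t_min, .data$volume_um3,
                                    group = .data$track_id)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time (min)", y = expression(volume ~ (mu * m^3))) +
    ggplot2::theme_minimal()
  if (nrow(series$slopes) > 0) {
    mid <- dplyr::mutate(series$slopes,
                         t_mid = (.data$t_start + .data$t_end) / 2)
    mid <- dplyr::left_join(
      mid,
      dplyr::transmute(series$tracks, track_id = .data$track_id,
                       t_end = .data$t_min, v_end = .data$volume_um3),
      by = c("track_id", "t_end"))
    p <- p + ggplot2::geom_point(
      data = mid,
      ggplot2::aes(.data$t_end, .data$v_end, color = .data$stage),
      size = 3, shape = 1, stroke = 1.2)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.volume_series <- function(object, ...) plot_volume_series(object)
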