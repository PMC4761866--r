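# ggplot2 methods for the package's result types.

#' @exportS3Method ggplot2::autoplot
autoplot.scalar_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$F_nT)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$F_nT), colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "F (nT)") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("Total intensity, t = %g", object$time))
}

#' @exportS3Method ggplot2::autoplot
autoplot.isoline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       group = .data$segment)) +
    ggplot2::geom_path(...) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("%.0f nT isoline at t = %g",
                                  attr(object, "level"), attr(object, "time")))
}

#' @exportS3Method ggplot2::autoplot
autoplot.plume_snapshot <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       colour = .data$age / 24)) +
    ggplot2::geom_point(size = 0.5, ...) +
    ggplot2::scale_colour_viridis_c(name = "age (d)") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("Plume snapshot, t = %g h", attr(object, "time")))
}

#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               group = .data$id, colour = .data$time / 24)) +
    ggplot2::geom_path(alpha = 0.3, linewidth = 0.2, ...) +
    ggplot2::scale_colour_viridis_c(name = "day") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", title = "Particle trajectories")
}

#' @exportS3Method ggplot2::autoplot
autoplot.scenario_outcome <- function(object, ...) {
  ggplot2::ggplot(object$tracks,
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               group = .data$id, colour = .data$mode)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.2) +
    ggplot2::annotate("point", x = object$island[2], y = object$island[1],
                      shape = 17, size = 3) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = sprintf("%s: %.0f%% arrived", object$params$strategy,
                                  100 * object$success_rate))
}

#' Bar chart of intersection rates with confidence intervals
#'
#' @param results Tibble of `intersection_result` rows (e.g. from
#'   [duration_sensitivity()]).
#' @return A ggplot object.
#' @export
plot_intersection_rates <- function(results) {
  df <- dplyr::mutate(results,
                      duration = factor(.data$duration_days),
                      panel = ifelse(is.na(.data$year), "mean",
                                     as.character(.data$year)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$duration, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Odorant duration (days)",
                  y = "Proportion of snapshots intersecting")
}

#' @exportS3Method generics::tidy
tidy.trajectory_set <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.trajectory_set <- function(x, ...) {
  st <- table(factor(x$particles$status, c("alive", "expired", "exited")))
  tibble::tibble(n_particles = nrow(x$particles),
                 n_alive = as.integer(st[["alive"]]),
                 n_expired = as.integer(st[["expired"]]),
                 n_exited = as.integer(st[["exited"]]),
                 t_start = x$t_start, t_end = x$t_end, dt = x$dt,
                 seed = as.integer(x$seed))
}

#' @importFrom rlang .data
NULL
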