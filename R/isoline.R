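#' Constant-intensity isolines and their secular drift
#'
#' An isoline is the curve of constant total field intensity F (nT). Because
#' the main geomagnetic field changes slowly (secular variation), the isoline
#' carrying a remembered intensity value moves over the years; the distance it
#' moves sets how far a magnetic "signature" ends up from the site where it was
#' learned.
#'
#' @name isoline
NULL

new_isoline <- function(lat, lon, level, time, segment = 1L) {
  out <- tibble::tibble(segment = rep_len(as.integer(segment), length(lat)),
                        lat = lat, lon = lon)
  attr(out, "level") <- level
  attr(out, "time") <- time
  class(out) <- c("isoline", class(out))
  out
}

#' @export
print.isoline <- function(x, ...) {
  cat(sprintf("<isoline> level %.1f nT at t = %g: %d vertices in %d segment(s)\n",
              attr(x, "level"), attr(x, "time"), nrow(x),
              length(unique(x$segment))))
  NextMethod()
}

#' Extract constant-value contours from a scalar grid
#'
#' Marching-squares contouring with linear interpolation along cell edges
#' (via [grDevices::contourLines()]). Each connected contour component is
#' returned as its own polyline.
#'
#' @param grid A `scalar_grid` from [intensity_grid()].
#' @param level Contour level (nT).
#' @return List of [isoline] polylines (possibly empty if `level` is outside
#'   the grid's value range).
#' @export
extract_isolines <- function(grid, level) {
  stopifnot(inherits(grid, "scalar_grid"))
  if (any(!is.finite(grid$values))) {
    stop("grid contains non-finite values", call. = FALSE)
  }
  if (level < min(grid$values) || level > max(grid$values)) {
    return(list())
  }
  cl <- grDevices::contourLines(x = grid$lats, y = grid$lons, z = grid$values,
                                levels = level)
  lapply(seq_along(cl), function(i) {
    new_isoline(lat = cl[[i]]$x, lon = cl[[i]]$y, level = level,
                time = grid$time, segment = i)
  })
}

# choose the contour component nearest a reference point; ties broken by
# the longest (most-vertex) component
nearest_component <- function(components, lat, lon) {
  if (length(components) == 0) return(NULL)
  d <- vapply(components, function(p) min(dist_point_to_polyline(lat, lon, p)), 0)
  nv <- vapply(components, nrow, 0L)
  components[[order(d, -nv)[1]]]
}

#' Isoline of the intensity found at a reference point
#'
#' Computes F at `point` for date `t`, then extracts the contour of that level
#' over the window and returns the connected component passing nearest the
#' point.
#'
#' @param series A `gauss_series`.
#' @param t Decimal year.
#' @param point Numeric `c(lat, lon)` in degrees; must lie inside the window.
#' @param lat_range,lon_range Extraction window (degrees); defaults cover the
#'   Brazil-to-Ascension corridor.
#' @param step_deg Grid step in degrees.
#' @return An [isoline]; its `level` attribute is F(point, t).
#' @export
isoline_through_point <- function(series, t, point,
                                  lat_range = c(-25, 10), lon_range = c(-45, 5),
                                  step_deg = 0.1) {
  if (point[1] < lat_range[1] || point[1] > lat_range[2] ||
      point[2] < lon_range[1] || point[2] > lon_range[2]) {
    stop("reference point lies outside the extraction window", call. = FALSE)
  }
  coeffs <- coefficients_at(series, t)
  level <- evaluate_field(coeffs, point[1], point[2])$F
  grid <- intensity_grid(series, t, lat_range, lon_range, step_deg)
  comp <- nearest_component(extract_isolines(grid, level), point[1], point[2])
  if (is.null(comp)) {
    stop(sprintf("no contour at level %.1f nT found in window at t = %g",
                 level, t), call. = FALSE)
  }
  comp
}

#' Drift of an intensity isoline over a time interval
#'
#' Fixes the intensity level at F(`point`, `t0`), extracts the isoline of that
#' level `delta_years` later, and reports how far the reference point now lies
#' from it (minimum great-circle distance). This is the displacement a
#' navigator relying on a remembered intensity value would experience after an
#' absence of `delta_years`.
#'
#' @inheritParams isoline_through_point
#' @param t0 Reference decimal year.
#' @param delta_years Interval in years (the drifted isoline is evaluated at
#'   `t0 + delta_years`).
#' @return A `drift_report`: one-row tibble with `t0`, `delta_years`, `level`
#'   (nT), `drift_km`, and the drifted [isoline] in attribute `"isoline"`.
#' @examples
#' series <- read_igrf(magplume_igrf_file())
#' drifted_isoline(series, point = c(-7.933, -14.367), t0 = 1980,
#'                 delta_years = 25, step_deg = 0.5)
#' @export
drifted_isoline <- function(series, point, t0, delta_years,
                            lat_range = c(-25, 10), lon_range = c(-45, 5),
                            step_deg = 0.1) {
  coeffs0 <- coefficients_at(series, t0)
  level <- evaluate_field(coeffs0, point[1], point[2])$F
  grid <- intensity_grid(series, t0 + delta_years, lat_range, lon_range, step_deg)
  comps <- extract_isolines(grid, level)
  comp <- nearest_component(comps, point[1], point[2])
  if (is.null(comp)) {
    stop(sprintf(
      "isoline left the window: level %.1f nT (from t0 = %g) not present at t = %g over lat [%g, %g], lon [%g, %g]",
      level, t0, t0 + delta_years, lat_range[1], lat_range[2],
      lon_range[1], lon_range[2]), call. = FALSE)
  }
  out <- tibble::tibble(
    ref_lat = point[1], ref_lon = point[2], t0 = t0,
    delta_years = delta_years, level = level,
    drift_km = min(dist_point_to_polyline(point[1], point[2], comp))
  )
  attr(out, "isoline") <- comp
  class(out) <- c("drift_report", class(out))
  out
}

#' Isoline drift distances over a sweep of start years
#'
#' Runs [drifted_isoline()] for every `(t0, delta)` combination for which both
#' endpoints fall inside the series' tabulated span.
#'
#' @inheritParams drifted_isoline
#' @param t0s Start years (defaults to every tabulated epoch).
#' @param deltas Intervals in years.
#' @return Tibble of drift-report rows (without polylines).
#' @export
isoline_drift_table <- function(series, point, t0s = NULL, deltas = c(5, 25),
                                lat_range = c(-25, 10), lon_range = c(-45, 5),
                                step_deg = 0.1) {
  if (is.null(t0s)) t0s <- series$epochs
  # the predictive secular-variation column extends validity up to 5 years
  # past the last tabulated epoch; only intervals short enough to fit inside
  # that predictive window may end in it
  last <- max(series$epochs)
  sv_span <- if (is.null(series$sv_g)) 0 else 5
  grid <- tidyr::expand_grid(t0 = t0s, delta_years = deltas) |>
    dplyr::filter(.data$t0 + .data$delta_years <= last |
                    (.data$delta_years <= sv_span & .data$t0 <= last))
  purrr::pmap_dfr(grid, function(t0, delta_years) {
    rep <- drifted_isoline(series, point, t0, delta_years,
                           lat_range, lon_range, step_deg)
    tibble::as_tibble(rep)
  })
}
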