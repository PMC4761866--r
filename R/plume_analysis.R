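#' Does a plume snapshot intersect an isoline?
#'
#' A snapshot intersects when any living particle lies within `buffer_km`
#' great-circle distance of the isoline polyline. The buffer stands in for the
#' width of one ocean-model grid cell (~8-9 km): maps overlay plumes and
#' isolines at that resolution, so contact within a cell counts as overlap.
#'
#' @param snap A `plume_snapshot` (or any data frame with `lat`, `lon`).
#' @param isoline An [isoline] polyline.
#' @param buffer_km Contact buffer (km), >= 0.
#' @return Logical scalar; an empty snapshot never intersects.
#' @export
plume_intersects <- function(snap, isoline, buffer_km = 10) {
  stopifnot(buffer_km >= 0)
  if (nrow(isoline) == 0) stop("empty isoline", call. = FALSE)
  if (nrow(snap) == 0) return(FALSE)
  # cheap prefilter: particles whose bounding-box distance already exceeds
  # the buffer cannot intersect
  latr <- range(isoline$lat); lonr <- range(isoline$lon)
  margin <- (buffer_km + 1) / KM_PER_DEG
  coslat <- cos(mean(latr) * pi / 180)
  near <- snap$lat >= latr[1] - margin & snap$lat <= latr[2] + margin &
    snap$lon >= lonr[1] - margin / coslat & snap$lon <= lonr[2] + margin / coslat
  if (!any(near)) return(FALSE)
  d <- dist_point_to_polyline(snap$lat[near], snap$lon[near], isoline)
  any(d <= buffer_km)
}

#' Evenly spaced snapshot times across a window
#'
#' `k` instants evenly spaced over `[t_start, t_end]`, endpoints included
#' (`k = 1` degenerates to the midpoint).
#'
#' @param t_start,t_end Window in hours.
#' @param k Number of snapshot times (>= 1).
#' @return Numeric vector of length `k`.
#' @export
snapshot_times <- function(t_start, t_end, k = 10) {
  stopifnot(k >= 1, t_end >= t_start)
  if (k == 1) return((t_start + t_end) / 2)
  seq(t_start, t_end, length.out = k)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Named vector `c(low, high)`, both within \[0, 1\].
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Intersection rate of plume snapshots with an isoline
#'
#' Counts intersecting snapshots and reports the proportion with a 95% Wilson
#' score interval (appropriate for the small snapshot counts involved: 40
#' waterborne, 15 airborne).
#'
#' @param snapshots List of `plume_snapshot` objects, or a logical vector of
#'   pre-computed hits.
#' @param isoline An [isoline] (ignored when `snapshots` is logical).
#' @param buffer_km Contact buffer (km).
#' @param conf Confidence level for the interval.
#' @param labels Optional named list of condition labels (duration, year, ...)
#'   added as columns.
#' @return An `intersection_result`: one-row tibble with `n_snapshots`,
#'   `n_intersecting`, `proportion`, `ci_low`, `ci_high` and any labels.
#' @export
intersection_rate <- function(snapshots, isoline = NULL, buffer_km = 10,
                              conf = 0.95, labels = NULL) {
  hits <- if (is.logical(snapshots)) snapshots else {
    vapply(snapshots, plume_intersects, TRUE, isoline = isoline,
           buffer_km = buffer_km)
  }
  n <- length(hits)
  stopifnot(n >= 1)
  k <- sum(hits)
  ci <- wilson_ci(k, n, conf)
  out <- tibble::tibble(n_snapshots = n, n_intersecting = k,
                        proportion = k / n,
                        ci_low = ci[["low"]], ci_high = ci[["high"]])
  for (nm in names(labels %||% list())) out[[nm]] <- labels[[nm]]
  class(out) <- c("intersection_result", class(out))
  out
}

#' Odorant-duration sensitivity of plume-isoline contact
#'
#' For each year (one independently seeded flow realization per year) a single
#' dispersal run at the longest lifetime is performed; the shorter lifetimes
#' are imposed post hoc by age-filtering the snapshots (see [snapshot()]).
#' Because the living set under a shorter lifetime is a subset of the living
#' set under a longer one at every instant, the intersection rate is exactly
#' non-decreasing in lifetime within a year -- the qualitative lifetime effect
#' is a theorem of the construction, not a statistical accident.
#'
#' @param make_field Function `(seed) -> velocity_field` producing one flow
#'   realization per year.
#' @param schedule A [release_schedule()]; its `lifetime_days` must be
#'   `max(lifetimes)`.
#' @param isoline An [isoline] the plumes are tested against.
#' @param lifetimes Odorant lifetimes in days.
#' @param years Vector of year labels; year `i` uses seed `seeds[i]`.
#' @param seeds Integer seeds, one per year.
#' @param k_snapshots Snapshots per year, evenly spaced across the season.
#' @param buffer_km Contact buffer (km).
#' @param dispersion A [dispersion_params()].
#' @param dt Tracker step (hours).
#' @return Tibble of `intersection_result` rows, one per (year, lifetime),
#'   plus per-lifetime means across years (`year = NA`).
#' @export
duration_sensitivity <- function(make_field, schedule, isoline,
                                 lifetimes = c(15, 30, 45),
                                 years = 1:4, seeds = years,
                                 k_snapshots = 10, buffer_km = 10,
                                 dispersion = dispersion_params(),
                                 dt = 2) {
  stopifnot(max(lifetimes) <= schedule$lifetime_days,
            length(seeds) == length(years))
  per_year <- purrr::map2_dfr(years, seeds, function(yr, sd) {
    field <- make_field(sd)
    traj <- advect(schedule, field, dispersion = dispersion, dt = dt, seed = sd,
                   t_end = min(schedule$season_hours,
                               max(field$times)))
    times <- snapshot_times(0, traj$t_end, k_snapshots)
    purrr::map_dfr(sort(lifetimes), function(lt) {
      snaps <- lapply(times, function(tt) snapshot(traj, tt, lifetime_days = lt))
      intersection_rate(snaps, isoline, buffer_km,
                        labels = list(duration_days = lt, year = yr))
    })
  })
  means <- per_year |>
    dplyr::group_by(.data$duration_days) |>
    dplyr::summarise(n_snapshots = sum(.data$n_snapshots),
                     n_intersecting = sum(.data$n_intersecting),
                     proportion = mean(.data$proportion), .groups = "drop") |>
    dplyr::mutate(year = NA_integer_)
  ci <- purrr::map2(means$n_intersecting, means$n_snapshots, wilson_ci)
  means$ci_low <- vapply(ci, `[[`, 0, "low")
  means$ci_high <- vapply(ci, `[[`, 0, "high")
  dplyr::bind_rows(per_year, means[names(per_year)])
}
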