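#' Odorant release schedule
#'
#' Describes where, when and how many odorant particles are released. The
#' waterborne defaults follow the island-source protocol: particles seeded
#' uniformly over a 10 x 10 km zone centered on the island, 100 particles at
#' each of five depth layers (0, 10, 20, 30, 50 m) every day across the
#' nesting season (December 15 -- April 29). Airborne runs use the same
#' engine with a single 0-m layer, hourly releases and a 48-hour lifetime.
#'
#' @param zone_center `c(lat, lon)` of the release zone (degrees).
#' @param zone_half_width_km Half-width of the square release zone (km).
#' @param layer_depths Depth layers (m).
#' @param per_layer_per_release Particles per layer per release event.
#' @param release_interval_h Hours between releases (24 waterborne, 1 airborne).
#' @param season_start,season_end Month-day strings `"MM-DD"`; the season runs
#'   from `season_start` of one calendar year to `season_end` of the next.
#' @param year Calendar year in which the season starts (sets leap-day
#'   handling); simulation time is hours since `season_start` 00:00.
#' @param lifetime_days Odorant lifetime in days (15, 30 or 45 waterborne;
#'   2 airborne).
#' @return A `release_schedule` object.
#' @export
release_schedule <- function(zone_center = c(-7.933, -14.367),
                             zone_half_width_km = 5,
                             layer_depths = c(0, 10, 20, 30, 50),
                             per_layer_per_release = 100,
                             release_interval_h = 24,
                             season_start = "12-15", season_end = "04-29",
                             year = 2004, lifetime_days = 45) {
  stopifnot(per_layer_per_release >= 1, lifetime_days > 0,
            zone_half_width_km >= 0, release_interval_h > 0)
  start <- as.Date(paste0(year, "-", season_start))
  end <- as.Date(paste0(year + 1, "-", season_end))
  if (end <= start) stop("season_end must fall after season_start", call. = FALSE)
  season_h <- as.numeric(end - start) * 24
  structure(list(zone_center = zone_center,
                 zone_half_width_km = zone_half_width_km,
                 layer_depths = layer_depths,
                 per_layer_per_release = per_layer_per_release,
                 release_interval_h = release_interval_h,
                 season_start = start, season_end = end,
                 season_hours = season_h,
                 lifetime_days = lifetime_days),
            class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf(
    "<release_schedule> %d/layer x %d layer(s) every %g h, %s to %s (%g h), lifetime %g d\n",
    x$per_layer_per_release, length(x$layer_depths), x$release_interval_h,
    format(x$season_start), format(x$season_end), x$season_hours,
    x$lifetime_days))
  invisible(x)
}

#' Release a batch of particles
#'
#' Seeds `per_layer_per_release` particles per depth layer, uniformly over the
#' square release zone (km offsets converted to degrees at the zone latitude).
#' Outside the season window no particles are released.
#'
#' @param schedule A [release_schedule()].
#' @param t Release time, hours since season start.
#' @param id_start First particle id to assign.
#' @return Tibble of particles (possibly empty): `id`, `release_time`,
#'   `layer_depth`, `lat`, `lon`, `age`, `status`.
#' @export
release_particles <- function(schedule, t, id_start = 1L) {
  if (t < 0 || t > schedule$season_hours) {
    return(empty_particles())
  }
  n_layer <- length(schedule$layer_depths)
  n <- schedule$per_layer_per_release * n_layer
  hw <- schedule$zone_half_width_km
  dx <- stats::runif(n, -hw, hw)
  dy <- stats::runif(n, -hw, hw)
  lat0 <- schedule$zone_center[1]; lon0 <- schedule$zone_center[2]
  tibble::tibble(
    id = seq.int(id_start, length.out = n),
    release_time = t,
    layer_depth = rep(schedule$layer_depths, each = schedule$per_layer_per_release),
    lat = lat0 + dy / KM_PER_DEG,
    lon = lon0 + dx / (KM_PER_DEG * cos(lat0 * pi / 180)),
    age = 0,
    status = "alive"
  )
}

empty_particles <- function() {
  tibble::tibble(id = integer(), release_time = numeric(),
                 layer_depth = numeric(), lat = numeric(), lon = numeric(),
                 age = numeric(), status = character())
}

# degrees of lat/lon per hour for a velocity in m/s
deg_rates <- function(u, v, lat) {
  m_per_deg <- KM_PER_DEG * 1000
  list(dlat = v * 3600 / m_per_deg,
       dlon = u * 3600 / (m_per_deg * cos(lat * pi / 180)))
}

#' One classical RK4 advection step
#'
#' Integrates `d(lat)/dt = v / R * (180/pi)`, `d(lon)/dt = u / (R cos lat) *
#' (180/pi)` with the classical fourth-order Runge-Kutta scheme. Exact (to
#' float precision) for velocity fields constant in space and time. If any
#' stage samples outside the field domain, the particle is marked `exited`
#' and frozen at its last valid position.
#'
#' @param field A [velocity_field()].
#' @param lat,lon Positions (degrees), vectors.
#' @param depth Depth (m), scalar or vector (nearest layer sampling).
#' @param t Step start time (hours).
#' @param dt Step length (hours).
#' @param frozen_daily Passed to [sample_velocity()].
#' @return List with `lat`, `lon` (degrees) and logical `exited`.
#' @export
rk4_step <- function(field, lat, lon, depth = 0, t = 0, dt = 1,
                     frozen_daily = FALSE) {
  vel <- function(la, lo, tt) {
    s <- sample_velocity(field, la, lo, depth, tt, frozen_daily = frozen_daily)
    deg_rates(s$u, s$v, la)
  }
  k1 <- vel(lat, lon, t)
  k2 <- vel(lat + 0.5 * dt * k1$dlat, lon + 0.5 * dt * k1$dlon, t + dt / 2)
  k3 <- vel(lat + 0.5 * dt * k2$dlat, lon + 0.5 * dt * k2$dlon, t + dt / 2)
  k4 <- vel(lat + dt * k3$dlat, lon + dt * k3$dlon, t + dt)
  dlat <- dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  dlon <- dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  exited <- !is.finite(dlat) | !is.finite(dlon)
  list(lat = ifelse(exited, lat, lat + dlat),
       lon = ifelse(exited, lon, lon + dlon),
       exited = exited)
}

#' Horizontal dispersion parameters
#'
#' Sub-gridscale turbulent mixing is represented as an uncorrelated Gaussian
#' random walk: independent displacements per horizontal axis with standard
#' deviation `sqrt(2 K_h dt)`.
#'
#' @param K_h Horizontal diffusivity (m^2/s); the default 10 is a typical
#'   sub-gridscale value for ~8 km grids.
#' @param enabled Logical master switch.
#' @return A `dispersion_params` list.
#' @export
dispersion_params <- function(K_h = 10, enabled = TRUE) {
  stopifnot(K_h >= 0)
  structure(list(K_h = K_h, enabled = enabled), class = "dispersion_params")
}

#' Apply one random-walk dispersion step
#'
#' @param lat,lon Positions (degrees).
#' @param params A [dispersion_params()].
#' @param dt Step (hours).
#' @return List with displaced `lat`, `lon`.
#' @export
apply_dispersion <- function(lat, lon, params = dispersion_params(), dt = 1) {
  if (!params$enabled || params$K_h == 0 || length(lat) == 0) {
    return(list(lat = lat, lon = lon))
  }
  sd_m <- sqrt(2 * params$K_h * dt * 3600)
  n <- length(lat)
  dy <- stats::rnorm(n, 0, sd_m)
  dx <- stats::rnorm(n, 0, sd_m)
  m_per_deg <- KM_PER_DEG * 1000
  list(lat = lat + dy / m_per_deg,
       lon = lon + dx / (m_per_deg * cos(lat * pi / 180)))
}

#' Advect scheduled particle releases through a velocity field
#'
#' The core dispersal loop: at each step, release particles that are due,
#' advance all living particles by one RK4 step at their own depth layer,
#' apply horizontal dispersion, age everything by `dt`, and expire particles
#' older than their lifetime. Particles that sample outside the field domain
#' are frozen (`exited`), not reflected. Positions of all particles are
#' recorded every `record_interval_h` hours.
#'
#' @param schedule A [release_schedule()].
#' @param field A [velocity_field()].
#' @param dispersion A [dispersion_params()].
#' @param t_start,t_end Simulation span, hours since season start; `t_end`
#'   defaults to the season end plus one lifetime so the last releases can
#'   live out their days.
#' @param dt Time step (hours).
#' @param seed Integer RNG seed; the run is a pure function of
#'   (arguments, seed).
#' @param record_interval_h Snapshot recording cadence (hours).
#' @param frozen_daily If `TRUE`, velocities are held at each day's 00:00
#'   snapshot instead of interpolated continuously in time.
#' @return A `trajectory_set`: list with `history` (tibble of recorded
#'   particle states), `particles` (final states), and the run metadata.
#' @export
advect <- function(schedule, field, dispersion = dispersion_params(),
                   t_start = 0, t_end = NULL, dt = 1, seed = 1,
                   record_interval_h = 24, frozen_daily = FALSE) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(t_end)) {
    t_end <- schedule$season_hours + schedule$lifetime_days * 24
  }
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  zc <- schedule$zone_center
  if (zc[1] < min(field$lats) || zc[1] > max(field$lats) ||
      zc[2] < min(field$lons) || zc[2] > max(field$lons)) {
    stop("release zone lies outside the velocity-field domain", call. = FALSE)
  }
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lifetime_h <- schedule$lifetime_days * 24
  parts <- empty_particles()
  next_id <- 1L
  steps <- seq(t_start, t_end, by = dt)
  history <- vector("list", length(steps))
  rec_i <- 0L
  record <- function(t, parts) {
    if (nrow(parts) == 0) return(NULL)
    dplyr::mutate(parts, time = t, .before = 1)
  }
  for (si in seq_along(steps)) {
    t <- steps[si]
    # releases due at this instant
    if (t <= schedule$season_hours &&
        abs(t %% schedule$release_interval_h) < dt / 2) {
      batch <- release_particles(schedule, t, id_start = next_id)
      if (nrow(batch) > 0) {
        next_id <- next_id + nrow(batch)
        parts <- dplyr::bind_rows(parts, batch)
      }
    }
    # record state at t (before stepping past it)
    if (abs(t %% record_interval_h) < dt / 2 || si == length(steps)) {
      rec_i <- rec_i + 1L
      history[[rec_i]] <- record(t, parts)
    }
    if (si == length(steps)) break
    alive <- parts$status == "alive"
    if (any(alive)) {
      st <- rk4_step(field, parts$lat[alive], parts$lon[alive],
                     parts$layer_depth[alive], t, dt,
                     frozen_daily = frozen_daily)
      dsp <- apply_dispersion(st$lat, st$lon, dispersion, dt)
      parts$lat[alive] <- ifelse(st$exited, st$lat, dsp$lat)
      parts$lon[alive] <- ifelse(st$exited, st$lon, dsp$lon)
      stat <- parts$status[alive]
      stat[st$exited] <- "exited"
      parts$status[alive] <- stat
    }
    live <- parts$status != "expired"
    parts$age[live] <- parts$age[live] + dt
    newly_dead <- parts$status == "alive" & parts$age > lifetime_h
    parts$status[newly_dead] <- "expired"
  }
  structure(list(history = dplyr::bind_rows(history[seq_len(rec_i)]),
                 particles = parts,
                 schedule = schedule, dt = dt, seed = seed,
                 t_start = t_start, t_end = t_end,
                 record_interval_h = record_interval_h,
                 frozen_daily = frozen_daily),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d particles over t = [%g, %g] h (dt = %g h, seed %s)\n",
    nrow(x$particles), x$t_start, x$t_end, x$dt, format(x$seed)))
  cat(sprintf("  status: %s\n",
              paste(names(table(x$particles$status)),
                    table(x$particles$status), collapse = ", ", sep = " = ")))
  invisible(x)
}

#' Plume snapshot: all living particles at one instant
#'
#' Pools every depth layer into one 2-D point set (plumes are overlaid on maps
#' in plan view). `t` is snapped to the nearest recorded time. A shorter
#' odorant lifetime than the one simulated can be imposed post hoc with
#' `lifetime_days`: because a particle's trajectory does not depend on its
#' expiry, the living set under a shorter lifetime is exactly the subset of
#' particles young enough -- the mechanism behind the lifetime-sensitivity
#' analysis.
#'
#' @param trajectories A `trajectory_set` from [advect()].
#' @param t Snapshot time (hours); must lie within the recorded span.
#' @param lifetime_days Optional lifetime (days) no longer than the simulated
#'   one.
#' @return A `plume_snapshot`: tibble of particle positions with attributes
#'   `time` and `n_particles`.
#' @export
snapshot <- function(trajectories, t, lifetime_days = NULL) {
  hist <- trajectories$history
  times <- unique(hist$time)
  if (length(times) == 0 || t < trajectories$t_start - 1e-9 ||
      t > trajectories$t_end + 1e-9) {
    stop(sprintf("snapshot time %g h outside simulated span [%g, %g]",
                 t, trajectories$t_start, trajectories$t_end), call. = FALSE)
  }
  lifetime_h <- (lifetime_days %||% trajectories$schedule$lifetime_days) * 24
  if (lifetime_h > trajectories$schedule$lifetime_days * 24 + 1e-9) {
    stop("lifetime_days exceeds the simulated lifetime", call. = FALSE)
  }
  before <- times[times <= t + 1e-9]
  if (length(before) == 0) {
    # requested instant precedes the first recorded (released) state
    snap <- hist[0, c("id", "lat", "lon", "layer_depth", "age")]
    attr(snap, "time") <- t
    attr(snap, "n_particles") <- 0L
    class(snap) <- c("plume_snapshot", class(snap))
    return(snap)
  }
  t_rec <- before[which.min(abs(before - t))]
  snap <- hist |>
    dplyr::filter(.data$time == t_rec, .data$status == "alive",
                  .data$age <= lifetime_h) |>
    dplyr::select("id", "lat", "lon", "layer_depth", "age")
  attr(snap, "time") <- t_rec
  attr(snap, "n_particles") <- nrow(snap)
  class(snap) <- c("plume_snapshot", class(snap))
  snap
}

#' @export
print.plume_snapshot <- function(x, ...) {
  cat(sprintf("<plume_snapshot> %d particles at t = %g h\n",
              attr(x, "n_particles"), attr(x, "time")))
  NextMethod()
}
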