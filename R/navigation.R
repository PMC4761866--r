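#' Agent (virtual turtle) parameters
#'
#' Strategy parameters for the homing simulation. None of these are measured
#' quantities; they are modelling assumptions exposed for sensitivity
#' exploration. The island radius default corresponds to a small (5 km
#' diameter) island.
#'
#' @param swim_speed Sustained swim speed (m/s).
#' @param strategy One of `"magnetic_only"`, `"odor_only"`, `"dual"`.
#' @param target_level Remembered intensity (nT) -- the isoline the agent
#'   follows.
#' @param detection_radius_km Odor detection range (km): a plume particle
#'   within this distance counts as odor contact.
#' @param crosstrack_gain Dimensionless gain of the return-to-isoline
#'   correction during isoline following.
#' @param search One of `"expanding_spiral"`, `"none"`: behaviour after plume
#'   contact is lost.
#' @param time_limit_days Give-up time.
#' @param island_radius_km Arrival radius around the island center.
#' @param lost_lapse_h Hours without detection (in plume phase) before
#'   switching to search.
#' @return An `agent_params` list.
#' @export
agent_params <- function(swim_speed = 0.6, strategy = "dual",
                         target_level = NA_real_, detection_radius_km = 15,
                         crosstrack_gain = 1, search = "expanding_spiral",
                         time_limit_days = 30, island_radius_km = 2.5,
                         lost_lapse_h = 12) {
  stopifnot(swim_speed > 0, island_radius_km > 0, detection_radius_km >= 0,
            strategy %in% c("magnetic_only", "odor_only", "dual"),
            search %in% c("expanding_spiral", "none"))
  structure(list(swim_speed = swim_speed, strategy = strategy,
                 target_level = target_level,
                 detection_radius_km = detection_radius_km,
                 crosstrack_gain = crosstrack_gain, search = search,
                 time_limit_days = time_limit_days,
                 island_radius_km = island_radius_km,
                 lost_lapse_h = lost_lapse_h),
            class = "agent_params")
}

new_agents <- function(lat, lon, mode, heading = 90) {
  n <- length(lat)
  tibble::tibble(id = seq_len(n), lat = lat, lon = lon,
                 mode = rep_len(mode, n), heading = rep_len(heading, n),
                 elapsed_h = 0, center_lat = NA_real_, center_lon = NA_real_,
                 spiral_theta = 0, lost_h = 0, path_km = 0)
}

# unit heading vector (east, north components) from bearing degrees
bearing_vec <- function(deg) list(e = sin(deg * pi / 180), n = cos(deg * pi / 180))
vec_bearing <- function(e, n) (atan2(e, n) * 180 / pi) %% 360

# displace agents along their heading by speed*dt
swim_forward <- function(agents, idx, speed_ms, dt_h) {
  if (!any(idx)) return(agents)
  step_km <- speed_ms * dt_h * 3.6
  hv <- bearing_vec(agents$heading[idx])
  agents$lat[idx] <- agents$lat[idx] + hv$n * step_km / KM_PER_DEG
  agents$lon[idx] <- agents$lon[idx] +
    hv$e * step_km / (KM_PER_DEG * cos(agents$lat[idx] * pi / 180))
  agents$path_km[idx] <- agents$path_km[idx] + step_km
  agents
}

#' One isoline-following step
#'
#' Agents in the isoline phase swim along the local isoline tangent
#' (perpendicular to the intensity gradient), signed to keep their previous
#' direction of progress, plus a cross-track correction toward the target
#' level proportional to the signed offset `(target - F)/|grad F|` (the local
#' linear estimate of the distance to the isoline, in km). Where the gradient
#' falls below 1e-3 nT/km (magnetic plateau) the previous heading is held.
#'
#' @param coeffs `gauss_set` of the field the agents sense.
#' @param agents Agent state tibble (see [run_scenario()]).
#' @param params [agent_params()].
#' @param dt_h Step (hours).
#' @return Updated agents tibble.
#' @export
isoline_following_step <- function(coeffs, agents, params, dt_h = 1) {
  idx <- agents$mode == "isoline"
  if (!any(idx)) return(agents)
  la <- agents$lat[idx]; lo <- agents$lon[idx]
  d <- 0.05  # degrees, finite-difference stencil
  pts_lat <- c(la, la + d, la - d, la, la)
  pts_lon <- c(lo, lo, lo, lo + d, lo - d)
  f <- evaluate_field(coeffs, pts_lat, pts_lon)$F
  k <- length(la)
  F0 <- f[1:k]
  gy <- (f[k + 1:k] - f[2 * k + 1:k]) / (2 * d * KM_PER_DEG)          # nT/km north
  gx <- (f[3 * k + 1:k] - f[4 * k + 1:k]) /
    (2 * d * KM_PER_DEG * cos(la * pi / 180))                          # nT/km east
  gmag <- sqrt(gx^2 + gy^2)
  plateau <- gmag < 1e-3
  ghx <- ifelse(plateau, 0, gx / gmag); ghy <- ifelse(plateau, 0, gy / gmag)
  # tangent candidates, keep continuity with previous heading
  tx <- ghy; ty <- -ghx
  hv <- bearing_vec(agents$heading[idx])
  flip <- tx * hv$e + ty * hv$n < 0
  tx[flip] <- -tx[flip]; ty[flip] <- -ty[flip]
  offset_km <- (params$target_level - F0) / pmax(gmag, 1e-3)
  w <- pmax(pmin(params$crosstrack_gain * offset_km / 10, 2), -2)
  dx <- tx + w * ghx; dy <- ty + w * ghy
  nrm <- sqrt(dx^2 + dy^2)
  ok <- !plateau & nrm > 1e-9
  newhead <- agents$heading[idx]
  newhead[ok] <- vec_bearing(dx[ok] / nrm[ok], dy[ok] / nrm[ok])
  agents$heading[idx] <- newhead
  swim_forward(agents, idx, params$swim_speed, dt_h)
}

#' Odor detection against a plume snapshot
#'
#' @param agents Agent state tibble.
#' @param snap A `plume_snapshot` (may be empty).
#' @param detection_radius_km Detection range (km).
#' @return Logical vector, one per agent: any plume particle within range.
#' @export
odor_detected <- function(agents, snap, detection_radius_km) {
  n <- nrow(agents)
  if (is.null(snap) || nrow(snap) == 0 || detection_radius_km <= 0) {
    return(rep(FALSE, n))
  }
  A <- latlon_to_unit(agents$lat, agents$lon)
  P <- latlon_to_unit(snap$lat, snap$lon)
  # nearest particle via maximum dot product
  best <- apply(A %*% t(P), 1, max)
  chord_angle(best) * EARTH_RADIUS_KM <= detection_radius_km
}

#' One plume-following step
#'
#' Particles stream downstream from the island source, so heading up-flow
#' (against the local current) leads toward it. Up-flow alone, however,
#' parallels a streamline at whatever lateral offset the agent first
#' contacted the plume, so the heading blends the up-flow direction with a
#' centering pull toward the centroid of the particles currently detected --
#' the agent climbs back into the plume core while working upstream, and
#' inside the near-source release zone the centroid pull converges on the
#' island. With no resolvable flow the centroid pull alone is used. Contact
#' lost for longer than `lost_lapse_h` demotes the agent to the search phase.
#'
#' @param flow A [velocity_field()] (surface layer is sampled).
#' @param agents,params,dt_h As in [isoline_following_step()].
#' @param snap Current `plume_snapshot` (for the centering component).
#' @param t_h Time (hours, on the flow field's clock) for flow sampling.
#' @return Updated agents tibble.
#' @export
plume_following_step <- function(flow, agents, params, dt_h = 1, snap = NULL,
                                 t_h = 0) {
  idx <- which(agents$mode == "plume")
  if (length(idx) == 0) return(agents)
  tt <- min(max(t_h, min(flow$times)), max(flow$times))
  s <- sample_velocity(flow, agents$lat[idx], agents$lon[idx],
                       depth = flow$depths[1], t_hours = tt)
  spd <- sqrt(s$u^2 + s$v^2)
  have_flow <- !is.na(spd) & spd > 1e-6
  ue <- ifelse(have_flow, -s$u / spd, 0)
  un <- ifelse(have_flow, -s$v / spd, 0)
  ce <- numeric(length(idx)); cn <- numeric(length(idx))
  if (!is.null(snap) && nrow(snap) > 0) {
    for (j in seq_along(idx)) {
      ai <- idx[j]
      d <- haversine_km(agents$lat[ai], agents$lon[ai], snap$lat, snap$lon)
      nearby <- d <= params$detection_radius_km
      if (any(nearby)) {
        de <- (mean(snap$lon[nearby]) - agents$lon[ai]) *
          cos(agents$lat[ai] * pi / 180)
        dn <- mean(snap$lat[nearby]) - agents$lat[ai]
        nrm <- sqrt(de^2 + dn^2)
        if (nrm > 1e-9) { ce[j] <- de / nrm; cn[j] <- dn / nrm }
      }
    }
  }
  de <- ue + ce; dn <- un + cn
  nrm <- sqrt(de^2 + dn^2)
  ok <- nrm > 1e-9
  newhead <- agents$heading[idx]
  newhead[ok] <- vec_bearing(de[ok] / nrm[ok], dn[ok] / nrm[ok])
  agents$heading[idx] <- newhead
  agents <- swim_forward(agents, seq_len(nrow(agents)) %in% idx,
                         params$swim_speed, dt_h)
  agents
}

#' One expanding-spiral search step
#'
#' Archimedean spiral centered on the point where odor contact was made (or
#' lost), with pitch `2 * detection_radius_km` so successive passes leave no
#' gap wider than the detection diameter.
#'
#' @param agents,params,dt_h As in [isoline_following_step()].
#' @return Updated agents tibble.
#' @export
search_step <- function(agents, params, dt_h = 1) {
  idx <- which(agents$mode == "search")
  if (length(idx) == 0) return(agents)
  pitch <- 2 * params$detection_radius_km
  b <- pitch / (2 * pi)
  step_km <- params$swim_speed * dt_h * 3.6
  th <- agents$spiral_theta[idx]
  r <- b * th
  dth <- step_km / sqrt(r^2 + b^2)
  th <- th + dth
  r <- b * th
  agents$spiral_theta[idx] <- th
  clat <- agents$center_lat[idx]; clon <- agents$center_lon[idx]
  agents$lat[idx] <- clat + r * cos(th) / KM_PER_DEG
  agents$lon[idx] <- clon + r * sin(th) / (KM_PER_DEG * cos(clat * pi / 180))
  agents$heading[idx] <- vec_bearing(cos(th), -sin(th))  # tangent direction
  agents$path_km[idx] <- agents$path_km[idx] + step_km
  agents
}

#' Place agents along an isoline corridor west of the island
#'
#' Evenly spaced (by vertex order) along the portion of the polyline lying
#' west of the island at great-circle distance within `dist_range_km`,
#' emulating arrival from the Brazilian foraging grounds along the remembered
#' magnetic signature.
#'
#' @param isoline An [isoline].
#' @param island `c(lat, lon)`.
#' @param n Number of agents.
#' @param dist_range_km Distance band from the island (km).
#' @return Tibble with `lat`, `lon` start positions.
#' @export
place_agents_on_isoline <- function(isoline, island, n = 200,
                                    dist_range_km = c(300, 600)) {
  d <- haversine_km(isoline$lat, isoline$lon, island[1], island[2])
  west <- isoline$lon < island[2] & d >= dist_range_km[1] & d <= dist_range_km[2]
  cand <- isoline[west, ]
  if (nrow(cand) < 2) stop("isoline has no corridor west of the island in the requested band",
                           call. = FALSE)
  pick <- unique(round(seq(1, nrow(cand), length.out = n)))
  out <- cand[pick, c("lat", "lon")]
  # recycle if rounding collapsed duplicates
  while (nrow(out) < n) out <- dplyr::bind_rows(out, out[seq_len(min(n - nrow(out), nrow(out))), ])
  out[seq_len(n), ]
}

#' Run a homing scenario for one strategy
#'
#' Simulates `n_agents` virtual migrants from their start positions to
#' arrival, failure, or time-out, under one of three strategies:
#' `magnetic_only` follows the remembered intensity isoline and ignores odor;
#' `odor_only` swims its initial heading (no magnetic guidance) until odor
#' contact; `dual` follows the isoline until odor contact. After contact both
#' odor-using strategies track the plume up-flow and fall back to an
#' expanding-spiral search when contact is lost. Mode transitions are
#' monotone: isoline/transit -> (plume <-> search) -> arrived/failed.
#'
#' @param coeffs `gauss_set` of the present-day field (what agents sense).
#' @param flow [velocity_field()] used for up-flow plume tracking.
#' @param plume A `trajectory_set` (snapshots are taken at each step's
#'   simulation time, clamped to the recorded span), or a static
#'   `plume_snapshot`, or `NULL` for an odor-free world.
#' @param start Tibble/data frame with `lat`, `lon` start positions (one row
#'   per agent).
#' @param island `c(lat, lon)` of the target island.
#' @param params [agent_params()].
#' @param dt_h Step (hours).
#' @param plume_time_offset_h Added to the agent clock when indexing plume
#'   snapshots (aligns homing time with the plume season).
#' @param record_interval_h Track recording cadence.
#' @return A `scenario_outcome`: list with `agents` (final states and
#'   outcomes), `tracks` (recorded positions), `params`, and summary fields
#'   `n_arrived`, `success_rate`, `median_arrival_days`.
#' @export
run_scenario <- function(coeffs, flow, plume, start, island, params,
                         dt_h = 0.5, plume_time_offset_h = 0,
                         record_interval_h = 12) {
  n <- nrow(start)
  init_mode <- switch(params$strategy,
                      magnetic_only = "isoline", dual = "isoline",
                      odor_only = "transit")
  agents <- new_agents(start$lat, start$lon, init_mode)
  if (params$strategy == "odor_only") {
    # no magnetic guidance: agents hold the direction of travel of the
    # migration (due east along the corridor), not the bearing to the island
    agents$heading <- 90
  } else {
    # sets the sign of the initial isoline tangent (island side)
    agents$heading <- vec_bearing(
      (island[2] - agents$lon) * cos(agents$lat * pi / 180),
      island[1] - agents$lat)
  }
  arrival_h <- rep(NA_real_, n)
  steps <- seq(0, params$time_limit_days * 24, by = dt_h)
  tracks <- list(); rec <- 0L
  snap_cache_t <- NA_real_; snap <- NULL
  use_odor <- params$strategy %in% c("odor_only", "dual") && !is.null(plume)
  for (t in steps) {
    active <- !(agents$mode %in% c("arrived", "failed"))
    if (!any(active)) break
    # plume snapshot for this instant
    if (use_odor) {
      if (inherits(plume, "trajectory_set")) {
        tt <- min(max(t + plume_time_offset_h, plume$t_start), plume$t_end)
        t_near <- unique(plume$history$time)
        t_near <- t_near[which.min(abs(t_near - tt))]
        if (!identical(t_near, snap_cache_t)) {
          snap <- snapshot(plume, t_near)
          snap_cache_t <- t_near
        }
      } else {
        snap <- plume
      }
    }
    # arrivals
    d_isl <- haversine_km(agents$lat, agents$lon, island[1], island[2])
    hit <- active & d_isl <= params$island_radius_km
    if (any(hit)) {
      agents$mode[hit] <- "arrived"
      arrival_h[hit & is.na(arrival_h)] <- t
      active <- active & !hit
    }
    # detection and transitions (forward only)
    if (use_odor) {
      det <- odor_detected(agents, snap, params$detection_radius_km)
      promote <- det & agents$mode %in% c("isoline", "transit", "search")
      agents$mode[promote] <- "plume"
      agents$lost_h[det & agents$mode == "plume"] <- 0
      lost <- !det & agents$mode == "plume"
      agents$lost_h[lost] <- agents$lost_h[lost] + dt_h
      demote <- agents$lost_h > params$lost_lapse_h & agents$mode == "plume"
      if (any(demote)) {
        if (params$search == "expanding_spiral") {
          agents$mode[demote] <- "search"
          agents$center_lat[demote] <- agents$lat[demote]
          agents$center_lon[demote] <- agents$lon[demote]
          agents$spiral_theta[demote] <- 0
        } else {
          agents$mode[demote] <- "failed"
        }
        agents$lost_h[demote] <- 0
      }
    }
    # movement by mode
    agents <- isoline_following_step(coeffs, agents, params, dt_h)
    agents <- swim_forward(agents, agents$mode == "transit",
                           params$swim_speed, dt_h)
    if (use_odor) {
      agents <- plume_following_step(flow, agents, params, dt_h, snap,
                                     t + plume_time_offset_h)
      agents <- search_step(agents, params, dt_h)
    }
    agents$elapsed_h[active] <- agents$elapsed_h[active] + dt_h
    if (abs(t %% record_interval_h) < dt_h / 2) {
      rec <- rec + 1L
      tracks[[rec]] <- tibble::tibble(time = t, id = agents$id,
                                      lat = agents$lat, lon = agents$lon,
                                      mode = agents$mode)
    }
  }
  agents$mode[agents$mode != "arrived"] <- "failed"
  agents$outcome <- ifelse(is.na(arrival_h), "failed", "arrived")
  agents$arrival_h <- arrival_h
  out <- list(agents = agents, tracks = dplyr::bind_rows(tracks),
              params = params, island = island,
              n_agents = n, n_arrived = sum(!is.na(arrival_h)),
              success_rate = mean(!is.na(arrival_h)),
              median_arrival_days = stats::median(arrival_h / 24, na.rm = TRUE))
  class(out) <- "scenario_outcome"
  out
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf(
    "<scenario_outcome> strategy %s: %d/%d arrived (%.1f%%), median %.1f days\n",
    x$params$strategy, x$n_arrived, x$n_agents, 100 * x$success_rate,
    x$median_arrival_days))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scenario_outcome <- function(x, ...) {
  dplyr::select(x$agents, "id", "outcome", "arrival_h", "path_km",
                final_lat = "lat", final_lon = "lon", final_mode = "mode")
}

#' @exportS3Method generics::glance
glance.scenario_outcome <- function(x, ...) {
  tibble::tibble(strategy = x$params$strategy, n_agents = x$n_agents,
                 n_arrived = x$n_arrived, success_rate = x$success_rate,
                 median_arrival_days = x$median_arrival_days)
}
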