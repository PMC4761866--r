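#' Default run configuration
#'
#' A single nested list drives the whole analysis; [read_config()] loads and
#' validates a YAML or JSON file against these defaults (unknown keys are
#' rejected, known keys override).
#'
#' @return Named list of configuration defaults.
#' @export
magplume_config <- function() {
  list(
    seed = 1L,
    output_dir = "magplume-output",
    coefficients_file = NULL,            # NULL = vendored IGRF-style table
    reference_point = c(-7.933, -14.367),
    geomag = list(window_lat = c(-25, 10), window_lon = c(-45, 5),
                  step_deg = 0.1),
    drift = list(t0s = NULL, deltas = c(5, 25)),
    plume = list(velocity_file = NULL,   # NULL = synthetic eddy field
                 years = 1:4, lifetimes = c(15, 30, 45),
                 k_snapshots = 10, buffer_km = 10, dt = 2, K_h = 10,
                 per_layer = 20, layer_depths = c(0, 10, 20, 30, 50),
                 season_days = 45, frozen_daily = FALSE,
                 ocean = list(mean_u = -0.25, mean_v = 0.12, n_eddies = 6,
                              eddy_amp = 8000, eddy_radius_km = 60,
                              eddy_drift = 0.05,
                              lat_range = c(-12, -4), lon_range = c(-19, -10),
                              step_deg = 0.08)),
    navigation = list(n_agents = 200, drift_km = 100,
                      strategies = c("magnetic_only", "odor_only", "dual"),
                      detection_radius_km = 15, swim_speed = 0.6,
                      time_limit_days = 30, dt_h = 0.5)
  )
}

#' Load and validate a run configuration
#'
#' @param path YAML or JSON file; keys not present in [magplume_config()] are
#'   rejected, missing keys take defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(magplume_config(), user, prefix = "")
}

merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste0(prefix, extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     prefix = paste0(prefix, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10), tmp)
  unname(tools::md5sum(tmp))
}

load_series <- function(config) {
  read_igrf(config$coefficients_file %||% magplume_igrf_file())
}

meta_lines <- function(config) {
  c(sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %d", as.integer(config$seed)))
}

write_table_with_meta <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(config), con)
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ round(.x, 6)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Pipeline stages
#'
#' Config-driven orchestration of the full analysis. Each stage recomputes
#' what it needs from the configuration, writes its outputs (CSV/JSON/GeoJSON
#' stamped with the configuration hash and seed) under `output_dir`, and
#' returns its result invisibly. `run_full()` chains all stages.
#'
#' `run_isoline_drift()`: drift distances of the reference-point intensity
#' isoline for every configured (start year, interval) pair.
#' `run_simulate_plume()`: per-year synthetic-flow dispersal runs.
#' `run_intersections()`: plume-isoline intersection rates per odorant
#' lifetime and year. `run_navigate()`: strategy comparison on the standard
#' scenario.
#'
#' @param config Configuration list (see [magplume_config()], [read_config()]).
#' @return The stage result, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_isoline_drift <- function(config = magplume_config()) {
  series <- load_series(config)
  tab <- isoline_drift_table(series, config$reference_point,
                             t0s = config$drift$t0s,
                             deltas = config$drift$deltas,
                             lat_range = config$geomag$window_lat,
                             lon_range = config$geomag$window_lon,
                             step_deg = config$geomag$step_deg)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_with_meta(tab, file.path(config$output_dir, "isoline_drift.csv"),
                        config)
  jsonlite::write_json(
    c(list(config_hash = config_hash(config), seed = config$seed),
      list(drift = tab)),
    file.path(config$output_dir, "isoline_drift.json"),
    auto_unbox = TRUE, digits = 6)
  invisible(tab)
}

plume_make_field <- function(config) {
  oc <- config$plume$ocean
  function(seed) {
    if (!is.null(config$plume$velocity_file)) {
      read_velocity_nc(config$plume$velocity_file)
    } else {
      synth_ocean_field(mean_u = oc$mean_u, mean_v = oc$mean_v,
                        n_eddies = oc$n_eddies, eddy_amp = oc$eddy_amp,
                        eddy_radius_km = oc$eddy_radius_km,
                        eddy_drift = oc$eddy_drift,
                        lat_range = oc$lat_range, lon_range = oc$lon_range,
                        step_deg = oc$step_deg,
                        depths = config$plume$layer_depths,
                        n_days = config$plume$season_days, seed = seed)
    }
  }
}

plume_schedule <- function(config) {
  release_schedule(zone_center = config$reference_point,
                   layer_depths = config$plume$layer_depths,
                   per_layer_per_release = config$plume$per_layer,
                   lifetime_days = max(config$plume$lifetimes))
}

#' @rdname pipeline
#' @export
run_simulate_plume <- function(config = magplume_config()) {
  make_field <- plume_make_field(config)
  sched <- plume_schedule(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- purrr::map(seq_along(config$plume$years), function(i) {
    yr <- config$plume$years[i]
    seed <- as.integer(config$seed) + i - 1L
    field <- make_field(seed)
    traj <- advect(sched, field,
                   dispersion = dispersion_params(K_h = config$plume$K_h),
                   t_end = min(sched$season_hours, max(field$times)),
                   dt = config$plume$dt, seed = seed,
                   frozen_daily = isTRUE(config$plume$frozen_daily))
    write_table_with_meta(
      traj$history,
      file.path(config$output_dir, sprintf("trajectories_year%s.csv", yr)),
      config)
    traj
  })
  names(runs) <- as.character(config$plume$years)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   years = config$plume$years,
                   n_particles = vapply(runs, function(r) nrow(r$particles), 0))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "plume_manifest.json"),
                       auto_unbox = TRUE)
  invisible(runs)
}

#' @rdname pipeline
#' @export
run_intersections <- function(config = magplume_config()) {
  series <- load_series(config)
  results <- purrr::map_dfr(config$drift$deltas, function(delta) {
    t0 <- max(series$epochs) - delta
    rep <- drifted_isoline(series, config$reference_point, t0, delta,
                           lat_range = config$geomag$window_lat,
                           lon_range = config$geomag$window_lon,
                           step_deg = max(config$geomag$step_deg, 0.2))
    iso <- attr(rep, "isoline")
    duration_sensitivity(plume_make_field(config), plume_schedule(config),
                         iso, lifetimes = config$plume$lifetimes,
                         years = config$plume$years,
                         seeds = as.integer(config$seed) +
                           seq_along(config$plume$years) - 1L,
                         k_snapshots = config$plume$k_snapshots,
                         buffer_km = config$plume$buffer_km,
                         dispersion = dispersion_params(K_h = config$plume$K_h),
                         dt = config$plume$dt) |>
      dplyr::mutate(delta_years = delta)
  })
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_with_meta(results,
                        file.path(config$output_dir, "intersections.csv"),
                        config)
  invisible(results)
}

#' @rdname pipeline
#' @export
run_navigate <- function(config = magplume_config()) {
  nv <- config$navigation
  scn <- standard_scenario(seed = as.integer(config$seed),
                           n_agents = nv$n_agents, drift_km = nv$drift_km)
  cmp <- compare_strategies(scn, strategies = nv$strategies,
                            detection_radius_km = nv$detection_radius_km,
                            swim_speed = nv$swim_speed,
                            time_limit_days = nv$time_limit_days,
                            dt_h = nv$dt_h)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_table_with_meta(cmp$summary,
                        file.path(config$output_dir, "navigation.csv"),
                        config)
  invisible(cmp)
}

#' @rdname pipeline
#' @export
run_full <- function(config = magplume_config()) {
  invisible(list(drift = run_isoline_drift(config),
                 plumes = run_simulate_plume(config),
                 intersections = run_intersections(config),
                 navigation = run_navigate(config)))
}

#' GeoJSON export helpers
#'
#' Isolines become `MultiLineString` features (one line per segment) with
#' `level_nT` and `time` properties; snapshots become `MultiPoint` features.
#' Coordinates are written lon-first at fixed 6-decimal precision so reruns
#' are byte-identical.
#'
#' @param x An [isoline] or `plume_snapshot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  coords6 <- function(lon, lat) {
    lapply(seq_along(lon), function(i) {
      c(as.numeric(sprintf("%.6f", lon[i])), as.numeric(sprintf("%.6f", lat[i])))
    })
  }
  if (inherits(x, "isoline")) {
    segs <- split(x, x$segment)
    geom <- list(type = "MultiLineString",
                 coordinates = lapply(segs, function(s) coords6(s$lon, s$lat)))
    props <- list(level_nT = attr(x, "level"), time = attr(x, "time"))
  } else {
    geom <- list(type = "MultiPoint", coordinates = coords6(x$lon, x$lat))
    props <- list(time = attr(x, "time"), n_particles = nrow(x))
  }
  feature <- list(type = "Feature", properties = props, geometry = geom)
  fc <- list(type = "FeatureCollection", features = list(feature))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
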