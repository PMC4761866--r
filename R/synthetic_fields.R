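#' Synthetic mesoscale ocean flow with known ground truth
#'
#' Builds a divergence-free flow from a streamfunction: a uniform mean current
#' plus a sum of Gaussian eddies whose centers are seeded reproducibly and may
#' drift with the mean flow. Velocities are obtained by central-differencing
#' the streamfunction on the grid, so the discrete divergence vanishes by
#' construction (passive plumes neither concentrate nor evacuate, mirroring
#' the near-incompressibility of mesoscale surface flow). Depth layers share
#' the mean flow but get independently seeded eddy phases, emulating vertical
#' shear.
#'
#' @param mean_u,mean_v Mean current (m/s).
#' @param n_eddies Number of Gaussian eddies per depth layer.
#' @param eddy_amp Streamfunction amplitude (m^2/s); an eddy of amplitude
#'   `A` and radius `r` has peak swirl speed about `A * exp(-0.5) / r`.
#' @param eddy_radius_km Eddy e-folding radius (km).
#' @param eddy_drift Eddy-center drift speed along the mean-flow direction
#'   (m/s); 0 freezes the eddy field in time.
#' @param lat_range,lon_range Domain (degrees); default is a roughly
#'   900 x 900 km box around Ascension Island.
#' @param step_deg Grid spacing (degrees); default 0.08 mirrors the
#'   resolution of global ocean hindcasts.
#' @param depths Depth layers (m).
#' @param n_days Length of the run; one velocity snapshot per day (00:00).
#' @param seed Integer seed; same seed, same field.
#' @return A [velocity_field()].
#' @export
synth_ocean_field <- function(mean_u = -0.25, mean_v = 0.12, n_eddies = 6,
                              eddy_amp = 8000, eddy_radius_km = 60,
                              eddy_drift = 0.05,
                              lat_range = c(-12, -4), lon_range = c(-19, -10),
                              step_deg = 0.08,
                              depths = c(0, 10, 20, 30, 50),
                              n_days = 45, seed = 1) {
  stopifnot(eddy_radius_km > 0, n_eddies >= 0, n_days >= 1)
  lats <- seq(lat_range[1], lat_range[2], by = step_deg)
  lons <- seq(lon_range[1], lon_range[2], by = step_deg)
  lat0 <- mean(lat_range)
  R <- EARTH_RADIUS_KM * 1000
  y <- R * lats * pi / 180                       # meters northward
  x <- R * cos(lat0 * pi / 180) * lons * pi / 180  # meters eastward
  span_x <- diff(range(x)); span_y <- diff(range(y))
  sigma <- eddy_radius_km * 1000
  if (n_eddies > 0 && (span_x < sigma || span_y < sigma)) {
    stop("domain smaller than one eddy radius", call. = FALSE)
  }
  times <- seq(0, n_days * 24, by = 24)
  nt <- length(times); nd <- length(depths)
  nlat <- length(lats); nlon <- length(lons)

  # eddy centers/signs per depth layer, reproducible in seed
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  centers <- lapply(seq_len(nd), function(d) {
    if (n_eddies == 0) return(NULL)
    list(x = stats::runif(n_eddies, min(x), max(x)),
         y = stats::runif(n_eddies, min(y), max(y)),
         s = sample(c(-1, 1), n_eddies, replace = TRUE))
  })
  sp <- sqrt(mean_u^2 + mean_v^2)
  drift_dir <- if (sp > 0) c(mean_u, mean_v) / sp else c(-1, 0)

  u <- array(0, c(nt, nd, nlat, nlon))
  v <- array(0, c(nt, nd, nlat, nlon))
  dx <- if (nlon > 1) x[2] - x[1] else 1
  dy <- if (nlat > 1) y[2] - y[1] else 1
  for (ti in seq_len(nt)) {
    tsec <- times[ti] * 3600
    for (d in seq_len(nd)) {
      # psi = -mean_u * y + mean_v * x + eddies; u = -dpsi/dy, v = dpsi/dx
      psi <- outer(-mean_u * y, rep(1, nlon)) + outer(rep(1, nlat), mean_v * x)
      cc <- centers[[d]]
      if (!is.null(cc)) {
        for (ei in seq_len(n_eddies)) {
          cx <- cc$x[ei] + eddy_drift * drift_dir[1] * tsec
          cy <- cc$y[ei] + eddy_drift * drift_dir[2] * tsec
          # wrap drifting centers through the domain so eddies persist
          cx <- min(x) + (cx - min(x)) %% span_x
          cy <- min(y) + (cy - min(y)) %% span_y
          g <- outer(exp(-(y - cy)^2 / (2 * sigma^2)),
                     exp(-(x - cx)^2 / (2 * sigma^2)))
          psi <- psi + cc$s[ei] * eddy_amp * g
        }
      }
      # central differences (one-sided at edges)
      ddy <- psi; ddx <- psi
      if (nlat > 2) {
        ddy[2:(nlat - 1), ] <- (psi[3:nlat, ] - psi[1:(nlat - 2), ]) / (2 * dy)
        ddy[1, ] <- (psi[2, ] - psi[1, ]) / dy
        ddy[nlat, ] <- (psi[nlat, ] - psi[nlat - 1, ]) / dy
      } else ddy[] <- 0
      if (nlon > 2) {
        ddx[, 2:(nlon - 1)] <- (psi[, 3:nlon] - psi[, 1:(nlon - 2)]) / (2 * dx)
        ddx[, 1] <- (psi[, 2] - psi[, 1]) / dx
        ddx[, nlon] <- (psi[, nlon] - psi[, nlon - 1]) / dx
      } else ddx[] <- 0
      u[ti, d, , ] <- -ddy
      v[ti, d, , ] <- ddx
    }
  }
  velocity_field(lats, lons, depths, times, u, v)
}

# save/restore the global RNG state so generators are pure in (params, seed)
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic trade-wind field
#'
#' Spatially uniform wind toward a fixed bearing plus a temporally correlated
#' (AR(1), 6-hour decorrelation) Gaussian gust component. The default bearing
#' of 292.5 degrees pushes particles WNW, the persistent trade-wind direction
#' at Ascension.
#'
#' @param mean_speed Mean wind speed (m/s).
#' @param toward_bearing Direction the wind blows *toward*, degrees clockwise
#'   from north.
#' @param gust_sd Standard deviation of the gust components (m/s).
#' @param n_hours Length of the hourly series.
#' @param lat_range,lon_range Spatial domain covered (field is uniform).
#' @param seed Integer seed.
#' @return A [velocity_field()] with a single 0-m layer.
#' @export
synth_wind_field <- function(mean_speed = 7, toward_bearing = 292.5,
                             gust_sd = 1.5, n_hours = 48,
                             lat_range = c(-12, -4), lon_range = c(-19, -10),
                             seed = 1) {
  stopifnot(mean_speed >= 0, gust_sd >= 0, n_hours >= 1)
  br <- toward_bearing * pi / 180
  u0 <- mean_speed * sin(br)
  v0 <- mean_speed * cos(br)
  times <- seq(0, n_hours)
  nt <- length(times)
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rho <- exp(-1 / 6)
  ar1 <- function() {
    g <- numeric(nt)
    g[1] <- stats::rnorm(1, 0, gust_sd)
    for (i in seq_len(nt - 1)) {
      g[i + 1] <- rho * g[i] + sqrt(1 - rho^2) * stats::rnorm(1, 0, gust_sd)
    }
    g
  }
  gu <- if (gust_sd > 0) ar1() else numeric(nt)
  gv <- if (gust_sd > 0) ar1() else numeric(nt)
  lats <- lat_range; lons <- lon_range
  u <- array(rep(u0 + gu, times = 4), c(nt, 1, 2, 2))
  v <- array(rep(v0 + gv, times = 4), c(nt, 1, 2, 2))
  velocity_field(lats, lons, depths = 0, times = times, u = u, v = v)
}

#' Synthetic magnetic-field series with controllable secular drift
#'
#' Generates a Gauss-coefficient series whose intensity pattern translates at
#' a configured ground-truth velocity. The translation is implemented as an
#' exact rigid rotation of the dipole moment about a horizontal axis, so at
#' the reference point the pattern moves at exactly
#' `translation_km_per_yr` along `translation_bearing`. Optional static
#' anomaly terms (degree 2-3) add spatial structure; with anomalies the
#' translation ground truth holds only to first order, so drift-recovery
#' checks should use `anomaly = NULL`.
#'
#' @param base_g10 Dipole strength (nT) at the first epoch (the g(1,0) value
#'   an axial dipole of the same moment would have).
#' @param base_axis `c(lat, lon)` of the dipole axis pole at the first epoch;
#'   the default `c(90, 0)` is an axial dipole. An Earth-like tilt (~11
#'   degrees off the rotation axis) makes intensity isolines run obliquely to
#'   geographic parallels, as real ones do.
#' @param translation_km_per_yr Ground-truth pattern speed at the reference
#'   point (km/yr).
#' @param translation_bearing Direction of pattern motion, degrees clockwise
#'   from north (default 0 = north).
#' @param ref_point `c(lat, lon)` where the translation speed is exact.
#' @param anomaly Optional list of terms `list(key, n, m, value_nT)` with
#'   `key` "g" or "h", held constant over time.
#' @param epochs Decimal years (strictly increasing, evenly spaced).
#' @return A `gauss_series` with attribute `"translation"` recording the
#'   ground truth.
#' @export
synth_magnetic_series <- function(base_g10 = -30000, base_axis = c(90, 0),
                                  translation_km_per_yr = 0,
                                  translation_bearing = 0,
                                  ref_point = c(-7.933, -14.367),
                                  anomaly = NULL,
                                  epochs = seq(2000, 2030, by = 5)) {
  stopifnot(length(epochs) >= 1, all(diff(epochs) > 0))
  spacing <- if (length(epochs) > 1) min(diff(epochs)) else 1
  # refuse translations that rotate the pattern so far between epochs that
  # linear-in-time coefficient interpolation aliases it
  if (translation_km_per_yr * spacing > 1500) {
    stop("translation too fast for epoch spacing (pattern aliasing)", call. = FALSE)
  }
  nmax <- if (is.null(anomaly)) 1L else
    max(3L, max(vapply(anomaly, function(a) as.integer(a$n), 0L)))
  r0 <- latlon_to_unit(ref_point[1], ref_point[2])[1, ]
  br <- translation_bearing * pi / 180
  # local east/north at the reference point
  east <- c(-sin(ref_point[2] * pi / 180), cos(ref_point[2] * pi / 180), 0)
  north <- pracma_cross(r0, east)
  dhat <- sin(br) * east + cos(br) * north
  w <- pracma_cross(r0, dhat)          # rotation axis: moves r0 along dhat
  t0 <- epochs[1]
  m0 <- base_g10 * latlon_to_unit(base_axis[1], base_axis[2])[1, ]
  sets <- lapply(epochs, function(t) {
    alpha <- translation_km_per_yr * (t - t0) / EARTH_RADIUS_KM
    mrot <- rotate_about(m0, w, alpha)
    g <- matrix(0, nmax, nmax + 1L); h <- matrix(0, nmax, nmax + 1L)
    g[1, 1] <- mrot[3]; g[1, 2] <- mrot[1]; h[1, 2] <- mrot[2]
    for (a in anomaly %||% list()) {
      if (a$key == "g") g[a$n, a$m + 1L] <- a$value
      else h[a$n, a$m + 1L] <- a$value
    }
    new_gauss_set(t, g, h)
  })
  out <- new_gauss_series(sets, sv_g = matrix(0, nmax, nmax + 1L),
                          sv_h = matrix(0, nmax, nmax + 1L))
  attr(out, "translation") <- list(km_per_yr = translation_km_per_yr,
                                   bearing = translation_bearing,
                                   ref_point = ref_point)
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v about unit axis w by angle alpha
rotate_about <- function(v, w, alpha) {
  w <- w / sqrt(sum(w^2))
  v * cos(alpha) + pracma_cross(w, v) * sin(alpha) +
    w * sum(w * v) * (1 - cos(alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
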