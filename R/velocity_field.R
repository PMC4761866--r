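#' Gridded horizontal velocity fields
#'
#' A `velocity_field` holds eastward (`u`) and northward (`v`) velocity in m/s
#' on a regular lat/lon grid, for one or more depth layers and time steps
#' (hours since run start). Sampling is bilinear in space, linear in time and
#' nearest-neighbour in depth; queries outside the spatial or temporal hull
#' return `NA` (the tracker treats that as leaving the domain -- there is no
#' extrapolation).
#'
#' @param lats,lons Ascending coordinate vectors (degrees).
#' @param depths Depth layers in meters (>= 1).
#' @param times Time steps in hours since run start (>= 1).
#' @param u,v 4-D arrays `[time, depth, lat, lon]`, m/s.
#' @return A `velocity_field` object.
#' @export
velocity_field <- function(lats, lons, depths, times, u, v) {
  expect_dim <- c(length(times), length(depths), length(lats), length(lons))
  stopifnot(all(dim(u) == expect_dim), all(dim(v) == expect_dim),
            !is.unsorted(lats, strictly = TRUE),
            !is.unsorted(lons, strictly = TRUE),
            !is.unsorted(times))
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("velocity arrays contain non-finite values", call. = FALSE)
  }
  structure(list(lats = lats, lons = lons, depths = depths, times = times,
                 u = u, v = v),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %d times x %d depths x %d lats x %d lons\n",
    length(x$times), length(x$depths), length(x$lats), length(x$lons)))
  cat(sprintf("  lat [%g, %g], lon [%g, %g], t [%g, %g] h, depths {%s} m\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons),
              min(x$times), max(x$times),
              paste(x$depths, collapse = ", ")))
  invisible(x)
}

# fractional interpolation index: position of x in ascending grid g.
# Returns NA outside [g_1, g_n].
frac_index <- function(x, g) {
  i <- findInterval(x, g)
  out <- rep(NA_real_, length(x))
  inside <- !is.na(x) & x >= g[1] & x <= g[length(g)]
  i[inside & i == length(g)] <- length(g) - 1L   # right edge
  ok <- inside & i >= 1
  if (length(g) == 1) {
    out[inside] <- 1
    return(out)
  }
  out[ok] <- i[ok] + (x[ok] - g[i[ok]]) / (g[i[ok] + 1L] - g[i[ok]])
  out
}

#' Sample a velocity field
#'
#' @param field A [velocity_field()].
#' @param lat,lon Positions (degrees); vectors.
#' @param depth Depth in meters (scalar or vector); snapped to the nearest
#'   layer.
#' @param t_hours Time in hours (scalar or vector); linear interpolation, with
#'   `frozen_daily = TRUE` snapping to the 00:00 snapshot of the current day.
#' @param frozen_daily Logical; see above.
#' @return List with numeric vectors `u` and `v` (m/s); `NA` out of domain.
#' @export
sample_velocity <- function(field, lat, lon, depth = field$depths[1],
                            t_hours = field$times[1], frozen_daily = FALSE) {
  k <- max(length(lat), length(lon))
  lat <- rep_len(lat, k); lon <- rep_len(lon, k)
  depth <- rep_len(depth, k); t_hours <- rep_len(t_hours, k)
  if (frozen_daily) t_hours <- pmin(floor(t_hours / 24) * 24, max(field$times))
  fi <- frac_index(lat, field$lats)
  fj <- frac_index(lon, field$lons)
  ft <- frac_index(t_hours, field$times)
  # nearest depth layer
  di <- vapply(depth, function(d) which.min(abs(field$depths - d)), 0L)
  bad <- is.na(fi) | is.na(fj) | is.na(ft)
  u <- v <- rep(NA_real_, k)
  idx <- which(!bad)
  if (length(idx) > 0) {
    interp <- function(arr) {
      i0 <- pmin(floor(fi[idx]), length(field$lats) - (length(field$lats) > 1))
      j0 <- pmin(floor(fj[idx]), length(field$lons) - (length(field$lons) > 1))
      t0 <- pmin(floor(ft[idx]), length(field$times) - (length(field$times) > 1))
      i0 <- pmax(i0, 1); j0 <- pmax(j0, 1); t0 <- pmax(t0, 1)
      wi <- fi[idx] - i0; wj <- fj[idx] - j0; wt <- ft[idx] - t0
      i1 <- pmin(i0 + 1L, length(field$lats))
      j1 <- pmin(j0 + 1L, length(field$lons))
      t1 <- pmin(t0 + 1L, length(field$times))
      dd <- di[idx]
      at <- function(ti, ii, jj) arr[cbind(ti, dd, ii, jj)]
      lerp_t <- function(ii, jj) {
        (1 - wt) * at(t0, ii, jj) + wt * at(t1, ii, jj)
      }
      (1 - wi) * ((1 - wj) * lerp_t(i0, j0) + wj * lerp_t(i0, j1)) +
        wi * ((1 - wj) * lerp_t(i1, j0) + wj * lerp_t(i1, j1))
    }
    u[idx] <- interp(field$u)
    v[idx] <- interp(field$v)
  }
  list(u = u, v = v)
}

#' Read/write velocity fields as NetCDF (HYCOM-style variable names)
#'
#' Files carry dimensions `time` (hours), `depth` (m), `lat`, `lon` and
#' variables `water_u`, `water_v` (m/s), so synthetic fields and subsets of
#' real ocean-model output flow through the same reader. Requires the
#' \pkg{ncdf4} package.
#'
#' @param field A [velocity_field()].
#' @param path NetCDF file path.
#' @return `read_velocity_nc()` returns a [velocity_field()];
#'   `write_velocity_nc()` returns `path` invisibly.
#' @export
write_velocity_nc <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("NetCDF I/O requires the 'ncdf4' package", call. = FALSE)
  }
  dt <- ncdf4::ncdim_def("time", "hours since start", field$times)
  dd <- ncdf4::ncdim_def("depth", "m", field$depths)
  dla <- ncdf4::ncdim_def("lat", "degrees_north", field$lats)
  dlo <- ncdf4::ncdim_def("lon", "degrees_east", field$lons)
  vu <- ncdf4::ncvar_def("water_u", "m s-1", list(dlo, dla, dd, dt), prec = "double")
  vv <- ncdf4::ncvar_def("water_v", "m s-1", list(dlo, dla, dd, dt), prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  # our arrays are [time, depth, lat, lon]; NetCDF wants fastest-first lon
  ncdf4::ncvar_put(nc, vu, aperm(field$u, c(4, 3, 2, 1)))
  ncdf4::ncvar_put(nc, vv, aperm(field$v, c(4, 3, 2, 1)))
  invisible(path)
}

#' @rdname write_velocity_nc
#' @export
read_velocity_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("NetCDF I/O requires the 'ncdf4' package", call. = FALSE)
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dims <- nc$dim
  gv <- function(nm) as.numeric(dims[[nm]]$vals)
  u <- ncdf4::ncvar_get(nc, "water_u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "water_v", collapse_degen = FALSE)
  velocity_field(lats = gv("lat"), lons = gv("lon"), depths = gv("depth"),
                 times = gv("time"),
                 u = aperm(u, c(4, 3, 2, 1)), v = aperm(v, c(4, 3, 2, 1)))
}
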