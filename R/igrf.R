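#' Read a Gauss-coefficient table in the standard IGRF text layout
#'
#' Parses the whitespace-delimited coefficient format used by the International
#' Geomagnetic Reference Field: comment/header lines, then one row per
#' coefficient, keyed `g` or `h`, with degree `n`, order `m`, one value (nT) per
#' epoch column, and a final predictive secular-variation column (nT/yr).
#'
#' @param source Path to a coefficient file, or a character vector of lines.
#' @return A `gauss_series` object: epoch-ordered Gauss coefficient sets with
#'   the secular-variation column attached to the last epoch, and reference
#'   radius `a` = 6371.2 km.
#' @examples
#' series <- read_igrf(magplume_igrf_file())
#' series$epochs
#' @export
read_igrf <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^#", lines)]
  # drop the "c/s" style header row(s): anything whose first token is not g/h
  is_data <- grepl("^[gh]\\s", lines)
  header <- lines[!is_data]
  data <- lines[is_data]
  if (length(data) == 0) {
    stop("no coefficient rows found: empty or header-only stream", call. = FALSE)
  }

  # epochs from the header if present, otherwise inferred from column count
  toks <- strsplit(data, "\\s+")
  ncol_val <- unique(lengths(toks)) - 3L
  if (length(ncol_val) != 1) {
    bad <- which(lengths(toks) != (ncol_val[1] + 3L))[1]
    stop("malformed coefficient row (ragged columns) at data line ", bad,
         ": '", data[bad], "'", call. = FALSE)
  }
  epochs <- NULL
  if (length(header) > 0) {
    hd <- strsplit(utils::tail(header, 1), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(hd))
    epochs <- num[!is.na(num)]
  }
  has_sv <- TRUE
  if (!is.null(epochs) && length(epochs) == ncol_val) {
    has_sv <- FALSE # no SV column
  } else if (is.null(epochs) || length(epochs) != ncol_val - 1L) {
    # fall back: assume last column is SV, 5-yr spacing from 1900 is not
    # assumed -- epochs must come from the header
    stop("cannot determine epoch columns from header; expected a header row ",
         "listing one decimal year per value column", call. = FALSE)
  }
  n_epoch <- if (has_sv) ncol_val - 1L else ncol_val
  if (any(diff(epochs) <= 0)) {
    stop("epoch columns must be strictly increasing", call. = FALSE)
  }

  key <- vapply(toks, `[[`, "", 1L)
  n <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 2L)))
  m <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 3L)))
  vals <- t(vapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[-(1:3)]))
    v
  }, numeric(ncol_val)))
  bad <- which(is.na(n) | is.na(m) | apply(is.na(vals), 1, any))
  if (length(bad) > 0) {
    stop("malformed coefficient row (non-numeric cell) at data line ", bad[1],
         ": '", data[bad[1]], "'", call. = FALSE)
  }
  if (any(m > n) || any(n < 1) || any(m < 0)) {
    stop("invalid degree/order: require 1 <= n and 0 <= m <= n", call. = FALSE)
  }
  nmax <- max(n)

  empty <- function() matrix(0, nrow = nmax, ncol = nmax + 1L)
  sets <- lapply(seq_len(n_epoch), function(j) {
    g <- empty(); h <- empty()
    for (i in seq_along(key)) {
      if (key[i] == "g") g[n[i], m[i] + 1L] <- vals[i, j]
      else h[n[i], m[i] + 1L] <- vals[i, j]
    }
    new_gauss_set(epoch = epochs[j], g = g, h = h)
  })
  sv_g <- empty(); sv_h <- empty()
  if (has_sv) {
    for (i in seq_along(key)) {
      if (key[i] == "g") sv_g[n[i], m[i] + 1L] <- vals[i, ncol_val]
      else sv_h[n[i], m[i] + 1L] <- vals[i, ncol_val]
    }
  }
  new_gauss_series(sets, sv_g = sv_g, sv_h = sv_h)
}

#' Path to the bundled IGRF-style coefficient table
#'
#' The package ships a transcription of the published IGRF-13 Gauss-coefficient
#' table covering epochs 1900.0--2010.0 at 5-year intervals, truncated at
#' degree 10 (terms above degree 10 contribute at the ~1 nT level and are
#' irrelevant to isoline geometry at the scales analyzed here). The
#' transcription has not been re-verified against the official distribution;
#' residual transcription error, if any, is concentrated in high-degree
#' mid-century terms.
#'
#' @return File path of the vendored coefficient table.
#' @export
magplume_igrf_file <- function() {
  system.file("extdata", "igrf13coeffs_1900_2010_deg10.txt",
              package = "magplume", mustWork = TRUE)
}

new_gauss_set <- function(epoch, g, h) {
  stopifnot(is.matrix(g), is.matrix(h), all(dim(g) == dim(h)))
  if (any(!is.finite(g)) || any(!is.finite(h))) {
    stop("non-finite Gauss coefficient", call. = FALSE)
  }
  structure(list(epoch = epoch, max_degree = nrow(g), g = g, h = h),
            class = "gauss_set")
}

new_gauss_series <- function(sets, sv_g = NULL, sv_h = NULL, a = 6371.2) {
  epochs <- vapply(sets, `[[`, 0, "epoch")
  if (length(epochs) < 1) stop("need at least one epoch", call. = FALSE)
  if (any(diff(epochs) <= 0)) {
    stop("epochs must be strictly increasing", call. = FALSE)
  }
  structure(list(epochs = epochs, sets = sets, sv_g = sv_g, sv_h = sv_h, a = a),
            class = "gauss_series")
}

#' @export
print.gauss_series <- function(x, ...) {
  cat(sprintf("<gauss_series> %d epochs (%s-%s), max degree %d, a = %.1f km\n",
              length(x$epochs), min(x$epochs), max(x$epochs),
              x$sets[[1]]$max_degree, x$a))
  invisible(x)
}

#' @export
print.gauss_set <- function(x, ...) {
  cat(sprintf("<gauss_set> epoch %.1f, max degree %d, g(1,0) = %.1f nT\n",
              x$epoch, x$max_degree, x$g[1, 1]))
  invisible(x)
}

#' Serialize a Gauss-coefficient series back to the IGRF text layout
#'
#' @param series A `gauss_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_igrf <- function(series, path) {
  nmax <- series$sets[[1]]$max_degree
  hdr <- paste("g/h n m", paste(sprintf("%.1f", series$epochs), collapse = " "), "SV")
  rows <- character(0)
  fmt <- function(v) sub("\\.?0+$", "", sprintf("%.2f", v))
  for (n in seq_len(nmax)) {
    for (m in 0:n) {
      for (key in c("g", "h")) {
        if (key == "h" && m == 0) next
        vals <- vapply(series$sets, function(s) s[[key]][n, m + 1L], 0)
        sv <- if (key == "g") series$sv_g[n, m + 1L] else series$sv_h[n, m + 1L]
        rows <- c(rows, paste(key, n, m, paste(fmt(vals), collapse = " "), fmt(sv)))
      }
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Interpolate Gauss coefficients to an arbitrary date
#'
#' Linear interpolation in time between bracketing tabulated epochs (the IGRF
#' convention); beyond the last epoch the predictive secular-variation column
#' extrapolates linearly. At a tabulated epoch the stored set is returned
#' exactly.
#'
#' @param series A `gauss_series`.
#' @param t Decimal year, `t >=` first epoch.
#' @return A `gauss_set` at time `t`.
#' @export
coefficients_at <- function(series, t) {
  ep <- series$epochs
  if (t < ep[1]) {
    stop(sprintf("t = %.2f precedes first tabulated epoch %.2f", t, ep[1]),
         call. = FALSE)
  }
  k <- length(ep)
  if (t > ep[k]) {
    last <- series$sets[[k]]
    dt <- t - ep[k]
    sv_g <- if (is.null(series$sv_g)) 0 * last$g else series$sv_g
    sv_h <- if (is.null(series$sv_h)) 0 * last$h else series$sv_h
    return(new_gauss_set(t, last$g + dt * sv_g, last$h + dt * sv_h))
  }
  i <- findInterval(t, ep)
  if (ep[i] == t) {
    s <- series$sets[[i]]
    return(new_gauss_set(t, s$g, s$h))
  }
  f <- (t - ep[i]) / (ep[i + 1] - ep[i])
  a <- series$sets[[i]]; b <- series$sets[[i + 1]]
  new_gauss_set(t, (1 - f) * a$g + f * b$g, (1 - f) * a$h + f * b$h)
}

# Schmidt quasi-normalized associated Legendre functions and their
# colatitude derivatives, by stable upward recurrence, vectorized over theta.
# Returns list(P, dP): arrays [npts, n + 1, m + 1] indexed [i, n+1, m+1].
schmidt_legendre <- function(nmax, theta) {
  npts <- length(theta)
  ct <- cos(theta); st <- sin(theta)
  P <- array(0, dim = c(npts, nmax + 1L, nmax + 1L))
  dP <- array(0, dim = c(npts, nmax + 1L, nmax + 1L))
  P[, 1, 1] <- 1
  if (nmax >= 1) {
    P[, 2, 1] <- ct;            dP[, 2, 1] <- -st
    P[, 2, 2] <- st;            dP[, 2, 2] <- ct
  }
  for (n in seq_len(nmax)[-1]) {
    # sectoral m = n
    k <- sqrt((2 * n - 1) / (2 * n))
    P[, n + 1, n + 1] <- k * st * P[, n, n]
    dP[, n + 1, n + 1] <- k * (ct * P[, n, n] + st * dP[, n, n])
    for (m in 0:(n - 1)) {
      a1 <- (2 * n - 1) / sqrt(n^2 - m^2)
      a2 <- sqrt((n - 1)^2 - m^2) / sqrt(n^2 - m^2)
      P[, n + 1, m + 1] <- a1 * ct * P[, n, m + 1] - a2 * P[, n - 1, m + 1]
      dP[, n + 1, m + 1] <- a1 * (ct * dP[, n, m + 1] - st * P[, n, m + 1]) -
        a2 * dP[, n - 1, m + 1]
    }
  }
  list(P = P, dP = dP)
}

# clamp latitude away from the exact poles (1/sin(theta) singularity)
clamp_lat <- function(lat) pmin(pmax(lat, -89.9999), 89.9999)

#' Normalize longitudes to (-180, 180]
#' @param lon Longitudes in degrees east.
#' @return Normalized longitudes.
#' @export
norm_lon <- function(lon) {
  x <- (lon + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}

#' Evaluate geomagnetic field elements by spherical-harmonic synthesis
#'
#' Synthesizes the internal-field potential from a Gauss coefficient set with
#' Schmidt quasi-normalized associated Legendre functions, truncated at the
#' set's maximum degree, on the reference sphere r = a (geocentric convention).
#'
#' @param coeffs A `gauss_set` (see [coefficients_at()]).
#' @param lat,lon Vectors of geographic latitude / longitude in degrees
#'   (equal length, or one of them scalar).
#' @return A tibble with one row per position: `lat`, `lon`, the field vector
#'   `X` (north), `Y` (east), `Z` (down) in nT, horizontal intensity `H`,
#'   total intensity `F` (nT), inclination `I` and declination `D` (degrees).
#' @examples
#' dip <- dipole_set(-30000)
#' evaluate_field(dip, lat = c(0, 45, 90), lon = 0)
#' @export
evaluate_field <- function(coeffs, lat, lon) {
  stopifnot(inherits(coeffs, "gauss_set"))
  nmax <- coeffs$max_degree
  if (nmax < 1) stop("max_degree must be >= 1", call. = FALSE)
  k <- max(length(lat), length(lon))
  lat <- rep_len(lat, k); lon <- norm_lon(rep_len(lon, k))
  theta <- (90 - clamp_lat(lat)) * pi / 180
  phi <- lon * pi / 180
  leg <- schmidt_legendre(nmax, theta)
  st <- sin(theta)
  X <- Y <- Z <- numeric(k)
  for (n in seq_len(nmax)) {
    for (m in 0:n) {
      g <- coeffs$g[n, m + 1L]; h <- coeffs$h[n, m + 1L]
      if (g == 0 && h == 0) next
      cm <- cos(m * phi); sm <- sin(m * phi)
      gc_hs <- g * cm + h * sm
      X <- X + gc_hs * leg$dP[, n + 1, m + 1]
      if (m > 0) Y <- Y + m * (g * sm - h * cm) * leg$P[, n + 1, m + 1] / st
      Z <- Z - (n + 1) * gc_hs * leg$P[, n + 1, m + 1]
    }
  }
  field_elements_tbl(lat, lon, X, Y, Z)
}

field_elements_tbl <- function(lat, lon, X, Y, Z) {
  H <- sqrt(X^2 + Y^2)
  F <- sqrt(X^2 + Y^2 + Z^2)
  tibble::tibble(
    lat = lat, lon = lon, X = X, Y = Y, Z = Z, H = H, F = F,
    I = atan2(Z, H) * 180 / pi,
    D = atan2(Y, X) * 180 / pi
  )
}

#' Single-coefficient helpers for closed-form fixtures
#'
#' `dipole_set()` builds a pure axial-dipole coefficient set (only g(1,0)
#' non-zero); `tilted_dipole_set()` builds a dipole whose moment points along
#' an arbitrary axis.
#'
#' @param g10 Axial dipole coefficient in nT (negative for the Earth-like
#'   orientation with field pointing north at the equator).
#' @param epoch Decimal year tag.
#' @return A `gauss_set`.
#' @export
dipole_set <- function(g10 = -30000, epoch = 2000) {
  g <- matrix(0, 1, 2); h <- matrix(0, 1, 2)
  g[1, 1] <- g10
  new_gauss_set(epoch, g, h)
}

#' @rdname dipole_set
#' @param moment_nT Dipole strength in nT (the g(1,0) value an axial dipole of
#'   the same moment would have).
#' @param axis_lat,axis_lon Geographic coordinates (degrees) of the point the
#'   dipole axis exits through in the northern hemisphere sense.
#' @export
tilted_dipole_set <- function(moment_nT = -30000, axis_lat = 90, axis_lon = 0,
                              epoch = 2000) {
  th <- (90 - axis_lat) * pi / 180
  ph <- axis_lon * pi / 180
  nz <- cos(th); nx <- sin(th) * cos(ph); ny <- sin(th) * sin(ph)
  g <- matrix(0, 1, 2); h <- matrix(0, 1, 2)
  g[1, 1] <- moment_nT * nz
  g[1, 2] <- moment_nT * nx
  h[1, 2] <- moment_nT * ny
  new_gauss_set(epoch, g, h)
}

#' Grid of total intensity F over a latitude/longitude window
#'
#' Evaluates F on a regular grid via a longitude-separable synthesis (Legendre
#' functions computed once per latitude row), which keeps 0.1-degree corridor
#' grids fast.
#'
#' @param series A `gauss_series`.
#' @param t Decimal year.
#' @param lat_range,lon_range Numeric length-2 vectors, min < max, degrees.
#' @param step_deg Grid spacing in degrees (> 0).
#' @return A `scalar_grid`: list with ascending `lats`, `lons`, an
#'   `values` matrix (rows = lats) of F in nT, and `time = t`.
#' @export
intensity_grid <- function(series, t, lat_range = c(-25, 10),
                           lon_range = c(-45, 5), step_deg = 0.1) {
  stopifnot(step_deg > 0)
  if (lat_range[1] >= lat_range[2] || lon_range[1] >= lon_range[2]) {
    stop("degenerate lat/lon range (min >= max)", call. = FALSE)
  }
  coeffs <- if (inherits(series, "gauss_set")) series else coefficients_at(series, t)
  lats <- seq(lat_range[1], lat_range[2], by = step_deg)
  lons <- seq(lon_range[1], lon_range[2], by = step_deg)
  nmax <- coeffs$max_degree
  theta <- (90 - clamp_lat(lats)) * pi / 180
  leg <- schmidt_legendre(nmax, theta)
  st <- sin(theta)
  phi <- lons * pi / 180
  nlat <- length(lats); nlon <- length(lons)
  X <- matrix(0, nlat, nlon); Y <- matrix(0, nlat, nlon); Z <- matrix(0, nlat, nlon)
  for (m in 0:nmax) {
    ax <- bx <- az <- bz <- ay <- by <- numeric(nlat)
    for (n in seq(max(m, 1), nmax)) {
      g <- coeffs$g[n, m + 1L]; h <- coeffs$h[n, m + 1L]
      if (g == 0 && h == 0) next
      dPn <- leg$dP[, n + 1, m + 1]; Pn <- leg$P[, n + 1, m + 1]
      ax <- ax + g * dPn; bx <- bx + h * dPn
      az <- az - (n + 1) * g * Pn; bz <- bz - (n + 1) * h * Pn
      if (m > 0) {
        ay <- ay + m * g * Pn / st
        by <- by + m * h * Pn / st
      }
    }
    cm <- cos(m * phi); sm <- sin(m * phi)
    X <- X + outer(ax, cm) + outer(bx, sm)
    Z <- Z + outer(az, cm) + outer(bz, sm)
    if (m > 0) Y <- Y + outer(ay, sm) - outer(by, cm)
  }
  structure(list(lats = lats, lons = lons,
                 values = sqrt(X^2 + Y^2 + Z^2), time = t),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid> %d x %d nodes, lat [%g, %g], lon [%g, %g], t = %g\n",
              length(x$lats), length(x$lons), min(x$lats), max(x$lats),
              min(x$lons), max(x$lons), x$time))
  cat(sprintf("  F range: %.1f .. %.1f nT\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.scalar_grid <- function(x, ...) {
  tidyr::expand_grid(lat = x$lats, lon = x$lons) |>
    dplyr::mutate(F_nT = as.vector(t(x$values)), time = x$time)
}

#' Export an intensity grid to CSV (lat, lon, F_nT)
#' @param grid A `scalar_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as_tibble(grid), path, row.names = FALSE)
  invisible(path)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
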