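planar_grid <- function() {
  lats <- seq(0, 20, 0.5); lons <- seq(-10, 10, 0.5)
  structure(list(lats = lats, lons = lons,
                 values = matrix(rep(lats, length(lons)), nrow = length(lats)),
                 time = 2000),
            class = "scalar_grid")
}

test_that("contours of a planar field are the expected straight line", {
  comps <- extract_isolines(planar_grid(), 10.25)
  expect_length(comps, 1)
  expect_true(all(abs(comps[[1]]$lat - 10.25) < 1e-6))
  # level outside the range: empty, not an error
  expect_length(extract_isolines(planar_grid(), 99), 0)
  bad <- planar_grid(); bad$values[3, 3] <- NaN
  expect_error(extract_isolines(bad, 10), "non-finite")
})

test_that("axial-dipole isolines are latitude circles", {
  ser <- magplume:::new_gauss_series(list(dipole_set(-30000)))
  g <- intensity_grid(ser, 2000, c(-20, 0), c(-40, 0), 0.25)
  level <- evaluate_field(dipole_set(-30000), -10, 0)$F
  comps <- extract_isolines(g, level)
  for (p in comps) expect_lt(stats::sd(p$lat), 0.25)
})

test_that("every bracketing grid-cell edge is crossed by a contour vertex", {
  lats <- seq(0, 5, 0.5); lons <- seq(0, 5, 0.5)
  vals <- withr::with_seed(3, {
    outer(lats, lons, function(a, b) sin(a) + cos(b)) +
      matrix(stats::rnorm(length(lats) * length(lons), 0, 0.05),
             length(lats))
  })
  grid <- structure(list(lats = lats, lons = lons, values = vals, time = 0),
                    class = "scalar_grid")
  level <- stats::median(vals)
  comps <- extract_isolines(grid, level)
  verts <- dplyr::bind_rows(comps)
  # brute-force scan of vertical (constant-lon) edges
  n_cross <- 0; n_hit <- 0
  for (j in seq_along(lons)) {
    for (i in seq_len(length(lats) - 1)) {
      lo <- vals[i, j]; hi <- vals[i + 1, j]
      if ((lo - level) * (hi - level) < 0) {
        n_cross <- n_cross + 1
        frac <- (level - lo) / (hi - lo)
        vlat <- lats[i] + frac * 0.5
        hit <- any(abs(verts$lon - lons[j]) < 1e-9 &
                     abs(verts$lat - vlat) < 1e-6)
        n_hit <- n_hit + hit
      }
    }
  }
  expect_gt(n_cross, 10)
  expect_equal(n_hit, n_cross)
})

test_that("point-to-polyline distance matches closed forms and a dense oracle", {
  eq <- tibble::tibble(lat = rep(0, 21), lon = seq(-10, 10))
  # point on a vertex
  expect_equal(dist_point_to_polyline(0, 3, eq), 0)
  # one degree of meridian arc
  expect_equal(dist_point_to_polyline(1, 0, eq), pi * 6371 / 180,
               tolerance = 1e-6)
  # dense-sampling oracle on random point/polyline pairs
  withr::with_seed(21, {
    for (rep in 1:5) {
      pl <- tibble::tibble(lat = cumsum(stats::rnorm(8, 0, 1)) - 5,
                           lon = seq(-14, 0, by = 2))
      pt <- c(stats::runif(1, -10, 0), stats::runif(1, -15, 1))
      d_pkg <- dist_point_to_polyline(pt[1], pt[2], pl)
      # brute force: 1e4 points interpolated along the polyline (slerp)
      dense <- do.call(rbind, lapply(seq_len(nrow(pl) - 1), function(i) {
        f <- seq(0, 1, length.out = 1500)
        a <- magplume:::latlon_to_unit(pl$lat[i], pl$lon[i])[1, ]
        b <- magplume:::latlon_to_unit(pl$lat[i + 1], pl$lon[i + 1])[1, ]
        om <- acos(sum(a * b))
        w <- outer(sin((1 - f) * om), a) + outer(sin(f * om), b)
        w / sqrt(rowSums(w^2))
      }))
      ll <- magplume:::unit_to_latlon(dense)
      d_ora <- min(haversine_km(pt[1], pt[2], ll[, 1], ll[, 2]))
      expect_equal(d_pkg, d_ora, tolerance = 0.1)
    }
  })
  expect_error(dist_point_to_polyline(0, 0, eq[0, ]), "empty")
})

test_that("isoline through a point passes by it and is stationary for a static field", {
  ser <- magplume:::new_gauss_series(list(dipole_set(-30000)))
  iso <- isoline_through_point(ser, 2000, ascension,
                               lat_range = c(-14, -2), lon_range = c(-20, -8),
                               step_deg = 0.1)
  expect_lt(max(abs(iso$lat - ascension[1])), 0.1)
  expect_lt(min(dist_point_to_polyline(ascension[1], ascension[2], iso)), 11.2)

  iso2 <- isoline_through_point(ser, 2025, ascension,
                                lat_range = c(-14, -2), lon_range = c(-20, -8),
                                step_deg = 0.1)
  expect_equal(iso$lat, iso2$lat)
  expect_equal(iso$lon, iso2$lon)
  expect_error(isoline_through_point(ser, 2000, c(40, 0),
                                     lat_range = c(-14, -2),
                                     lon_range = c(-20, -8)),
               "outside the extraction window")
})

test_that("drift is zero for a static field and recovers a known translation", {
  ser <- magplume:::new_gauss_series(list(dipole_set(-30000)))
  rep0 <- drifted_isoline(ser, ascension, 2000, 25,
                          lat_range = c(-14, -2), lon_range = c(-20, -8),
                          step_deg = 0.1)
  expect_lt(rep0$drift_km, 11.2)  # one grid step

  mov <- synth_magnetic_series(translation_km_per_yr = 10,
                               epochs = seq(2000, 2030, 5))
  rep25 <- drifted_isoline(mov, ascension, 2000, 25,
                           lat_range = c(-14, -2), lon_range = c(-22, -8),
                           step_deg = 0.05)
  expect_equal(rep25$drift_km, 250, tolerance = 0.05)
  rep5 <- drifted_isoline(mov, ascension, 2000, 5,
                          lat_range = c(-14, -2), lon_range = c(-22, -8),
                          step_deg = 0.05)
  expect_equal(rep5$drift_km / 5, 10, tolerance = 0.05)
})

test_that("drift distance is invariant to vertex order and window enlargement", {
  mov <- synth_magnetic_series(translation_km_per_yr = 10,
                               epochs = seq(2000, 2030, 5))
  rep1 <- drifted_isoline(mov, ascension, 2000, 25,
                          lat_range = c(-14, -2), lon_range = c(-22, -8),
                          step_deg = 0.1)
  iso <- attr(rep1, "isoline")
  rev_iso <- iso[rev(seq_len(nrow(iso))), ]
  expect_equal(min(dist_point_to_polyline(ascension[1], ascension[2], iso)),
               min(dist_point_to_polyline(ascension[1], ascension[2], rev_iso)))
  rep2 <- drifted_isoline(mov, ascension, 2000, 25,
                          lat_range = c(-18, 2), lon_range = c(-26, -4),
                          step_deg = 0.1)
  expect_equal(rep1$drift_km, rep2$drift_km, tolerance = 0.02)
})

test_that("halving the grid step changes drift by less than one coarse step", {
  mov <- synth_magnetic_series(translation_km_per_yr = 10,
                               epochs = seq(2000, 2030, 5))
  d_coarse <- drifted_isoline(mov, ascension, 2000, 25,
                              lat_range = c(-14, -2), lon_range = c(-22, -8),
                              step_deg = 0.2)$drift_km
  d_fine <- drifted_isoline(mov, ascension, 2000, 25,
                            lat_range = c(-14, -2), lon_range = c(-22, -8),
                            step_deg = 0.1)$drift_km
  expect_lt(abs(d_coarse - d_fine), 0.2 * 111.195)
})

test_that("a level that left the window raises an informative error", {
  mov <- synth_magnetic_series(translation_km_per_yr = 100,
                               epochs = seq(2000, 2030, 5))
  expect_error(
    drifted_isoline(mov, ascension, 2000, 25,
                    lat_range = c(-9, -7), lon_range = c(-16, -13),
                    step_deg = 0.1),
    "left the window")
})
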