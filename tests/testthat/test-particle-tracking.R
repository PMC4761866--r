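test_that("release schedules produce the configured particle batches", {
  sched <- release_schedule()  # waterborne defaults
  expect_equal(sched$lifetime_days, 45)
  expect_equal(sched$season_hours / 24, 135)  # Dec 15 to Apr 29, non-leap
  batch <- withr::with_seed(1, release_particles(sched, 0))
  expect_equal(nrow(batch), 500)  # 100 particles x 5 depth layers
  expect_equal(sort(unique(batch$layer_depth)), c(0, 10, 20, 30, 50))
  expect_equal(nrow(release_particles(sched, sched$season_hours + 1)), 0)

  # leap-year season picks up the extra day
  leap <- release_schedule(year = 2003)
  expect_equal(leap$season_hours / 24, 136)

  degenerate <- release_schedule(zone_half_width_km = 0)
  b0 <- withr::with_seed(1, release_particles(degenerate, 0))
  expect_true(all(b0$lat == degenerate$zone_center[1]))
  expect_true(all(b0$lon == degenerate$zone_center[2]))
  expect_error(release_schedule(season_start = "04-29", season_end = "12-15",
                                year = 2004), NA)  # wraps into next year
})

test_that("released positions are uniform over the 10 x 10 km zone", {
  sched <- release_schedule(layer_depths = 0, per_layer_per_release = 1e4)
  b <- withr::with_seed(2, release_particles(sched, 0))
  dy <- (b$lat - sched$zone_center[1]) * magplume:::KM_PER_DEG
  dx <- (b$lon - sched$zone_center[2]) * magplume:::KM_PER_DEG *
    cos(sched$zone_center[1] * pi / 180)
  expect_lte(max(abs(dy)), 5)
  expect_lte(max(abs(dx)), 5)
  se <- 5 / sqrt(3) / sqrt(1e4)  # sd of U(-5,5) over sqrt(n)
  expect_lt(abs(mean(dx)), 3 * se)
  expect_lt(abs(mean(dy)), 3 * se)
})

test_that("RK4 is exact for uniform flow and conserves solid-body radius", {
  uf <- uniform_field(u = 1, v = 0)
  st <- rk4_step(uf, lat = -8, lon = -15, depth = 0, t = 0, dt = 1)
  expect_false(st$exited)
  expect_equal(st$lon + 15,
               3600 / (6371e3 * pi / 180) / cos(-8 * pi / 180),
               tolerance = 1e-12)
  expect_equal(st$lat, -8)
  st0 <- rk4_step(uniform_field(u = 0, v = 0), -8, -15, 0, 0, 1)
  expect_equal(st0$lon, -15)
  expect_equal(st0$lat, -8)

  # solid-body rotation about (0, -15): the velocity field is built so the
  # induced (lat, lon) system is an exact linear rotation
  omega <- 0.1  # rad/h
  m_per_deg <- 6371e3 * pi / 180
  lats <- seq(-0.5, 0.5, 0.01); lons <- seq(-15.5, -14.5, 0.01)
  uu <- array(0, c(2, 1, length(lats), length(lons)))
  vv <- uu
  for (i in seq_along(lats)) {
    for (j in seq_along(lons)) {
      uu[, 1, i, j] <- -omega * lats[i] * m_per_deg / 3600 *
        cos(lats[i] * pi / 180)
      vv[, 1, i, j] <- omega * (lons[j] + 15) * m_per_deg / 3600
    }
  }
  rot <- velocity_field(lats, lons, 0, c(0, 1000), uu, vv)
  pos <- c(lat = 0, lon = -15 + 0.3)
  r0 <- 0.3
  for (k in 1:100) {
    st <- rk4_step(rot, pos[["lat"]], pos[["lon"]], 0, t = 0, dt = 0.5)
    pos <- c(lat = unname(st$lat), lon = unname(st$lon))
  }
  r_end <- sqrt(pos[["lat"]]^2 + (pos[["lon"]] + 15)^2)
  expect_equal(r_end, r0, tolerance = 1e-6)
  # and the endpoint matches the analytic circle
  ang <- omega * 0.5 * 100
  expect_equal(pos[["lon"]] + 15, r0 * cos(ang), tolerance = 1e-4)
  expect_equal(pos[["lat"]], r0 * sin(ang), tolerance = 1e-4)
})

test_that("leaving the domain freezes the particle as exited", {
  uf <- uniform_field(u = 1, v = 0, lon_range = c(-19, -10))
  st <- rk4_step(uf, 0, -10.001, 0, 0, dt = 10)  # next step leaves east edge
  expect_true(st$exited || st$lon > -10)
  far <- rk4_step(uf, 0, -9.9, 0, 0, dt = 1)     # already outside
  expect_true(far$exited)
  expect_equal(far$lon, -9.9)
})

test_that("dispersion obeys the two-dimensional diffusion law", {
  p0 <- dispersion_params(K_h = 0)
  expect_equal(apply_dispersion(1:3, 4:6, p0, 1), list(lat = 1:3, lon = 4:6))

  K <- 100; dt <- 1
  n <- 1e5
  out <- withr::with_seed(8, apply_dispersion(rep(0, n), rep(0, n),
                                              dispersion_params(K_h = K), dt))
  m_per_deg <- 6371e3 * pi / 180
  d2 <- (out$lat * m_per_deg)^2 + (out$lon * m_per_deg)^2   # m^2
  msd_expect <- 4 * K * dt * 3600
  se <- stats::sd(d2) / sqrt(n)
  expect_lt(abs(mean(d2) - msd_expect), 3 * se)

  a <- withr::with_seed(5, apply_dispersion(rep(0, 10), rep(0, 10),
                                            dispersion_params(), 1))
  b <- withr::with_seed(5, apply_dispersion(rep(0, 10), rep(0, 10),
                                            dispersion_params(), 1))
  expect_identical(a, b)
})

test_that("the dispersal loop books releases, deaths and reruns exactly", {
  uf <- uniform_field(u = 0.3, v = 0)
  sched <- release_schedule(zone_center = c(-8, -14), zone_half_width_km = 0,
                            layer_depths = 0, per_layer_per_release = 5,
                            release_interval_h = 24, lifetime_days = 2)
  tr <- advect(sched, uf, dispersion = dispersion_params(enabled = FALSE),
               t_start = 0, t_end = 96, dt = 1, seed = 1,
               record_interval_h = 12)
  first <- tr$particles[tr$particles$release_time == 0, ]
  expect_true(all(first$status == "expired"))
  # not dead before 48 h: at the 48-h record the first batch is still alive
  h48 <- tr$history[tr$history$time == 48 & tr$history$release_time == 0, ]
  expect_true(all(h48$status == "alive"))
  h49 <- tr$history[tr$history$time == 60 & tr$history$release_time == 0, ]
  expect_true(all(h49$status == "expired"))

  # 10-day uniform eastward drift: 0.3 m/s * 10 d = 259.2 km
  sched10 <- release_schedule(zone_center = c(-8, -14), zone_half_width_km = 0,
                              layer_depths = 0, per_layer_per_release = 2,
                              lifetime_days = 45)
  tr10 <- advect(sched10, uf, dispersion = dispersion_params(enabled = FALSE),
                 t_start = 0, t_end = 240, dt = 1, seed = 1)
  p <- tr10$particles[tr10$particles$release_time == 0, ]
  expect_equal(p$lat[1], -8)
  # arc length along the parallel recovers u * t exactly
  expect_equal((p$lon[1] + 14) * cos(-8 * pi / 180) * magplume:::KM_PER_DEG,
               259.2, tolerance = 1e-9)
  expect_equal(haversine_km(-8, -14, p$lat[1], p$lon[1]), 259.2,
               tolerance = 1e-5)

  # bit-identical rerun
  tr_a <- small_plume_run(seed = 3)
  tr_b <- small_plume_run(seed = 3)
  expect_identical(tr_a$history, tr_b$history)
  expect_error(advect(sched, uf, dt = -1), "dt must be positive")
})

test_that("particles are conserved across statuses at every record", {
  tr <- small_plume_run(seed = 2, lifetime_days = 3, n_days = 8)
  by_time <- dplyr::count(tr$history, .data$time, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0)
  released_by <- vapply(by_time$time, function(t) {
    sum(tr$particles$release_time <= t)
  }, 0)
  tot <- rowSums(by_time[, setdiff(names(by_time), "time")])
  expect_equal(as.numeric(tot), released_by)
})

test_that("lifetime filtering yields nested living sets (superset property)", {
  tr <- small_plume_run(seed = 4, lifetime_days = 5, n_days = 10)
  expect_error(snapshot(tr, -5), "outside")
  expect_error(snapshot(tr, 1e6), "outside")
  for (t in c(48, 120, 192)) {
    s1 <- snapshot(tr, t, lifetime_days = 1)
    s3 <- snapshot(tr, t, lifetime_days = 3)
    s5 <- snapshot(tr, t, lifetime_days = 5)
    expect_true(all(s1$id %in% s3$id))
    expect_true(all(s3$id %in% s5$id))
    # identical positions for the shared particles
    j <- match(s1$id, s3$id)
    expect_equal(s1$lat, s3$lat[j])
    expect_equal(s1$lon, s3$lon[j])
  }
  expect_error(snapshot(tr, 48, lifetime_days = 10), "exceeds")
  # empty before the first release reaches the record
  uf <- uniform_field()
  sched <- release_schedule(zone_center = c(-8, -14), layer_depths = 0,
                            per_layer_per_release = 2, lifetime_days = 2)
  tr2 <- advect(sched, uf, t_start = -24, t_end = 48, dt = 1, seed = 1)
  expect_equal(nrow(snapshot(tr2, -24)), 0)
})

test_that("with dispersion off, trajectories do not depend on the seed", {
  uf <- uniform_field(u = 0.2, v = 0.1)
  sched <- release_schedule(zone_center = c(-8, -14), zone_half_width_km = 0,
                            layer_depths = 0, per_layer_per_release = 3,
                            lifetime_days = 10)
  tr1 <- advect(sched, uf, dispersion = dispersion_params(enabled = FALSE),
                t_end = 120, dt = 1, seed = 1)
  tr2 <- advect(sched, uf, dispersion = dispersion_params(enabled = FALSE),
                t_end = 120, dt = 1, seed = 999)
  expect_equal(tr1$history$lat, tr2$history$lat)
  expect_equal(tr1$history$lon, tr2$history$lon)
})

test_that("halving dt barely moves uniform-flow endpoints (RK4 exactness)", {
  uf <- uniform_field(u = 0.3, v = 0.1)
  sched <- release_schedule(zone_center = c(-8, -14), zone_half_width_km = 0,
                            layer_depths = 0, per_layer_per_release = 1,
                            lifetime_days = 45)
  end_pos <- function(dt) {
    tr <- advect(sched, uf, dispersion = dispersion_params(enabled = FALSE),
                 t_end = 240, dt = dt, seed = 1)
    p <- tr$particles[1, ]
    c(p$lat, p$lon)
  }
  a <- end_pos(1); b <- end_pos(0.5)
  expect_lt(haversine_km(a[1], a[2], b[1], b[2]), 0.001)  # < 1 m
})
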