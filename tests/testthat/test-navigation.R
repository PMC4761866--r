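dipole <- dipole_set(-30000)
dip_level_at <- function(lat) evaluate_field(dipole, lat, 0)$F

test_that("isoline following on a dipole runs along the parallel and corrects offsets", {
  params <- agent_params(strategy = "dual", target_level = dip_level_at(-8))
  on_iso <- magplume:::new_agents(-8, -15, "isoline", heading = 90)
  out <- isoline_following_step(dipole, on_iso, params, dt_h = 1)
  # on the isoline of an axial dipole: pure east-west motion
  expect_equal(out$heading, 90, tolerance = 0.5)
  expect_equal(out$lat, -8, tolerance = 1e-3)
  expect_gt(out$lon, -15)

  # southern hemisphere: F increases poleward (southward). An agent north of
  # the target isoline reads F below target; the correction points south.
  north_of <- magplume:::new_agents(-7.5, -15, "isoline", heading = 90)
  out2 <- isoline_following_step(dipole, north_of, params, dt_h = 1)
  expect_lt(out2$lat, -7.5)

  south_of <- magplume:::new_agents(-8.5, -15, "isoline", heading = 90)
  out3 <- isoline_following_step(dipole, south_of, params, dt_h = 1)
  expect_gt(out3$lat, -8.5)
})

test_that("the cross-track correction is contracting near the isoline", {
  withr::with_seed(31, {
    for (gain in c(0.5, 1, 2)) {
      params <- agent_params(strategy = "dual",
                             target_level = dip_level_at(-8),
                             crosstrack_gain = gain)
      lat0 <- -8 + stats::runif(1, -0.25, 0.25)
      ag <- magplume:::new_agents(lat0, -15, "isoline", heading = 90)
      err <- abs(evaluate_field(dipole, ag$lat, ag$lon)$F - params$target_level)
      for (k in 1:40) ag <- isoline_following_step(dipole, ag, params, 1)
      err_end <- abs(evaluate_field(dipole, ag$lat, ag$lon)$F -
                       params$target_level)
      expect_lt(err_end, err)
    }
  })
})

test_that("odor detection agrees with a brute-force nearest-particle scan", {
  snap <- tibble::tibble(id = 1:30,
                         lat = withr::with_seed(2, stats::runif(30, -10, -6)),
                         lon = withr::with_seed(3, stats::runif(30, -18, -12)),
                         layer_depth = 0, age = 0)
  class(snap) <- c("plume_snapshot", class(snap))
  ag <- magplume:::new_agents(seq(-10, -6, length.out = 15),
                              seq(-18, -12, length.out = 15), "isoline")
  got <- odor_detected(ag, snap, 30)
  brute <- vapply(seq_len(nrow(ag)), function(i) {
    any(haversine_km(ag$lat[i], ag$lon[i], snap$lat, snap$lon) <= 30)
  }, TRUE)
  expect_identical(got, brute)
  # particle exactly at the agent position
  at <- magplume:::new_agents(snap$lat[1], snap$lon[1], "isoline")
  expect_true(odor_detected(at, snap, 0.001))
  expect_false(any(odor_detected(ag, snap[0, ], 30)))
})

test_that("plume following heads up-flow in a uniform current", {
  uf <- uniform_field(u = 0.4, v = 0)   # eastward flow
  params <- agent_params(strategy = "dual", target_level = 1)
  ag <- magplume:::new_agents(-8, -15, "plume", heading = 0)
  out <- plume_following_step(uf, ag, params, dt_h = 1, snap = NULL, t_h = 0)
  expect_equal(out$heading, 270)        # heads west, against the flow
  expect_lt(out$lon, -15)
})

test_that("the expanding spiral has the pitch that closes detection gaps", {
  params <- agent_params(strategy = "dual", target_level = 1,
                         detection_radius_km = 10)
  ag <- magplume:::new_agents(-8, -15, "search")
  ag$center_lat <- -8; ag$center_lon <- -15; ag$spiral_theta <- 0
  path <- list()
  for (k in 1:2000) {
    ag <- search_step(ag, params, dt_h = 0.5)
    path[[k]] <- c(ag$spiral_theta, haversine_km(ag$lat, ag$lon, -8, -15))
  }
  m <- do.call(rbind, path)
  # radius at theta = 2*pi*n is n * pitch, pitch = 2 * detection radius
  b <- 2 * params$detection_radius_km / (2 * pi)
  expect_equal(m[, 2], b * m[, 1], tolerance = 0.01)
  # successive passes (theta and theta + 2 pi) differ by one pitch: no gap
  # wider than the detection diameter
  expect_equal(b * 2 * pi, 2 * params$detection_radius_km, tolerance = 1e-12)
  # path length equals swim distance: analytic Archimedean arc length
  s_expect <- 2000 * 0.5 * params$swim_speed * 3.6
  th <- m[nrow(m), 1]
  arc <- b / 2 * (th * sqrt(1 + th^2) + asinh(th))
  expect_equal(arc, s_expect, tolerance = 0.01)
})

test_that("dual strategy degrades exactly to magnetic-only without odor", {
  scn_series <- synth_magnetic_series(base_g10 = -30000, base_axis = c(55, -60),
                                      translation_km_per_yr = 4.4,
                                      translation_bearing = 180,
                                      epochs = seq(1980, 2005, 5))
  co <- coefficients_at(scn_series, 2005)
  tl <- evaluate_field(coefficients_at(scn_series, 1980), -7.933, -14.367)$F
  flow <- uniform_field(u = -0.1, v = -0.1, lat_range = c(-13, -6),
                        lon_range = c(-21, -12))
  start <- tibble::tibble(lat = c(-9.9, -10.1), lon = c(-17.5, -18))
  base <- agent_params(strategy = "magnetic_only", target_level = tl,
                       time_limit_days = 5)
  dual <- agent_params(strategy = "dual", target_level = tl,
                       time_limit_days = 5)
  o1 <- run_scenario(co, flow, NULL, start, c(-7.933, -14.367), base, dt_h = 1)
  o2 <- run_scenario(co, flow, NULL, start, c(-7.933, -14.367), dual, dt_h = 1)
  expect_identical(o1$agents$lat, o2$agents$lat)
  expect_identical(o1$agents$lon, o2$agents$lon)
  expect_identical(o1$success_rate, o2$success_rate)
})

test_that("an isoline missing the island makes magnetic-only navigation fail", {
  scn <- standard_scenario(seed = 2, n_agents = 10)
  params <- agent_params(strategy = "magnetic_only",
                         target_level = scn$target_level,
                         time_limit_days = 20)
  out <- run_scenario(scn$coeffs, scn$flow, NULL, scn$start, scn$island,
                      params, dt_h = 1)
  expect_equal(out$success_rate, 0)
  # agents did progress along the isoline; they just never got closer than
  # the drift distance minus detection slack
  d_min <- min(haversine_km(out$tracks$lat, out$tracks$lon,
                            scn$island[1], scn$island[2]))
  expect_gt(d_min, scn$drift_report$drift_km * 0.5)
})

test_that("mode transitions are monotone: no return to the isoline phase", {
  scn <- standard_scenario(seed = 3, n_agents = 12)
  params <- agent_params(strategy = "dual", target_level = scn$target_level)
  out <- run_scenario(scn$coeffs, scn$flow, scn$plume, scn$start, scn$island,
                      params, dt_h = 0.5,
                      plume_time_offset_h = scn$plume_time_offset_h)
  rank <- c(isoline = 1, transit = 1, plume = 2, search = 2,
            arrived = 3, failed = 3)
  by_agent <- split(out$tracks, out$tracks$id)
  left_isoline <- 0
  for (tr in by_agent) {
    r <- rank[tr$mode[order(tr$time)]]
    # once past the isoline phase, never back
    past <- cummax(r)
    expect_true(all(r[past >= 2] >= 2))
    if (any(r >= 2)) left_isoline <- left_isoline + 1
  }
  expect_gt(left_isoline, 0)
  # path length bounded by swim speed x elapsed time
  expect_true(all(out$agents$path_km <=
                    params$swim_speed * 3.6 * (out$agents$elapsed_h + 1)))
})
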