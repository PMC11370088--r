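test_that("reference paths integrate point speed into distance", {
  fl <- straight_path(31, v = 10)            # 30 steps of 1 s at 10 m/s
  ref <- build_reference(fl)
  expect_equal(ref$D0, 300)
  expect_equal(ref$dt, 1)
  expect_equal(max(abs(ref$theta0)), 0, tolerance = 1e-6)
  fl$speed[5] <- NA
  expect_error(build_reference(fl), "indices 5")
  irregular <- gps_path(c(0, 1, 3), c(0, 1e-4, 3e-4), rep(-46, 3), 10)
  expect_error(build_reference(irregular), "uniform")
})

test_that("sub-sampling lands on exact multiples of k", {
  fl <- straight_path(101, v = 10)
  s1 <- subsample(fl, 1)                     # k = nominal: identity
  expect_equal(s1$lon, fl$lon)
  expect_equal(s1$lat, fl$lat)
  s10 <- subsample(fl, 10)
  expect_length(s10$time, 11)
  expect_length(s10$dist, 10)
  expect_equal(s10$time, fl$time[1] + 10 * 0:10)
  # interpolation at a node reproduces the recorded fix exactly
  p3 <- gps_path(0:4, c(0, 0.001, 0.0025, 0.0031, 0.0042),
                 c(-46, -46.001, -46.0015, -46.0022, -46.003), 10)
  s2 <- subsample(p3, 2)
  expect_identical(s2$lon, p3$lon[c(1, 3, 5)])
  expect_identical(s2$lat, p3$lat[c(1, 3, 5)])
  expect_error(subsample(fl, 60), "too short")
  expect_error(subsample(fl, 0.5), "below the nominal")
})

test_that("PD is exactly 1 on noise-free geodesic tracks", {
  fl <- straight_path(5001, v = 12)
  ref <- build_reference(fl)
  for (k in c(1, 7, 60, 999))
    expect_equal(proportional_distance(ref, subsample(fl, k)), 1,
                 tolerance = 1e-6)
})

test_that("PD on a noise-free circle matches the chord/arc closed form", {
  fl <- circle_track(duration = 1000, r = 100, v = 10)
  ref <- build_reference(fl)
  # theta = v k / r radians; chord / arc = sin(theta/2) / (theta/2)
  for (k in c(5, 10, 20)) {
    theta <- 10 * k / 100
    expect_equal(proportional_distance(ref, subsample(fl, k)),
                 sin(theta / 2) / (theta / 2), tolerance = 1e-3)
  }
  # PD decreases monotonically with k (deepening interpolation error)
  pd <- vapply(c(2, 5, 10, 20, 25, 50), function(k)
    proportional_distance(ref, subsample(fl, k)), numeric(1))
  expect_true(all(diff(pd) < 0))
})

test_that("point errors vanish on straight tracks and match circle forms", {
  st <- straight_path(601, v = 10, lat0 = 0)   # equator: a true geodesic
  ref <- build_reference(st)
  for (k in c(5, 30)) {
    pe <- point_errors(ref, subsample(st, k))
    expect_lt(max(pe$pe_dist), 1e-6)
    expect_lt(max(pe$pe_speed), 1e-7)
    expect_lt(max(pe$pe_angle, na.rm = TRUE), 1e-4)
  }
  # circle r = 100 m, v = 10 m/s, k = 10 s
  ci <- circle_track(duration = 1000, r = 100, v = 10)
  refc <- build_reference(ci)
  pec <- point_errors(refc, subsample(ci, 10))
  chord_speed <- 10 * sin(0.5) / 0.5
  expect_equal(mean(pec$pe_speed), 10 - chord_speed, tolerance = 1e-3)
  expect_equal(mean(pec$pe_dist), 10 * (10 - chord_speed), tolerance = 1e-2)
  # per-step polygon turn: v k / r minus the 1-s reference turn v dt / r
  expect_equal(mean(pec$pe_angle, na.rm = TRUE),
               (10 * 10 / 100 - 10 * 1 / 100) * 180 / pi, tolerance = 0.05)
})

test_that("distance and speed point errors are k-consistent", {
  tr <- gen_track(sim_config(seed = 31, gap_prob = 0,
                             regimes = list(list(regime = "soar",
                                                 duration = 1200, amp = 60,
                                                 period = 10))))
  ref <- build_reference(tr$path)
  for (k in c(10, 60)) {
    pe <- point_errors(ref, subsample(tr$path, k))
    expect_equal(pe$pe_dist, k * pe$pe_speed, tolerance = 1e-9)
  }
})

test_that("aggregation reproduces a brute-force group-by", {
  run <- run_bias_analysis(list(
    seed = 5, simulate = list(n_straight = 3, n_sinuous = 3,
                              duration = 4000),
    preprocess = list(min_flight_duration_s = 1800),
    bias = list(k_max = 240, k_step = 40)))
  agg <- run$aggregates
  # brute force from the raw per-flight / per-point records
  pd <- run$pd
  pe <- merge(run$pe, unique(pd[, c("flight_id", "flight_class")]),
              by = "flight_id")
  for (g in unique(pd$flight_class)) for (k in unique(pd$k)) {
    i <- agg$pd_curve$flight_class == g & agg$pd_curve$k == k
    expect_equal(agg$pd_curve$pd_mean[i],
                 mean(pd$pd[pd$flight_class == g & pd$k == k]))
    expect_equal(agg$pd_curve$pd_sd[i],
                 sd(pd$pd[pd$flight_class == g & pd$k == k]))
    j <- agg$pe_curve$flight_class == g & agg$pe_curve$k == k
    sel <- pe$flight_class == g & pe$k == k
    expect_equal(agg$pe_curve$pe_angle_mean[j],
                 mean(pe$pe_angle[sel], na.rm = TRUE))
    expect_equal(agg$pe_curve$pe_dist_mean[j], mean(pe$pe_dist[sel]))
  }
  # summary scalars recomputable from the aggregate curves
  for (g in unique(pd$flight_class)) {
    crv <- agg$pd_curve[agg$pd_curve$flight_class == g, ]
    expect_equal(agg$summary$mean_pd_over_60s[agg$summary$flight_class == g],
                 mean(crv$pd_mean[crv$k > 60]))
  }
})

test_that("degenerate aggregation cases behave", {
  fl <- straight_path(2001, v = 10)
  attr(fl, "flight_id") <- "a"
  b1 <- bias_curves(fl, k_grid = c(10, 20))
  b1$pd$flight_class <- "straight"
  one <- aggregate_bias(b1$pd, b1$pe)
  expect_equal(one$pd_curve$pd_mean, b1$pd$pd)
  expect_true(all(is.na(one$pd_curve$pd_sd)))     # single flight: no SD
  fl2 <- fl
  attr(fl2, "flight_id") <- "b"
  b2 <- bias_curves(fl2, k_grid = c(10, 20))
  b2$pd$flight_class <- "straight"
  two <- aggregate_bias(rbind(b1$pd, b2$pd), rbind(b1$pe, b2$pe))
  expect_equal(two$pd_curve$pd_sd, c(0, 0))       # identical flights: SD 0
})

test_that("reported trip distances are corrected by the PD bias", {
  expect_equal(correct_trip_distance(11000, bias = 0.10), 12100)
  expect_equal(correct_trip_distance(11000, pd = 0.62), 15180)
})
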