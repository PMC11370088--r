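test_that("cleaning removes duplicate timestamps and masked points", {
  p <- gps_path(c(0, 1, 1, 2), lon = c(0, 1e-4, 9, 2e-4),
                lat = rep(-46, 4), speed = 10)
  cl <- clean_path(p)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$lon[2], 1e-4)              # first duplicate kept
  expect_equal(attr(cl, "clean_report")$duplicates_removed, 1)
  expect_equal(attr(cl, "clean_report")$on_land_removed, 0)

  # 5 of 100 fixes inside a square mask, by construction
  n <- 100
  lon <- seq(2, 2.99, by = 0.01)             # all outside the square
  lon[c(3, 20, 41, 77, 90)] <- 0.505         # move 5 fixes inside
  p2 <- gps_path(1:n, lon, rep(-46, n), 10)
  square <- cbind(c(0.5, 0.52, 0.52, 0.5, 0.5),
                  c(-47, -47, -45, -45, -47))
  cl2 <- clean_path(p2, land_mask = square)
  expect_equal(nrow(cl2), 95)
  expect_equal(attr(cl2, "clean_report")$on_land_removed, 5)

  expect_error(clean_path(p2, land_mask = cbind(c(-1, 5, 5, -1),
                                                c(-50, -50, -40, -40))),
               "empty after cleaning")
})

test_that("2-s gaps are filled by linear midpoints, longer gaps left", {
  p <- gps_path(c(0, 1, 3), lon = c(0, 0.001, 0.003),
                lat = c(-46, -46.001, -46.003), speed = c(10, 10, 14))
  out <- interpolate_gaps(p)
  expect_equal(out$time, 0:3)
  expect_equal(out$lon[3], 0.002)
  expect_equal(out$lat[3], -46.002)
  expect_equal(out$speed[3], 12)

  p2 <- gps_path(c(0, 300), c(0, 0.01), c(-46, -46), 10)
  out2 <- interpolate_gaps(p2)
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "gap_report")$long_gaps, 0)  # gap starts at t = 0

  # seeded 10% 2-s gaps: interpolation restores span + 1 fixes at 1 Hz
  tr <- gen_track(sim_config(seed = 4, gap_prob = 0.1,
                             regimes = list(list(regime = "straight",
                                                 duration = 2000))))
  filled <- interpolate_gaps(tr$path)
  span <- tr$path$time[nrow(tr$path)] - tr$path$time[1]
  expect_equal(nrow(filled), span + 1)
  expect_true(all(diff(filled$time) == 1))
  # 2-s individuals keep their native interval
  p3 <- gps_path(seq(0, 10, by = 2), lon = seq(0, 0.01, length.out = 6),
                 lat = rep(-46, 6), speed = 10, nominal_interval = 2)
  expect_identical(nrow(interpolate_gaps(p3)), 6L)
})

test_that("flight segmentation follows the slow-run rule", {
  mk <- function(kmh_per_s) straight_path(length(kmh_per_s),
                                          speed = kmh_per_s / 3.6,
                                          v = 15 / 3.6)
  # constant 15 km/h for 2 h: one flight spanning the path
  f1 <- segment_flights(mk(rep(15, 7200)))
  expect_length(f1, 1)
  expect_equal(nrow(f1[[1]]), 7200)
  expect_true(attr(f1[[1]], "gt_min_duration"))
  # 120-s slow stretch splits the path in two
  f2 <- segment_flights(mk(c(rep(15, 3600), rep(5, 120), rep(15, 3600))))
  expect_length(f2, 2)
  # a 30-s dip is too short to count as rest
  f3 <- segment_flights(mk(c(rep(15, 3600), rep(5, 30), rep(15, 3600))))
  expect_length(f3, 1)
  # too-short path: empty result with a warning
  expect_warning(short <- segment_flights(mk(rep(15, 5))), "shorter")
  expect_length(short, 0)
})

test_that("segmentation is idempotent and accounts for the whole span", {
  spd <- c(rep(15, 3000), rep(4, 300), rep(18, 4000)) / 3.6
  p <- straight_path(length(spd), speed = spd, v = 15 / 3.6)
  fl <- segment_flights(p)
  expect_length(fl, 2)
  rep1 <- attr(fl, "segment_report")
  span <- p$time[nrow(p)] - p$time[1]
  expect_equal(rep1$flight_s + rep1$nonflight_s + rep1$gap_s, span)
  expect_equal(rep1$speed_source, "point_speed")
  # re-segmenting a returned flight returns it unchanged
  again <- segment_flights(fl[[1]])
  expect_length(again, 1)
  expect_equal(again[[1]]$time, fl[[1]]$time)
  expect_equal(again[[1]]$lon, fl[[1]]$lon)
})

test_that("straightness index matches closed-form geometries", {
  expect_equal(straightness_index(straight_path(600)), 1, tolerance = 1e-6)
  # out-and-back: displacement ~ 0
  east <- straight_path(300)
  back <- gps_path(c(east$time, max(east$time) + 1:300),
                   c(east$lon, rev(east$lon)), rep(-46, 600), 10)
  expect_lt(straightness_index(back), 0.01)
  # half-circle arc: chord / arc = 2 / pi
  half <- circle_track(duration = 50, r = 500 / pi, v = 10)
  expect_equal(straightness_index(half), 2 / pi, tolerance = 1e-3)
  # SI invariant under rigid rotation (same seed, rotated heading base)
  a <- gen_track(sim_config(seed = 7, heading0 = 0, pos_sd = 0,
                            speed_sd = 0, gap_prob = 0,
                            regimes = list(list(regime = "soar",
                                                duration = 600, amp = 60,
                                                period = 10))))$path
  b <- gen_track(sim_config(seed = 7, heading0 = 137, pos_sd = 0,
                            speed_sd = 0, gap_prob = 0,
                            regimes = list(list(regime = "soar",
                                                duration = 600, amp = 60,
                                                period = 10))))$path
  expect_equal(straightness_index(a), straightness_index(b),
               tolerance = 1e-4)
  expect_error(straightness_index(straight_path(10, v = 0, speed = 0)),
               "zero total distance")
})

test_that("the SI threshold knee separates a bimodal flight ensemble", {
  si <- c(rep(0.2, 50), rep(0.9, 50))
  tc <- select_si_threshold(si)
  expect_gt(tc$threshold, 0.2)
  expect_lt(tc$threshold, 0.9)
  expect_equal(sum(si > tc$threshold), 50)   # classification splits 50/50
  expect_true(all(diff(tc$pct_below) >= 0))  # cumulative curve monotone
  expect_true(tc$threshold %in% tc$grid)
  expect_warning(deg <- select_si_threshold(rep(0.5, 20)), "degenerate")
  expect_equal(deg$threshold, 0.5)
})

test_that("stationary loggers validate point speed as reference distance", {
  # identical error totals in both arms: Welch t is exactly 0
  a <- c(100, 200, 400)
  same <- lapply(seq_along(a), function(i) {
    gps_path(0:1, c(0, a[i] / (R_EARTH * cos(-46 * pi / 180)) * 180 / pi),
             c(-46, -46), speed = a[i], bird_id = paste0("L", i))
  })
  s0 <- stationary_error_summary(same)
  expect_equal(unname(s0$welch_total["t"]), 0, tolerance = 1e-6)
  # noise-free loggers: zero totals are refused by the log transform
  quiet <- gen_stationary(3, duration = 50, pos_sd = 0, speed_sd = 0,
                          gap_prob = 0, seed = 1)
  expect_error(stationary_error_summary(quiet), "S1")
  # jittered loggers: displacement error far exceeds point-speed error,
  # and the Welch statistic matches an independent oracle
  noisy <- gen_stationary(10, duration = 600, pos_sd = 5,
                          speed_sd = 0.0075, gap_prob = 0, seed = 9)
  s <- stationary_error_summary(noisy)
  per <- s$per_logger
  expect_true(all(per$displacement_error_m > 50 * per$point_speed_error_m))
  orc <- welch_oracle(log(per$displacement_error_m),
                      log(per$point_speed_error_m))
  expect_equal(unname(s$welch_total["t"]), orc$t, tolerance = 1e-10)
  expect_equal(unname(s$welch_total["df"]), orc$df, tolerance = 1e-10)
  expect_equal(unname(s$welch_total["p"]), orc$p, tolerance = 1e-10)
  expect_gt(s$welch_total["t"], 0)
})
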