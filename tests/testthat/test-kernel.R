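test_that("href follows the bivariate reference rule and the UD has mass 1", {
  set.seed(1)
  x <- rnorm(1000); y <- rnorm(1000)
  ud <- kernel_ud(x, y)
  expect_equal(ud$h, 0.5 * (sd(x) + sd(y)) * 1000^(-1 / 6))
  expect_equal(ud$h, 0.3162, tolerance = 0.05)   # near the n = 1000 plug-in
  expect_equal(sum(ud$z) * ud$cell_area, 1, tolerance = 1e-3)
  expect_error(kernel_ud(rep(1, 10), rep(2, 10)), "coincident")
  expect_error(kernel_ud(1:3, 1:3), "at least 5")
})

test_that("the 50% contour of an isotropic Gaussian holds half the mass", {
  ud <- analytic_ud(function(a, b) dnorm(a) * dnorm(b))
  co <- ud_contour(ud, 0.5)
  expect_equal(co$mass, 0.5, tolerance = 2e-3)
  # analytic 50% disk of a standard bivariate normal: radius sqrt(2 log 2)
  expect_equal(co$area, pi * 2 * log(2), tolerance = 0.02)
})

test_that("VI overlap has the min-integral properties", {
  ud_a <- analytic_ud(function(a, b) dnorm(a) * dnorm(b))
  expect_equal(overlap_vi(ud_a, ud_a), 1, tolerance = 1e-9)  # self-overlap
  # disjoint supports
  za <- function(a, b) (a < -1) * 1.0
  zb <- function(a, b) (a > 1) * 1.0
  expect_equal(overlap_vi(analytic_ud(za), analytic_ud(zb)), 0)
  # two unit Gaussians separated by 2 sd: VI = 2 * Phi(-1)
  ud_b <- analytic_ud(function(a, b) dnorm(a, 2) * dnorm(b))
  vi <- overlap_vi(ud_a, ud_b)
  expect_equal(vi, 2 * pnorm(-1), tolerance = 5e-3)
  expect_equal(vi, overlap_vi(ud_b, ud_a))                   # symmetry
  other <- analytic_ud(function(a, b) dnorm(a) * dnorm(b), step = 0.05)
  expect_error(overlap_vi(ud_a, other), "same grid")
})

test_that("projection preserves distances from the trip centre", {
  lon <- c(37.6, 37.8, 37.9); lat <- c(-46.7, -46.5, -46.9)
  pr <- project_aeqd(lon, lat, center = c(37.7, -46.7))
  d_gc <- geosphere::distHaversine(cbind(37.7, -46.7), cbind(lon, lat),
                                   r = 6371000)
  expect_equal(sqrt(pr$x^2 + pr$y^2), d_gc, tolerance = 1e-9)
})

test_that("state stability across k behaves on the labelled trip", {
  trip <- gen_trip(seed = 5)
  sc <- state_stability_curve(trip$path, k_grid = c(600, 1200, 1800),
                              seed = 3, n_restarts = 5)
  expect_length(sc$failed_k, 0)
  expect_equal(diag(sc$vi), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sc$vi, t(sc$vi))              # symmetric
  expect_true(all(sc$vi >= 0 & sc$vi <= 1 + 1e-9))
  expect_true(all(abs(rowSums(sc$state_pct) - 100) < 1e-6))
  # per-state speed ordering holds at every converged k
  for (m in sc$models) {
    lab <- suppressWarnings(label_states(m))
    sp <- m$mu[, 1]
    expect_true(sp[lab == "rest"] < sp[lab == "forage"])
    expect_true(sp[lab == "forage"] < sp[lab == "commute"])
  }
  # a single-interval grid degenerates to the self-overlap
  one <- state_stability_curve(trip$path, k_grid = 1200, seed = 3,
                               n_restarts = 3)
  expect_equal(dim(one$vi), c(1, 1))
  expect_equal(one$vi[1, 1], 1, tolerance = 1e-9)
  # shuffling the k grid permutes, but does not change, the matrix
  sh <- state_stability_curve(trip$path, k_grid = c(1800, 600, 1200),
                              seed = 3, n_restarts = 5)
  ord <- match(colnames(sc$vi), colnames(sh$vi))
  expect_equal(sh$vi[ord, ord], sc$vi)
})

test_that("forage kernels recover the true patch geography", {
  trip <- gen_trip(seed = 5)
  sub <- subsample(trip$path, 600)
  obs <- hmm_observations(sub)
  model <- fit_hmm(obs, seed = 3, n_restarts = 5)
  lab <- suppressWarnings(label_states(model))
  pick <- lab[decode_states(model, obs)] == "forage"
  ctr <- c(mean(trip$path$lon), mean(trip$path$lat))
  pr <- project_aeqd(obs$lon[pick], obs$lat[pick], center = ctr)
  ud <- kernel_ud(pr$x, pr$y)
  co <- ud_contour(ud, 0.5)
  pc <- project_aeqd(trip$patch_centers$lon, trip$patch_centers$lat,
                     center = ctr)
  for (i in seq_len(nrow(pc))) {
    ix <- which.min(abs(ud$xg - pc$x[i]))
    iy <- which.min(abs(ud$yg - pc$y[i]))
    expect_true(co$inside[ix, iy])
  }
})

test_that("speed distributions flatten as the interval coarsens", {
  sin_track <- gen_track(sim_config(
    seed = 8, gap_prob = 0,
    regimes = list(list(regime = "soar", duration = 4 * 3600, amp = 60,
                        period = 10))))$path
  v60 <- subsample(sin_track, 60)$speed
  v3600 <- subsample(sin_track, 3600)$speed
  expect_lt(var(v3600), var(v60))
})
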