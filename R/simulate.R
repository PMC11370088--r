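# Synthetic 1-Hz GPS tracks with the statistical structure the analysis
# assumes: flight regimes built from a speed/heading process integrated on
# the sphere in 0.1-s substeps, Gaussian positional jitter, near-unbiased
# Doppler point speeds, and occasional fixes dropped to 2-s gaps. Every
# generator is a pure function of (config, seed) and returns ground truth
# beside the observed path.

#' Simulation configuration
#'
#' @param seed integer RNG seed.
#' @param start `c(lon, lat)` starting position (decimal degrees); the
#'   default sits in the Southern Ocean near a sub-Antarctic colony.
#' @param regimes list of regime specs, each
#'   `list(regime, duration, ...params)` with `regime` one of `"straight"`
#'   (constant heading), `"soar"` (heading oscillating as
#'   `A * sin(2*pi*t/T)` about the entry heading — the dynamic-soaring
#'   signature), `"circle"` (constant turn rate set by `radius` and
#'   `direction`), `"rest"` (slow drift, random-walk heading). Per-regime
#'   `speed` defaults to `base_speed` (`rest` defaults to 0.3 m/s).
#' @param base_speed cruise speed (m/s), default 15.
#' @param heading0 initial heading (degrees), default 90.
#' @param pos_sd isotropic positional jitter SD (m), default 5 (typical
#'   low-cost logger horizontal accuracy).
#' @param speed_sd point-speed error SD (m/s), default 0.0075 (mean absolute
#'   error 0.006 m/s).
#' @param gap_prob probability that an interior fix is dropped, creating a
#'   2-s gap; default 0.02.
#' @param n_sub integration substeps per second, default 10.
#' @param bird_id,species metadata for the generated path.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, start = c(37.6, -46.7),
                       regimes = list(list(regime = "straight",
                                           duration = 3600)),
                       base_speed = 15, heading0 = 90,
                       pos_sd = 5, speed_sd = 0.0075, gap_prob = 0.02,
                       n_sub = 10, bird_id = "sim", species = "simulated") {
  stopifnot(gap_prob >= 0, gap_prob <= 1, n_sub >= 1,
            all(vapply(regimes, function(r) r$duration > 0, logical(1))))
  structure(list(seed = seed, start = start, regimes = regimes,
                 base_speed = base_speed, heading0 = heading0,
                 pos_sd = pos_sd, speed_sd = speed_sd, gap_prob = gap_prob,
                 n_sub = n_sub, bird_id = bird_id, species = species),
            class = "sim_config")
}

# fix times 0..dur where each inter-fix interval is independently 2 s with
# probability p (one fix skipped) and 1 s otherwise: only isolated 2-s gaps,
# so short-gap interpolation restores the uniform 1-s path exactly
gap_sample <- function(dur, p) {
  if (p <= 0) return(0:dur)
  steps <- 1 + stats::rbinom(dur, 1, p)
  tt <- cumsum(steps)
  c(0, tt[tt <= dur])
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic GPS track
#'
#' Integrates the configured speed/heading process on the sphere (0.1-s
#' great-circle substeps, so generator and analyzer share one distance
#' convention), samples true positions at 1 Hz, then overlays isotropic
#' Gaussian positional jitter, point-speed error and random 2-s gaps.
#'
#' @param config a [sim_config()].
#' @return list with `path` (observed `gps_path`), `truth` (data.frame of
#'   true `time`, `lon`, `lat`, instantaneous `speed`, per-second arc
#'   distance `dist` and `regime`) and `config`.
#' @export
gen_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_sub <- config$n_sub
    dt <- 1 / n_sub
    h_cur <- config$heading0
    spd <- list(); hdg <- list(); reg <- list()
    for (rg in config$regimes) {
      nn <- round(rg$duration * n_sub)
      tau <- (seq_len(nn) - 0.5) * dt
      v <- rg$speed %||% if (rg$regime == "rest") 0.3 else config$base_speed
      if (rg$regime == "straight") {
        h0 <- rg$heading %||% h_cur
        h <- rep(h0, nn)
        s <- rep(v, nn)
      } else if (rg$regime == "soar") {
        A <- rg$amp %||% 60
        Tp <- rg$period %||% 10
        h0 <- rg$heading %||% h_cur
        h <- h0 + A * sin(2 * pi * tau / Tp)
        s <- rep(v, nn)
      } else if (rg$regime == "circle") {
        r <- rg$radius %||% 100
        dir <- rg$direction %||% 1
        h <- h_cur + dir * (v / r) * tau * 180 / pi
        s <- rep(v, nn)
      } else if (rg$regime == "rest") {
        h <- h_cur + cumsum(stats::rnorm(nn, 0, 30 * sqrt(dt)))
        s <- v + cumsum(stats::rnorm(nn, 0, 0.05 * sqrt(dt)))
        s <- pmin(pmax(s, 0.02), 1)
      } else stop("gen_track: unknown regime '", rg$regime, "'")
      h_cur <- h[nn]
      spd[[length(spd) + 1]] <- s
      hdg[[length(hdg) + 1]] <- h
      reg[[length(reg) + 1]] <- rep(rg$regime, nn)
    }
    s <- unlist(spd); h <- unlist(hdg); regime <- unlist(reg)
    N <- length(s)
    d <- s * dt
    th <- h * pi / 180
    R <- EARTH_RADIUS_M
    lat0 <- config$start[2]; lon0 <- config$start[1]
    dlat <- d * cos(th) / R * 180 / pi
    lat <- lat0 + cumsum(dlat)
    lat_prev <- c(lat0, lat[-N])
    dlon <- d * sin(th) / (R * cos(lat_prev * pi / 180)) * 180 / pi
    lon <- lon0 + cumsum(dlon)
    dur <- N %/% n_sub
    fix_idx <- (1:dur) * n_sub
    t_fix <- 0:dur
    true_lon <- c(lon0, lon[fix_idx])
    true_lat <- c(lat0, lat[fix_idx])
    true_speed <- c(s[1], s[fix_idx])
    sec_dist <- vapply(seq_len(dur), function(i)
      sum(d[((i - 1) * n_sub + 1):(i * n_sub)]), numeric(1))
    true_regime <- c(regime[1], regime[fix_idx])
    truth <- data.frame(time = t_fix, lon = true_lon, lat = true_lat,
                        speed = true_speed, dist = c(sec_dist, NA),
                        regime = true_regime)
    nf <- length(t_fix)
    jx <- stats::rnorm(nf, 0, config$pos_sd)
    jy <- stats::rnorm(nf, 0, config$pos_sd)
    obs_lat <- true_lat + jy / R * 180 / pi
    obs_lon <- true_lon + jx / (R * cos(true_lat * pi / 180)) * 180 / pi
    obs_speed <- pmax(true_speed + stats::rnorm(nf, 0, config$speed_sd), 0)
    sel <- gap_sample(dur, config$gap_prob)
    path <- gps_path(t_fix[sel + 1], obs_lon[sel + 1], obs_lat[sel + 1],
                     obs_speed[sel + 1], bird_id = config$bird_id,
                     species = config$species, nominal_interval = 1)
    list(path = path, truth = truth, config = config)
  })
}

#' Generate stationary-logger fixtures
#'
#' Loggers at fixed positions observed through the configured noise; any
#' apparent movement downstream is pure error, the ground truth being zero
#' displacement.
#'
#' @param n_loggers number of loggers, default 10 (at least 2).
#' @param duration recording span (s), default 12 h.
#' @param pos_sd,speed_sd,gap_prob noise parameters as in [sim_config()];
#'   stationary point speeds are `|N(0, speed_sd)|`.
#' @param seed RNG seed.
#' @param start `c(lon, lat)` of the logger site.
#' @return list of `gps_path` objects (bird_id `S1`..`Sn`).
#' @export
gen_stationary <- function(n_loggers = 10, duration = 43200, pos_sd = 5,
                           speed_sd = 0.0075, gap_prob = 0.02, seed = 1,
                           start = c(37.6, -46.7)) {
  stopifnot(n_loggers >= 2)
  with_seed(seed, {
    R <- EARTH_RADIUS_M
    lapply(seq_len(n_loggers), function(i) {
      keep <- gap_sample(duration, gap_prob) + 1
      tt <- (0:duration)[keep]
      nf <- length(tt)
      lat <- start[2] + stats::rnorm(nf, 0, pos_sd) / R * 180 / pi
      lon <- start[1] + stats::rnorm(nf, 0, pos_sd) /
        (R * cos(start[2] * pi / 180)) * 180 / pi
      spd <- abs(stats::rnorm(nf, 0, speed_sd))
      gps_path(tt, lon, lat, spd,
               bird_id = sprintf("S%d", i), species = "stationary",
               nominal_interval = 1)
    })
  })
}

#' Generate a labelled foraging-trip fixture
#'
#' A central-place foraging trip at 1 Hz spanning more than a day: a
#' straight commute out, bouts of tortuous soaring flight (paired opposite
#' base headings, so each patch stays geographically compact) alternating
#' with rest, a transit to a second patch, a long night-time rest, more
#' foraging, and a commute back. Ground-truth behavioural states
#' (`commute` / `forage` / `rest`) and the true patch centres are returned
#' for state-recovery and kernel tests.
#'
#' @param seed RNG seed.
#' @param pos_sd,speed_sd noise scales (see [sim_config()]); the trip is
#'   generated without sampling gaps so the reference path is uniform.
#' @return list with `path`, `truth` (including a `state` column),
#'   `patch_centers` (data.frame patch, lon, lat) and `config`.
#' @export
gen_trip <- function(seed = 1, pos_sd = 5, speed_sd = 0.0075) {
  forage_bout <- function(patch, heading) {
    list(list(regime = "soar", duration = 1200, speed = 8, amp = 90,
              period = 15, heading = heading, patch = patch),
         list(regime = "soar", duration = 1200, speed = 8, amp = 90,
              period = 15, heading = heading + 180, patch = patch),
         list(regime = "rest", duration = 900, patch = patch))
  }
  regimes <- c(
    list(list(regime = "straight", duration = 3 * 3600, heading = 90)),
    forage_bout("A", 0), forage_bout("A", 90), forage_bout("A", 45),
    forage_bout("A", 135),
    list(list(regime = "straight", duration = 5400, heading = 0,
              speed = 15)),
    forage_bout("B", 90), forage_bout("B", 0), forage_bout("B", 135),
    forage_bout("B", 45),
    list(list(regime = "rest", duration = 5 * 3600, patch = "B")),
    forage_bout("B", 90), forage_bout("B", 135), forage_bout("B", 45),
    list(list(regime = "straight", duration = 5 * 3600, heading = 235)))
  cfg <- sim_config(seed = seed, regimes = regimes, base_speed = 15,
                    heading0 = 90, pos_sd = pos_sd, speed_sd = speed_sd,
                    gap_prob = 0, bird_id = "trip1",
                    species = "wandering albatross")
  out <- gen_track(cfg)
  # per-fix state and patch labels from the regime schedule
  durs <- vapply(regimes, function(r) r$duration, numeric(1))
  ends <- cumsum(durs)
  idx <- findInterval(out$truth$time, c(0, utils::head(ends, -1) + 0.5))
  state_of <- c(straight = "commute", soar = "forage", circle = "forage",
                rest = "rest")
  out$truth$state <- unname(state_of[vapply(regimes, `[[`, "", "regime")[idx]])
  patch <- vapply(regimes, function(r) r$patch %||% NA_character_,
                  character(1))[idx]
  out$truth$patch <- patch
  forage <- out$truth$state == "forage" & !is.na(patch)
  pc <- stats::aggregate(out$truth[forage, c("lon", "lat")],
                         list(patch = patch[forage]), mean)
  out$patch_centers <- pc
  out
}
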