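# Fixtures built in code: analytic paths with known geometry, plus small
# independent oracles (Welch's formula, a Markov-regime sampler) kept apart
# from the implementation they check.

R_EARTH <- 6371000

# straight eastward path at constant speed along a parallel (analytic, not
# via the simulator): step length is exact on the sphere at these scales
straight_path <- function(n, v = 10, lat0 = -46, t0 = 0, speed = v,
                          bird_id = "straight") {
  tt <- t0 + 0:(n - 1)
  dlon <- v / (R_EARTH * cos(lat0 * pi / 180)) * 180 / pi
  gps_path(tt, seq(0, by = dlon, length.out = n), rep(lat0, n),
           rep_len(speed, n), bird_id = bird_id)
}

# noise-free circle track from the generator (radius m, speed m/s)
circle_track <- function(duration = 1000, r = 100, v = 10, seed = 1) {
  cfg <- sim_config(seed = seed,
                    regimes = list(list(regime = "circle",
                                        duration = duration,
                                        speed = v, radius = r)),
                    pos_sd = 0, speed_sd = 0, gap_prob = 0)
  gen_track(cfg)$path
}

# independent Welch two-sample t oracle (statistic, df, p)
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# 3-regime Markov observation sampler at the stated separability:
# rest 0.5 +/- 0.3 m/s, 5 +/- 5 deg; forage 8 +/- 2, 60 +/- 20;
# commute 15 +/- 2, 8 +/- 5; sticky self-transitions 0.95
sample_three_regimes <- function(n = 2000, seed = 42) {
  set.seed(seed)
  mu <- rbind(c(0.5, 5), c(8, 60), c(15, 8))
  sd <- rbind(c(0.3, 5), c(2, 20), c(2, 5))
  P <- matrix(0.025, 3, 3); diag(P) <- 0.95
  st <- integer(n); st[1] <- 1L
  for (t in 2:n) st[t] <- sample.int(3, 1, prob = P[st[t - 1], ])
  obs <- data.frame(speed = rnorm(n, mu[st, 1], sd[st, 1]),
                    angle = abs(rnorm(n, mu[st, 2], sd[st, 2])))
  list(obs = obs, states = st, mu = mu, sd = sd,
       labels = c("rest", "forage", "commute"))
}

# analytic kernel_ud on a grid from a density function
analytic_ud <- function(f, xlim = c(-6, 6), ylim = c(-6, 6), step = 0.02) {
  xg <- seq(xlim[1], xlim[2], by = step)
  yg <- seq(ylim[1], ylim[2], by = step)
  make_ud(xg, yg, outer(xg, yg, f))
}
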