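# The core computation: reference path from Doppler point speeds, temporal
# sub-sampling at interval k, proportional distance PD_k and per-point
# distance / speed / turning-angle biases, plus the mean +/- SD aggregation.

#' Build the point-speed reference path of a flight
#'
#' The reference path F0 keeps the flight's native fixes but takes each
#' step's distance from the Doppler point speed (speed x interval) rather
#' than from the positions, because point speeds are free of positional
#' measurement error at 1-s sampling. Relative turning angles come from the
#' great-circle step bearings.
#'
#' @param flight a uniform-interval `flight`/`gps_path` with point speed on
#'   every fix.
#' @return object of class `reference_path`: list with `time`, `lon`, `lat`,
#'   `dt`, per-step reference distances `d0` (m), total `D0` (m), per-step
#'   point speeds `speed0`, interior-fix turning angles `theta0` (degrees,
#'   signed) and their times `theta0_time`.
#' @export
build_reference <- function(flight) {
  n <- nrow(flight)
  if (n < 2) stop("build_reference: need at least 2 fixes")
  miss <- which(is.na(flight$speed))
  if (length(miss) > 0)
    stop("build_reference: missing point_speed at fix indices ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  dt <- diff(flight$time)
  nominal <- attr(flight, "nominal_interval")
  if (!is.null(nominal) && any(dt != nominal))
    stop("build_reference: flight is not uniform at the nominal interval; ",
         "run interpolate_gaps/segment_flights first")
  speed0 <- flight$speed[-n]            # speed at each step's starting fix
  d0 <- speed0 * dt
  brg <- gc_step_bearing(flight$lon, flight$lat)
  theta0 <- rel_turn_angle(brg)         # turn at interior fixes 2..n-1
  structure(list(time = flight$time, lon = flight$lon, lat = flight$lat,
                 dt = dt[1], d0 = d0, D0 = sum(d0), speed0 = speed0,
                 theta0 = theta0, theta0_time = flight$time[2:(n - 1)],
                 flight_id = attr(flight, "flight_id"),
                 flight_class = attr(flight, "flight_class"),
                 species = attr(flight, "species"),
                 bird_id = attr(flight, "bird_id")),
            class = "reference_path")
}

#' @export
print.reference_path <- function(x, ...) {
  cat(sprintf("<reference_path> %s: %d fixes @ %g s, D0 = %.0f m\n",
              x$flight_id %||% "?", length(x$time), x$dt, x$D0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sub-sample a flight at interval k
#'
#' Positions are taken at exact multiples of k from the flight start,
#' linearly interpolated in lon/lat between the bracketing native fixes
#' (interpolation hits the recorded fix exactly whenever the time is a
#' node). Step distances are great-circle, step speed is distance / k, and
#' relative turning angles come from successive step bearings.
#'
#' @param flight a uniform `flight`/`gps_path`.
#' @param k sampling interval in seconds (at least the nominal interval).
#' @param snap if TRUE, positions snap to the nearest recorded fix instead
#'   of being interpolated.
#' @return object of class `subsampled_flight`: list with `k`, `time`,
#'   `lon`, `lat`, per-step `dist` (m) and `speed` (m/s), and `theta`
#'   (signed turning angle, degrees, at interior sub-sampled fixes).
#' @export
subsample <- function(flight, k, snap = FALSE) {
  nominal <- attr(flight, "nominal_interval") %||% 1
  if (k < nominal) stop("subsample: k below the nominal interval")
  n <- nrow(flight)
  dur <- flight$time[n] - flight$time[1]
  if (dur < 2 * k)
    stop("subsample: flight too short for k = ", k, " (need duration >= 2k)")
  tt <- flight$time[1] + k * 0:(floor(dur / k))
  idx <- findInterval(tt, flight$time)
  idx <- pmin(idx, n - 1L)
  frac <- (tt - flight$time[idx]) / (flight$time[idx + 1] - flight$time[idx])
  at_node <- frac <= 0
  if (snap) frac <- round(frac)
  lon <- flight$lon[idx] + frac * (flight$lon[idx + 1] - flight$lon[idx])
  lat <- flight$lat[idx] + frac * (flight$lat[idx + 1] - flight$lat[idx])
  lon[at_node] <- flight$lon[idx][at_node]
  lat[at_node] <- flight$lat[idx][at_node]
  at_end <- frac >= 1                       # final fix is its own node
  lon[at_end] <- flight$lon[idx + 1][at_end]
  lat[at_end] <- flight$lat[idx + 1][at_end]
  dist <- gc_step_dist(lon, lat)
  brg <- gc_step_bearing(lon, lat)
  structure(list(k = k, time = tt, lon = lon, lat = lat,
                 dist = dist, speed = dist / k,
                 theta = rel_turn_angle(brg),
                 flight_id = attr(flight, "flight_id")),
            class = "subsampled_flight")
}

#' @export
print.subsampled_flight <- function(x, ...) {
  cat(sprintf("<subsampled_flight> %s @ k = %d s: %d fixes, %d steps\n",
              x$flight_id %||% "?", x$k, length(x$time), length(x$dist)))
  invisible(x)
}

#' Proportional distance PD_k
#'
#' Total sub-sampled path length divided by the reference path length D0.
#' Values above 1 mean the sampling interval overestimates distance
#' (positional measurement error dominating), values below 1 mean
#' underestimation (straight-line interpolation across real sinuosity).
#' When k does not divide the flight duration, the sub-sampled path ends
#' before the last fix; D0 is then restricted to the span the sub-sampled
#' path covers, so both totals describe the same stretch of flight (and a
#' noise-free geodesic track gives PD = 1 exactly at every k).
#'
#' @param ref a `reference_path`.
#' @param sub a `subsampled_flight` derived from the same flight.
#' @return PD_k, a positive scalar.
#' @export
proportional_distance <- function(ref, sub) {
  t_last <- sub$time[length(sub$time)]
  covered <- ref$time[-length(ref$time)] < t_last
  d0 <- sum(ref$d0[covered])
  if (d0 <= 0) stop("proportional_distance: D0 = 0, PD undefined")
  sum(sub$dist) / d0
}

#' Per-point biases of a sub-sampled flight
#'
#' For every sub-sampled step j (fixes j to j+1): `pe_dist` is the absolute
#' difference between the reference distance accumulated inside the step and
#' the straight-line step distance; `pe_speed` the absolute difference
#' between the mean reference point speed inside the step and the step speed
#' (distance / k); `pe_angle` the absolute difference between the mean
#' absolute reference turning angle strictly inside the step and the
#' absolute sub-sampled turning angle at the step's end fix. Signed
#' (reference minus sub-sampled) versions are kept alongside.
#'
#' @inheritParams proportional_distance
#' @return data.frame with one row per sub-sampled step: `k`, `j`, `time`,
#'   `pe_dist` (m), `pe_speed` (m/s), `pe_angle` (degrees, NA on the final
#'   step where no turn is defined), and signed `err_*` columns.
#' @export
point_errors <- function(ref, sub) {
  m <- length(sub$time)
  nstep <- m - 1
  step_start_t <- ref$time[-length(ref$time)]
  # reference step -> sub-sampled step whose [t_j, t_{j+1}) contains its start
  win <- findInterval(step_start_t, sub$time)
  ok <- win >= 1 & win <= nstep
  d0_sum <- rep(0, nstep)
  sp_sum <- rep(0, nstep)
  sp_n <- rep(0L, nstep)
  tw <- tapply(ref$d0[ok], win[ok], sum)
  d0_sum[as.integer(names(tw))] <- tw
  tw <- tapply(ref$speed0[ok], win[ok], sum)
  sp_sum[as.integer(names(tw))] <- tw
  tn <- tapply(rep(1L, sum(ok)), win[ok], sum)
  sp_n[as.integer(names(tn))] <- tn
  if (any(sp_n == 0))
    stop("point_errors: empty reference window (k below nominal interval?)")
  err_dist <- d0_sum - sub$dist
  err_speed <- sp_sum / sp_n - sub$speed
  # angle windows are half-open (t_j, t_{j+1}]: at k = nominal each window
  # holds exactly the reference turn at the shared fix, so PE_angle = 0
  awin <- findInterval(ref$theta0_time, sub$time, left.open = TRUE)
  inside <- awin >= 1 & awin <= nstep
  a_mean <- rep(NA_real_, nstep)
  ta <- tapply(abs(ref$theta0[inside]), awin[inside], mean)
  a_mean[as.integer(names(ta))] <- ta
  sub_turn <- c(abs(sub$theta), NA_real_)  # turn at end fix of steps 1..m-2
  err_angle <- a_mean - sub_turn
  data.frame(flight_id = ref$flight_id %||% NA_character_,
             k = sub$k, j = seq_len(nstep), time = sub$time[-m],
             pe_dist = abs(err_dist), pe_speed = abs(err_speed),
             pe_angle = abs(err_angle),
             err_dist = err_dist, err_speed = err_speed,
             err_angle = err_angle)
}

#' PD and point-error curves of one flight across a k grid
#'
#' @param flight a uniform `flight` with point speed.
#' @param k_grid integer vector of sampling intervals (s); defaults to every
#'   multiple of the nominal interval up to 3600 s that the flight supports.
#' @param snap passed to [subsample()].
#' @return list with `pd` (data.frame flight_id, k, pd) and `pe` (long
#'   per-step data.frame from [point_errors()]).
#' @export
bias_curves <- function(flight, k_grid = NULL, snap = FALSE) {
  ref <- build_reference(flight)
  nominal <- attr(flight, "nominal_interval") %||% 1
  dur <- flight$time[nrow(flight)] - flight$time[1]
  if (is.null(k_grid))
    k_grid <- seq(nominal, min(3600, floor(dur / 2)), by = nominal)
  k_grid <- k_grid[k_grid >= nominal & k_grid <= dur / 2]
  pe_list <- vector("list", length(k_grid))
  pd <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    sub <- subsample(flight, k_grid[i], snap = snap)
    pd[i] <- proportional_distance(ref, sub)
    pe_list[[i]] <- point_errors(ref, sub)
  }
  list(pd = data.frame(flight_id = ref$flight_id %||% NA_character_,
                       flight_class = ref$flight_class %||% NA_character_,
                       species = ref$species %||% NA_character_,
                       k = k_grid, pd = pd),
       pe = do.call(rbind, pe_list))
}

#' Aggregate bias records into mean +/- SD curves
#'
#' PD is aggregated at the flight level and the PE metrics at the point
#' level, per sampling interval k and group (flight class, species or
#' individual). Summary scalars mirror the headline quantities: mean PD over
#' k > 60 s per group and the k at which the mean angle error peaks.
#'
#' @param pd data.frame with columns `flight_id`, `k`, `pd` and the grouping
#'   column.
#' @param pe long per-point data.frame from [point_errors()]/[bias_curves()],
#'   joined with the grouping column (or carrying it already).
#' @param group name of the grouping column (default `"flight_class"`).
#' @return object of class `bias_table`: list with `pd_curve`, `pe_curve`
#'   (mean/sd per group x k) and `summary` (per group: mean PD for k > 60 s,
#'   k of the maximum mean angle error, flight count).
#' @export
aggregate_bias <- function(pd, pe, group = "flight_class") {
  if (!group %in% names(pd)) stop("aggregate_bias: pd lacks column ", group)
  if (!group %in% names(pe)) {
    key <- unique(pd[, c("flight_id", group)])
    pe <- merge(pe, key, by = "flight_id", sort = FALSE)
  }
  agg2 <- function(df, value, keys) {
    f <- stats::aggregate(df[[value]], df[keys],
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v[!is.na(v)])))
    out <- cbind(f[keys], f$x)
    names(out) <- c(keys, paste0(value, c("_mean", "_sd")))
    out
  }
  pd_curve <- agg2(pd, "pd", c(group, "k"))
  pe_curve <- Reduce(function(a, b) merge(a, b, by = c(group, "k")),
                     lapply(c("pe_dist", "pe_speed", "pe_angle"),
                            function(v) agg2(pe, v, c(group, "k"))))
  pd_curve <- pd_curve[order(pd_curve[[group]], pd_curve$k), ]
  pe_curve <- pe_curve[order(pe_curve[[group]], pe_curve$k), ]
  groups <- unique(pd_curve[[group]])
  summary <- do.call(rbind, lapply(groups, function(g) {
    pdg <- pd_curve[pd_curve[[group]] == g, ]
    peg <- pe_curve[pe_curve[[group]] == g, ]
    over60 <- pdg$k > 60
    peak <- if (all(is.na(peg$pe_angle_mean))) NA_real_ else
      peg$k[which.max(peg$pe_angle_mean)]
    data.frame(group = g,
               n_flights = length(unique(pd$flight_id[pd[[group]] == g])),
               mean_pd_over_60s = if (any(over60))
                 mean(pdg$pd_mean[over60]) else NA_real_,
               k_max_pe_angle = peak)
  }))
  names(summary)[1] <- group
  structure(list(pd_curve = pd_curve, pe_curve = pe_curve,
                 summary = summary, group = group),
            class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("<bias_table> grouped by %s\n", x$group))
  print(x$summary)
  invisible(x)
}

#' Correct a reported trip distance for sampling-interval bias
#'
#' Inverts the long-interval underestimation: a trip distance reported from
#' coarsely sampled fixes is scaled up by the bias `1 - PD` measured (or
#' assumed) for the relevant flight style. For example, an 11,000 km trip
#' logged hourly corresponds to roughly 12,100 km of actual flight under the
#' 10% straight-flight bias, or 15,400 km under the 40% sinuous-flight bias.
#'
#' @param reported reported (sub-sampled) distance, any unit.
#' @param pd proportional distance PD at the relevant sampling interval
#'   (e.g. 0.90 for straight flight sampled hourly); alternatively supply
#'   `bias` directly.
#' @param bias fractional underestimate `1 - PD` (e.g. 0.10).
#' @return corrected distance, same unit as `reported`.
#' @export
correct_trip_distance <- function(reported, pd = NULL, bias = NULL) {
  if (is.null(bias)) {
    if (is.null(pd)) stop("correct_trip_distance: give pd or bias")
    bias <- 1 - pd
  }
  reported * (1 + bias)
}
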