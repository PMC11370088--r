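# Path cleaning, short-gap interpolation, flight segmentation, straightness
# classification and the stationary-logger validation of Doppler point speed
# as a reference distance.

#' Clean a raw GPS path
#'
#' Removes fixes with duplicate timestamps (first occurrence kept) and,
#' when a land mask is supplied, fixes falling inside any mask polygon.
#'
#' @param path a `gps_path`.
#' @param land_mask optional list of polygons, each a two-column matrix or
#'   data.frame of (lon, lat) vertices.
#' @return cleaned `gps_path` with attribute `clean_report` =
#'   `list(duplicates_removed, on_land_removed)`.
#' @export
clean_path <- function(path, land_mask = NULL) {
  stopifnot(inherits(path, "gps_path"))
  dup <- duplicated(path$time)
  n_dup <- sum(dup)
  out <- path[!dup, , drop = FALSE]
  n_land <- 0L
  if (!is.null(land_mask)) {
    if (!is.list(land_mask) || is.data.frame(land_mask))
      land_mask <- list(land_mask)
    on_land <- rep(FALSE, nrow(out))
    for (poly in land_mask) {
      poly <- as.matrix(poly)
      on_land <- on_land |
        point_in_polygon(out$lon, out$lat, poly[, 1], poly[, 2])
    }
    n_land <- sum(on_land)
    out <- out[!on_land, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("clean_path: empty after cleaning")
  out <- keep_path_attrs(out, path)
  attr(out, "clean_report") <- list(duplicates_removed = n_dup,
                                    on_land_removed = n_land)
  out
}

#' Fill short sampling gaps by linear interpolation
#'
#' Loggers set to 1 Hz intermittently record at 2-s intervals; those single
#' missing seconds are filled by linear interpolation of lat, lon and point
#' speed so the reference path is uniform at 1 s. Longer gaps are left
#' untouched and later act as flight breaks. Paths with a 2-s nominal
#' interval are returned unchanged (their native interval is kept).
#'
#' @param path a `gps_path` (cleaned: strictly increasing timestamps).
#' @param max_gap largest gap (s) that is interpolated; default 2.
#' @return a `gps_path`, uniform at the nominal interval within unbroken
#'   runs; attribute `gap_report` = `list(interpolated, long_gaps)` where
#'   `long_gaps` holds the start times of gaps wider than `max_gap`.
#' @export
interpolate_gaps <- function(path, max_gap = 2) {
  stopifnot(inherits(path, "gps_path"))
  if (attr(path, "nominal_interval") != 1) {
    attr(path, "gap_report") <- list(interpolated = 0L, long_gaps = numeric(0))
    return(path)
  }
  dt <- diff(path$time)
  if (any(dt <= 0)) stop("interpolate_gaps: timestamps not strictly increasing")
  fill <- which(dt > 1 & dt <= max_gap)
  long <- path$time[which(dt > max_gap)]
  if (length(fill) == 0) {
    attr(path, "gap_report") <- list(interpolated = 0L, long_gaps = long)
    return(path)
  }
  new_rows <- lapply(fill, function(i) {
    t0 <- path$time[i]; t1 <- path$time[i + 1]
    tt <- seq(t0 + 1, t1 - 1)
    w <- (tt - t0) / (t1 - t0)
    data.frame(time = tt,
               lon = path$lon[i] + w * (path$lon[i + 1] - path$lon[i]),
               lat = path$lat[i] + w * (path$lat[i + 1] - path$lat[i]),
               speed = path$speed[i] + w * (path$speed[i + 1] - path$speed[i]))
  })
  base <- as.data.frame(path)[, c("time", "lon", "lat", "speed")]
  out <- rbind(base, do.call(rbind, new_rows))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_path_attrs(out, path)
  attr(out, "gap_report") <- list(
    interpolated = sum(vapply(new_rows, nrow, 1L)), long_gaps = long)
  out
}

# centered rolling mean, partial windows at the edges
roll_mean_centered <- function(x, w) {
  n <- length(x)
  left <- floor((w - 1) / 2)
  right <- w - 1 - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Segment a path into individual flights
#'
#' Non-flying periods are runs where the 10-s rolling mean speed stays below
#' the threshold for at least `min_rest` seconds; they are removed, and the
#' resulting breaks (together with data gaps wider than the nominal
#' interval) delimit flights. A straightness index is attached to every
#' flight; flights longer than `min_flight_duration` are flagged for the
#' sub-sampling analysis, but all flights are returned.
#'
#' @param path cleaned, gap-interpolated `gps_path`.
#' @param speed_window rolling-mean window (s), default 10; the window is
#'   centered (configurable convention documented in the vignette).
#' @param speed_threshold_kmh threshold in km/h, default 10.
#' @param min_rest minimum slow-run duration (s) counted as non-flying,
#'   default 60.
#' @param min_flight_duration flights at most this long (s) are flagged
#'   `gt_min_duration = FALSE`; default 3600.
#' @return list of `flight` objects (a `gps_path` subclass with attributes
#'   `flight_id`, `si`, `flight_class`, `gt_min_duration`), with attribute
#'   `segment_report` accounting the path span into flight / non-flying /
#'   gap seconds and naming the speed source used.
#' @export
segment_flights <- function(path, speed_window = 10,
                            speed_threshold_kmh = 10, min_rest = 60,
                            min_flight_duration = 3600) {
  stopifnot(inherits(path, "gps_path"))
  nominal <- attr(path, "nominal_interval")
  n <- nrow(path)
  if ((path$time[n] - path$time[1]) < speed_window) {
    warning("segment_flights: path shorter than the speed window")
    return(structure(list(), segment_report = list(
      flight_s = 0, nonflight_s = 0, gap_s = 0, speed_source = "none")))
  }
  # observation speed: Doppler point speed where present, positional fallback
  spd <- path$speed
  pos_spd <- c(NA, gc_step_dist(path$lon, path$lat) / diff(path$time))
  if (length(pos_spd) >= 2) pos_spd[1] <- pos_spd[2]
  use_pos <- is.na(spd)
  spd[use_pos] <- pos_spd[use_pos]
  speed_source <- if (!any(use_pos)) "point_speed" else
    if (all(use_pos)) "positional" else "mixed"
  w <- max(1L, round(speed_window / nominal))
  roll <- roll_mean_centered(spd, w)
  thr <- speed_threshold_kmh / 3.6
  slow <- roll < thr
  slow[is.na(slow)] <- FALSE
  # non-flying = slow runs spanning >= min_rest seconds
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nonfly <- rep(FALSE, n)
  for (j in seq_along(r$lengths)) {
    if (r$values[j] &&
        (path$time[ends[j]] - path$time[starts[j]]) >= min_rest)
      nonfly[starts[j]:ends[j]] <- TRUE
  }
  dt <- diff(path$time)
  gap_iv <- dt > nominal
  # partition inter-fix seconds: gap / non-flying / flight
  same_fly <- !gap_iv & !nonfly[-n] & !nonfly[-1]
  gap_s <- sum(dt[gap_iv])
  flight_s <- sum(dt[same_fly])
  nonflight_s <- sum(dt) - gap_s - flight_s
  # flights: maximal runs of flying fixes with no internal gap
  seg_id <- cumsum(c(TRUE, !same_fly))  # increments at every break
  keep <- !nonfly
  flights <- list()
  fid <- 0L
  for (sid in unique(seg_id[keep])) {
    idx <- which(seg_id == sid & keep)
    if (length(idx) < 2) next
    fid <- fid + 1L
    fl <- keep_path_attrs(path[idx, , drop = FALSE], path)
    dur <- fl$time[nrow(fl)] - fl$time[1]
    si <- tryCatch(straightness_index(fl), error = function(e) NA_real_)
    flights[[fid]] <- structure(
      fl, class = c("flight", class(fl)),
      flight_id = sprintf("%s_f%03d", attr(path, "bird_id"), fid),
      si = si, flight_class = NA_character_,
      gt_min_duration = dur > min_flight_duration)
  }
  structure(flights, segment_report = list(
    flight_s = flight_s, nonflight_s = nonflight_s, gap_s = gap_s,
    speed_source = speed_source))
}

#' Straightness index of a flight
#'
#' Great-circle distance between the first and last fixes divided by the
#' total along-path distance; 1 is perfectly straight, values near 0 mark
#' highly sinuous flight.
#'
#' @param flight a `flight` or `gps_path` with at least 2 fixes.
#' @return SI in \[0, 1\].
#' @export
straightness_index <- function(flight) {
  n <- nrow(flight)
  if (is.null(n) || n < 2) stop("straightness_index: need at least 2 fixes")
  steps <- gc_step_dist(flight$lon, flight$lat)
  total <- sum(steps)
  if (total <= 0) stop("straightness_index: zero total distance, SI undefined")
  disp <- geosphere::distHaversine(c(flight$lon[1], flight$lat[1]),
                                   c(flight$lon[n], flight$lat[n]),
                                   r = EARTH_RADIUS_M)
  min(disp / total, 1)
}

#' Choose the straight/sinuous SI threshold from the flight ensemble
#'
#' Builds the cumulative curve "percent of flights with SI below t" on a
#' regular threshold grid and places the knee where the curve's gradient
#' changes most: the grid point maximizing the discrete second difference of
#' the 5-point-smoothed curve (ties broken toward the higher threshold, the
#' foot of the dominant rise).
#'
#' @param flights list of `flight` objects, or a numeric vector of SI values.
#' @param grid_step threshold grid spacing, default 0.01.
#' @return object of class `threshold_curve`: list with `grid`, `pct_below`,
#'   `threshold`, `degenerate`.
#' @export
select_si_threshold <- function(flights, grid_step = 0.01) {
  si <- if (is.numeric(flights)) flights else
    vapply(flights, function(f) attr(f, "si"), numeric(1))
  si <- si[!is.na(si)]
  if (length(si) < 2) stop("select_si_threshold: need at least 2 flights")
  grid <- seq(0, 1, by = grid_step)
  pct <- vapply(grid, function(t) 100 * mean(si < t), numeric(1))
  if (length(unique(si)) == 1) {
    warning("select_si_threshold: all SI equal; degenerate knee")
    return(structure(list(grid = grid, pct_below = pct,
                          threshold = unique(si), degenerate = TRUE),
                     class = "threshold_curve"))
  }
  sm <- roll_mean_centered(pct, 5)
  d2 <- c(NA, diff(sm, differences = 2), NA)
  best <- which(d2 == max(d2, na.rm = TRUE))
  thr <- grid[best[length(best)]]
  structure(list(grid = grid, pct_below = pct, threshold = thr,
                 degenerate = FALSE),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> SI threshold %.2f%s\n", x$threshold,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Classify flights as straight or sinuous
#'
#' @param flights list of `flight` objects.
#' @param threshold SI threshold (a number or a `threshold_curve`); flights
#'   with SI above it are labelled `"straight"`, others `"sinuous"`.
#' @return the flights with `flight_class` attributes set.
#' @export
classify_flights <- function(flights, threshold) {
  if (inherits(threshold, "threshold_curve")) threshold <- threshold$threshold
  out <- lapply(flights, function(f) {
    attr(f, "flight_class") <-
      if (isTRUE(attr(f, "si") > threshold)) "straight" else "sinuous"
    f
  })
  attr(out, "segment_report") <- attr(flights, "segment_report")
  out
}

#' Stationary-logger error summary
#'
#' Validates Doppler point speed as a reference distance: for loggers left
#' at a fixed position, any apparent movement is error. Per logger the
#' cumulative displacement error (sum of great-circle distances between
#' successive fixes) is compared against the cumulative point-speed error
#' (sum of point speed x interval) with a Welch two-sample t-test on the
#' log-transformed totals.
#'
#' @param paths list of `gps_path` objects from stationary loggers.
#' @return object of class `stationary_error_summary`: per-logger table and
#'   Welch tests on log totals and on log per-second means.
#' @export
stationary_error_summary <- function(paths) {
  if (length(paths) < 2)
    stop("stationary_error_summary: need at least 2 loggers")
  per <- do.call(rbind, lapply(paths, function(p) {
    dt <- diff(p$time)
    span <- sum(dt)
    disp <- sum(gc_step_dist(p$lon, p$lat))
    spd <- sum(p$speed[-nrow(p)] * dt)
    data.frame(bird_id = attr(p, "bird_id"),
               displacement_error_m = disp,
               point_speed_error_m = spd,
               displacement_error_mps = disp / span,
               point_speed_error_mps = spd / span)
  }))
  zero <- per$displacement_error_m <= 0 | per$point_speed_error_m <= 0
  if (any(zero))
    stop("stationary_error_summary: zero error total for logger(s) ",
         paste(per$bird_id[zero], collapse = ", "),
         "; log-transform undefined")
  tt_tot <- stats::t.test(log(per$displacement_error_m),
                          log(per$point_speed_error_m))
  tt_sec <- stats::t.test(log(per$displacement_error_mps),
                          log(per$point_speed_error_mps))
  structure(list(per_logger = per,
                 welch_total = c(t = unname(tt_tot$statistic),
                                 df = unname(tt_tot$parameter),
                                 p = tt_tot$p.value),
                 welch_per_second = c(t = unname(tt_sec$statistic),
                                      df = unname(tt_sec$parameter),
                                      p = tt_sec$p.value)),
            class = "stationary_error_summary")
}

#' @export
print.stationary_error_summary <- function(x, ...) {
  p <- x$per_logger
  cat(sprintf(
    "<stationary_error_summary> %d loggers\n  displacement error %.0f +/- %.0f m; point-speed error %.0f +/- %.0f m\n  Welch t = %.3f (df %.1f), p = %.4f on log totals\n",
    nrow(p), mean(p$displacement_error_m), stats::sd(p$displacement_error_m),
    mean(p$point_speed_error_m), stats::sd(p$point_speed_error_m),
    x$welch_total["t"], x$welch_total["df"], x$welch_total["p"]))
  invisible(x)
}
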