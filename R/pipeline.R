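# End-to-end orchestration: clean -> interpolate -> segment -> classify ->
# bias curves, and trip -> per-k HMM -> kernel overlap, from a single
# validated configuration with derived per-stage seeds.

default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    simulate = list(preset = "cohort", n_straight = 10, n_sinuous = 10,
                    duration = 7200),
    input = NULL,                     # list of files + column_map instead
    preprocess = list(speed_window_s = 10, speed_threshold_kmh = 10,
                      min_rest_s = 60, min_flight_duration_s = 3600,
                      si_grid_step = 0.01, max_gap_s = 2,
                      land_mask_file = NULL),
    bias = list(k_max = 3600, k_step = 1, group = "flight_class"),
    states = list(k_grid = seq(600, 3600, by = 600), state = "forage",
                  grid_cells = 200, n_restarts = 10)
  )
}

#' Read and validate a run configuration
#'
#' @param config a YAML file path, a list, or NULL for defaults; entries are
#'   merged over the defaults and validated.
#' @return validated config list.
#' @export
read_run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("read_run_config: config must be a list or file")
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            cfg$bias$k_max >= 1, cfg$bias$k_step >= 1,
            cfg$preprocess$speed_window_s > 0,
            cfg$preprocess$min_rest_s > 0)
  cfg
}

# stable per-stage seed stream: adding a stage never perturbs the others
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483587 * 7919 +
                sum(utf8ToInt(stage)) * 104729) %% 2147483587)
}

# straight or sinuous soaring track configs for the synthetic cohort
cohort_paths <- function(sim, seed) {
  n_s <- sim$n_straight %||% 10
  n_w <- sim$n_sinuous %||% 10
  dur <- sim$duration %||% 7200
  noise <- list(pos_sd = sim$pos_sd %||% 5,
                speed_sd = sim$speed_sd %||% 0.0075,
                gap_prob = sim$gap_prob %||% 0.02)
  paths <- list()
  for (i in seq_len(n_s)) {
    cfg <- sim_config(seed = derive_seed(seed, paste0("straight", i)),
                      regimes = list(list(regime = "straight",
                                          duration = dur)),
                      heading0 = (i * 37) %% 360,
                      pos_sd = noise$pos_sd, speed_sd = noise$speed_sd,
                      gap_prob = noise$gap_prob,
                      bird_id = sprintf("str%02d", i), species = "straight")
    paths[[length(paths) + 1]] <- gen_track(cfg)$path
  }
  for (i in seq_len(n_w)) {
    cfg <- sim_config(seed = derive_seed(seed, paste0("sinuous", i)),
                      regimes = list(list(regime = "soar", duration = dur,
                                          speed = 15, amp = 60,
                                          period = 10)),
                      heading0 = (i * 53) %% 360,
                      pos_sd = noise$pos_sd, speed_sd = noise$speed_sd,
                      gap_prob = noise$gap_prob,
                      bird_id = sprintf("sin%02d", i), species = "sinuous")
    paths[[length(paths) + 1]] <- gen_track(cfg)$path
  }
  paths
}

load_input_paths <- function(input) {
  lapply(input$files, function(f) {
    read_fix_table(f$file, column_map = input$column_map,
                   tz = input$tz %||% "UTC",
                   speed_unit = input$speed_unit %||% "m/s",
                   delim = input$delim %||% ",",
                   bird_id = f$bird_id %||% basename(f$file),
                   species = f$species %||% "unknown",
                   nominal_interval = f$nominal_interval %||% 1)
  })
}

#' Run the sampling-interval bias analysis end to end
#'
#' Simulates (or reads) logger paths, cleans and gap-interpolates them,
#' segments flights, selects the SI threshold and classifies flights, then
#' computes PD and point-error curves over the k grid and aggregates them
#' by group. Only flights longer than `min_flight_duration_s` enter the
#' bias computation, but the report counts all segmented flights.
#'
#' @param config see [read_run_config()].
#' @return object of class `bias_run`: list with `flights`, `threshold`,
#'   `pd`, `pe` (long tables), `aggregates` (a `bias_table`), `report` and
#'   `warnings`; products are written when `out_dir` is set.
#' @export
run_bias_analysis <- function(config = NULL) {
  cfg <- read_run_config(config)
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)
  paths <- if (!is.null(cfg$input)) load_input_paths(cfg$input) else
    cohort_paths(cfg$simulate, derive_seed(cfg$seed, "simulate"))
  pp <- cfg$preprocess
  land_mask <- if (!is.null(pp$land_mask_file)) {
    gj <- jsonlite::read_json(pp$land_mask_file)
    lapply(gj$features, function(ft)
      do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist)))
  } else NULL
  flights <- list()
  for (p in paths) {
    p <- clean_path(p, land_mask = land_mask)
    p <- interpolate_gaps(p, max_gap = pp$max_gap_s)
    fl <- withCallingHandlers(
      segment_flights(p, speed_window = pp$speed_window_s,
                      speed_threshold_kmh = pp$speed_threshold_kmh,
                      min_rest = pp$min_rest_s,
                      min_flight_duration = pp$min_flight_duration_s),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    flights <- c(flights, fl)
  }
  if (length(flights) == 0) stop("run_bias_analysis: no flights segmented")
  thr <- withCallingHandlers(
    select_si_threshold(flights, grid_step = pp$si_grid_step),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
  flights <- classify_flights(flights, thr)
  long <- Filter(function(f) isTRUE(attr(f, "gt_min_duration")), flights)
  if (length(long) == 0) {
    note("no flights above min_flight_duration; aggregates empty")
    return(structure(list(flights = flights, threshold = thr, pd = NULL,
                          pe = NULL, aggregates = NULL,
                          report = list(n_flights = length(flights),
                                        n_long = 0),
                          warnings = warnings),
                     class = "bias_run"))
  }
  k_grid <- seq(cfg$bias$k_step, cfg$bias$k_max, by = cfg$bias$k_step)
  curves <- lapply(long, bias_curves, k_grid = k_grid)
  pd <- do.call(rbind, lapply(curves, `[[`, "pd"))
  pe <- do.call(rbind, lapply(curves, `[[`, "pe"))
  agg <- aggregate_bias(pd, pe, group = cfg$bias$group)
  pdm <- agg$pd_curve
  cross <- vapply(split(pdm, pdm[[cfg$bias$group]]), function(g) {
    below <- g$k[g$pd_mean < 1]
    if (length(below)) min(below) else NA_real_
  }, numeric(1))
  report <- list(
    n_flights = length(flights),
    n_long = length(long),
    n_by_class = table(vapply(flights, attr, "", "flight_class")),
    si_threshold = thr$threshold,
    mean_pd_over_60s = stats::setNames(agg$summary$mean_pd_over_60s,
                                       agg$summary[[cfg$bias$group]]),
    k_pd_crosses_1 = cross,
    k_max_pe_angle = stats::setNames(agg$summary$k_max_pe_angle,
                                     agg$summary[[cfg$bias$group]]))
  out <- structure(list(flights = flights, threshold = thr, pd = pd,
                        pe = pe, aggregates = agg, report = report,
                        warnings = warnings),
                   class = "bias_run")
  if (!is.null(cfg$out_dir)) {
    write_products(cfg$out_dir, flights = flights,
                   tables = list(pd = pd, pe = pe,
                                 pd_aggregate = agg$pd_curve,
                                 pe_aggregate = agg$pe_curve,
                                 summary = agg$summary))
  }
  out
}

#' @export
print.bias_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<bias_run> %d flights (%d above duration cutoff), SI threshold %.2f\n",
              r$n_flights, r$n_long, r$si_threshold %||% NA))
  if (!is.null(x$aggregates)) print(x$aggregates$summary)
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Run the behavioural-state stability analysis end to end
#'
#' Simulates (or reads) a trip-scale path and runs the per-k HMM / kernel
#' overlap analysis of [state_stability_curve()].
#'
#' @param config see [read_run_config()]; `states$k_grid` sets the
#'   intervals.
#' @param trip optional `gps_path` overriding the simulated trip.
#' @return object of class `state_run`: the `overlap_curve` plus a report;
#'   per-k state tables, UD rasters and the VI matrix are written when
#'   `out_dir` is set.
#' @export
run_state_analysis <- function(config = NULL, trip = NULL) {
  cfg <- read_run_config(config)
  if (is.null(trip)) {
    sim <- gen_trip(seed = derive_seed(cfg$seed, "trip"))
    trip <- sim$path
  }
  st <- cfg$states
  curve <- state_stability_curve(trip, k_grid = st$k_grid,
                                 state = st$state,
                                 seed = derive_seed(cfg$seed, "hmm"),
                                 grid_cells = st$grid_cells,
                                 n_restarts = st$n_restarts)
  if (all(is.na(curve$vi))) stop("run_state_analysis: all k values failed")
  out <- structure(list(curve = curve,
                        report = list(k = curve$k,
                                      failed_k = curve$failed_k,
                                      state_pct = curve$state_pct)),
                   class = "state_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(curve$state_pct),
                     file.path(cfg$out_dir, "state_percentages.csv"))
    utils::write.csv(as.data.frame(curve$vi),
                     file.path(cfg$out_dir, "vi_matrix.csv"))
    for (i in seq_along(curve$k)) {
      if (!is.null(curve$uds[[i]]))
        write_ud_raster(curve$uds[[i]],
                        file.path(cfg$out_dir,
                                  sprintf("ud_%s_k%04d.txt", curve$state,
                                          curve$k[i])))
    }
  }
  out
}

#' @export
print.state_run <- function(x, ...) {
  print(x$curve)
  invisible(x)
}
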