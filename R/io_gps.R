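# Canonical in-memory representation: a `gps_path` is a data.frame with
# columns time (UTC epoch seconds), lon, lat (decimal degrees WGS84) and
# speed (Doppler point speed, m/s, may be NA), carrying bird_id, species and
# nominal_interval as attributes. All internal units are metres / seconds /
# m/s; km and km/h appear only at reporting boundaries.

#' Construct a GPS path
#'
#' @param time numeric UTC epoch seconds (or POSIXct, converted).
#' @param lon,lat decimal degrees WGS84.
#' @param speed Doppler point speed in m/s; `NA` where the logger did not
#'   report one.
#' @param bird_id,species identifiers carried through all products.
#' @param nominal_interval nominal fix interval in seconds (1 for all but one
#'   study logger, which ran at 2 s).
#' @param extra optional data.frame of pass-through columns (quality flags).
#' @return object of class `gps_path`.
#' @export
gps_path <- function(time, lon, lat, speed = NA_real_,
                     bird_id = "unknown", species = "unknown",
                     nominal_interval = 1, extra = NULL) {
  if (inherits(time, "POSIXct")) time <- as.numeric(time)
  n <- length(time)
  if (n == 0) stop("gps_path: empty path")
  if (!nominal_interval %in% c(1, 2))
    stop("gps_path: nominal_interval must be 1 or 2 s")
  if (any(lat < -90 | lat > 90, na.rm = TRUE))
    stop("gps_path: latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180, na.rm = TRUE))
    stop("gps_path: longitude out of [-180, 180]")
  if (any(speed < 0, na.rm = TRUE))
    stop("gps_path: negative point speed")
  if (is.unsorted(time))
    stop("gps_path: timestamps must be non-decreasing (ingestion never reorders)")
  df <- data.frame(time = as.numeric(time), lon = lon, lat = lat,
                   speed = rep_len(as.numeric(speed), n))
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, class = c("gps_path", "data.frame"),
            bird_id = bird_id, species = species,
            nominal_interval = nominal_interval)
}

#' @export
print.gps_path <- function(x, ...) {
  cat(sprintf("<gps_path> bird %s (%s), %d fixes @ %d s nominal, span %.0f s\n",
              attr(x, "bird_id"), attr(x, "species"), nrow(x),
              attr(x, "nominal_interval"),
              x$time[nrow(x)] - x$time[1]))
  invisible(x)
}

# rebuild a gps_path from a row subset, keeping path attributes
keep_path_attrs <- function(df, template) {
  structure(as.data.frame(df), class = c("gps_path", "data.frame"),
            bird_id = attr(template, "bird_id"),
            species = attr(template, "species"),
            nominal_interval = attr(template, "nominal_interval"))
}

#' Read a delimited logger fix table
#'
#' Reads one logger deployment from delimited text into the canonical
#' representation. Column names are supplied by a mapping because low-cost
#' logger exports (i-gotU, CatTraQ) do not share a layout. Rows whose
#' timestamp or coordinates fail to parse are dropped and counted.
#'
#' @param file path to a delimited text file with a header row.
#' @param column_map named list/character vector mapping canonical names
#'   (`time`, `lat`, `lon`, `speed`) to file column names; `speed` optional.
#' @param tz timezone of the file's timestamps (default "UTC").
#' @param speed_unit `"m/s"` or `"km/h"`; speeds are converted to m/s.
#' @param delim field delimiter (default ",").
#' @param bird_id,species,nominal_interval path metadata.
#' @param time_format passed to [base::as.POSIXct()]; default ISO-like.
#' @return a `gps_path`; attribute `ingest_report` holds
#'   `list(rows_read, rows_dropped)`.
#' @export
read_fix_table <- function(file, column_map,
                           tz = "UTC", speed_unit = c("m/s", "km/h"),
                           delim = ",", bird_id = "unknown",
                           species = "unknown", nominal_interval = 1,
                           time_format = "%Y-%m-%d %H:%M:%S") {
  speed_unit <- match.arg(speed_unit)
  if (!file.exists(file)) stop("read_fix_table: no such file: ", file)
  raw <- utils::read.table(file, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, dec = ".",
                           comment.char = "")
  if (nrow(raw) == 0) stop("read_fix_table: empty file: ", file)
  column_map <- as.list(column_map)
  for (req in c("time", "lat", "lon")) {
    if (is.null(column_map[[req]]))
      stop("read_fix_table: column_map lacks mandatory key '", req, "'")
    if (!column_map[[req]] %in% names(raw))
      stop("read_fix_table: mapped column '", column_map[[req]],
           "' (", req, ") not in file")
  }
  t_raw <- raw[[column_map$time]]
  tt <- if (is.numeric(t_raw)) as.numeric(t_raw) else
    as.numeric(as.POSIXct(as.character(t_raw), tz = tz, format = time_format))
  lat <- suppressWarnings(as.numeric(raw[[column_map$lat]]))
  lon <- suppressWarnings(as.numeric(raw[[column_map$lon]]))
  spd <- if (!is.null(column_map$speed)) {
    if (!column_map$speed %in% names(raw))
      stop("read_fix_table: mapped column '", column_map$speed,
           "' (speed) not in file")
    s <- suppressWarnings(as.numeric(raw[[column_map$speed]]))
    if (speed_unit == "km/h") s / 3.6 else s
  } else NA_real_
  ok <- !is.na(tt) & !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  if (!any(ok)) stop("read_fix_table: no parseable rows in ", file)
  spd_ok <- if (length(spd) > 1) spd[ok] else spd
  path <- gps_path(tt[ok], lon[ok], lat[ok], spd_ok,
                   bird_id = bird_id, species = species,
                   nominal_interval = nominal_interval)
  attr(path, "ingest_report") <- list(rows_read = nrow(raw),
                                      rows_dropped = sum(!ok))
  path
}

#' Write analysis products to a directory
#'
#' Flights are written as a GeoJSON FeatureCollection of LineStrings with
#' per-flight properties (bird_id, SI, class); tabular products as CSV. A
#' JSON manifest lists every file with its row/feature count.
#'
#' @param out_dir output directory (created if needed).
#' @param flights optional list of `flight` objects (see [segment_flights()]).
#' @param tables optional named list of data.frames, written as `<name>.csv`.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
write_products <- function(out_dir, flights = NULL, tables = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_products: cannot create directory ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0)
    stop("write_products: directory not writable: ", out_dir)
  manifest <- list()
  if (!is.null(flights)) {
    feats <- lapply(flights, function(fl) {
      list(
        type = "Feature",
        geometry = list(
          type = "LineString",
          coordinates = mapply(function(a, b) c(a, b), fl$lon, fl$lat,
                               SIMPLIFY = FALSE)
        ),
        properties = list(
          flight_id = attr(fl, "flight_id"),
          bird_id = attr(fl, "bird_id"),
          species = attr(fl, "species"),
          SI = attr(fl, "si"),
          flight_class = attr(fl, "flight_class"),
          duration_s = fl$time[nrow(fl)] - fl$time[1],
          start_time = fl$time[1]
        )
      )
    })
    gj <- list(type = "FeatureCollection", features = feats)
    fp <- file.path(out_dir, "flights.geojson")
    jsonlite::write_json(gj, fp, auto_unbox = TRUE, digits = NA)
    manifest[["flights.geojson"]] <- length(feats)
    # fix-level table alongside the geometry
    fixtab <- do.call(rbind, lapply(flights, function(fl) {
      data.frame(flight_id = attr(fl, "flight_id"),
                 time = fl$time, lon = fl$lon, lat = fl$lat,
                 speed = fl$speed)
    }))
    utils::write.csv(fixtab, file.path(out_dir, "flight_fixes.csv"),
                     row.names = FALSE)
    manifest[["flight_fixes.csv"]] <- nrow(fixtab)
  }
  for (nm in names(tables)) {
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], fp, row.names = FALSE)
    manifest[[paste0(nm, ".csv")]] <- nrow(tables[[nm]])
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read flights back from a GeoJSON file written by [write_products()]
#'
#' @param file path to `flights.geojson`.
#' @param fix_table optional path to the companion `flight_fixes.csv`; when
#'   given, timestamps and speeds are restored from it.
#' @return list of `flight` objects.
#' @export
read_flights_geojson <- function(file, fix_table = NULL) {
  gj <- jsonlite::read_json(file)
  fixes <- if (!is.null(fix_table))
    utils::read.csv(fix_table, stringsAsFactors = FALSE) else NULL
  lapply(gj$features, function(ft) {
    cc <- do.call(rbind, lapply(ft$geometry$coordinates, unlist))
    pr <- ft$properties
    if (!is.null(fixes)) {
      sub <- fixes[fixes$flight_id == pr$flight_id, ]
      tm <- sub$time; spd <- sub$speed
    } else {
      tm <- pr$start_time + seq_len(nrow(cc)) - 1
      spd <- NA_real_
    }
    fl <- gps_path(tm, cc[, 1], cc[, 2], spd,
                   bird_id = pr$bird_id, species = pr$species)
    structure(fl, class = c("flight", class(fl)),
              flight_id = pr$flight_id, si = pr$SI,
              flight_class = pr$flight_class)
  })
}
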