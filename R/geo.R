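# Spherical geometry on the WGS84-coordinates-as-sphere convention used
# throughout: great-circle ("haversine") distances and initial bearings with
# a fixed mean Earth radius. All positions are decimal-degree lon/lat.

#' Earth radius used for all great-circle computations (metres)
#' @keywords internal
EARTH_RADIUS_M <- 6371000

#' Great-circle distance between successive positions
#'
#' @param lon,lat numeric vectors of equal length (decimal degrees).
#' @return numeric vector of length `length(lon) - 1`: haversine distances in
#'   metres between consecutive positions on a sphere of radius 6,371,000 m.
#' @export
gc_step_dist <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  p <- cbind(lon, lat)
  geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                           r = EARTH_RADIUS_M)
}

#' Initial great-circle bearing of each step
#'
#' @inheritParams gc_step_dist
#' @return numeric vector of length `length(lon) - 1`: initial bearings in
#'   degrees (north = 0, clockwise) of the step from position i to i + 1.
#' @export
gc_step_bearing <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  p <- cbind(lon, lat)
  geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE], f = 0)
}

#' Signed relative turning angles from a bearing sequence
#'
#' The relative turning angle at an interior position is the change in step
#' bearing, normalized to (-180, 180] degrees; positive is a clockwise turn.
#'
#' @param bearing numeric vector of step bearings (degrees).
#' @return numeric vector of length `length(bearing) - 1`.
#' @export
rel_turn_angle <- function(bearing) {
  n <- length(bearing)
  if (n < 2) return(numeric(0))
  d <- diff(bearing)
  norm_angle_deg(d)
}

#' Normalize angles in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return normalized angles.
#' @export
norm_angle_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Advance positions along great circles
#'
#' Steps each position `d` metres along the great circle with initial bearing
#' `b`, on the package sphere. Used by the track simulator so that generator
#' and analyzer share one distance convention.
#'
#' @param lon,lat starting position(s), decimal degrees.
#' @param b bearing(s), degrees.
#' @param d distance(s), metres.
#' @return two-column matrix (lon, lat).
#' @export
gc_destination <- function(lon, lat, b, d) {
  geosphere::destPoint(cbind(lon, lat), b, d, a = EARTH_RADIUS_M, f = 0)
}

#' Azimuthal-equidistant projection about a centre point
#'
#' Projects lon/lat to planar metres: each point is placed at its great-circle
#' distance from the centre, in the direction of its initial bearing. Distances
#' from the centre are exact; the projection is the standard choice for
#' kernel home-range work on a single trip.
#'
#' @param lon,lat positions (decimal degrees).
#' @param center optional `c(lon, lat)` centre; defaults to the mean position.
#' @return data.frame with columns `x`, `y` (metres) and attribute `center`.
#' @export
project_aeqd <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  p <- cbind(lon, lat)
  ctr <- matrix(center, ncol = 2)
  d <- geosphere::distHaversine(ctr, p, r = EARTH_RADIUS_M)
  b <- geosphere::bearing(ctr[rep(1, nrow(p)), , drop = FALSE], p, f = 0)
  b[is.na(b)] <- 0  # point coincident with centre
  out <- data.frame(x = d * sin(b * pi / 180), y = d * cos(b * pi / 180))
  attr(out, "center") <- center
  out
}

#' Test points against a polygon (even-odd rule)
#'
#' Ray-casting point-in-polygon in lon/lat space, used for the optional
#' on-land mask. Adequate for masks far from the antimeridian and poles.
#'
#' @param lon,lat query points.
#' @param poly_lon,poly_lat polygon vertices (closed or open ring).
#' @return logical vector, TRUE where the point is inside.
#' @export
point_in_polygon <- function(lon, lat, poly_lon, poly_lat) {
  np <- length(poly_lon)
  if (np >= 2 && poly_lon[1] == poly_lon[np] && poly_lat[1] == poly_lat[np]) {
    poly_lon <- poly_lon[-np]; poly_lat <- poly_lat[-np]
    np <- np - 1
  }
  inside <- logical(length(lon))
  j <- np
  for (i in seq_len(np)) {
    yi <- poly_lat[i]; yj <- poly_lat[j]
    xi <- poly_lon[i]; xj <- poly_lon[j]
    crosses <- ((yi > lat) != (yj > lat))
    if (any(crosses)) {
      xint <- (xj - xi) * (lat[crosses] - yi) / (yj - yi) + xi
      inside[crosses] <- xor(inside[crosses], lon[crosses] < xint)
    }
    j <- i
  }
  inside
}
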