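#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over
#' coordinate pairs; inputs are recycled to a common length.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in meters.
#' @examples
#' haversine_m(0, 0, 0, 1) # ~111,195 m along the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  r <- 6371000
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  2 * r * asin(sqrt(a))
}

#' Initial bearing from one point to another
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @return Bearing in radians, clockwise from north.
#' @keywords internal
bearing_rad <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  atan2(
    sin(dlam) * cos(p2),
    cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  )
}

#' Project points to a local azimuthal-equidistant plane
#'
#' Planar coordinates (meters) centered on \code{origin}: each point is placed
#' at its great-circle distance from the origin along its initial bearing
#' (x east, y north). Exact in distance-to-origin; the appropriate projection
#' for farthest-distance, hull and dispersion summaries at city scale.
#'
#' @param lat,lon Decimal degrees.
#' @param origin Numeric \code{c(lat, lon)} of the projection center.
#' @return Matrix with columns \code{x}, \code{y} in meters.
#' @export
project_aeqd <- function(lat, lon, origin) {
  d <- haversine_m(origin[1], origin[2], lat, lon)
  th <- bearing_rad(origin[1], origin[2], lat, lon)
  cbind(x = d * sin(th), y = d * cos(th))
}

#' Destination point given start, bearing and distance
#'
#' Spherical forward geodesic, used by the trajectory simulator.
#'
#' @param lat,lon Start, decimal degrees.
#' @param bearing_deg Bearing clockwise from north, degrees.
#' @param dist_m Distance in meters.
#' @return Numeric \code{c(lat, lon)} in degrees.
#' @keywords internal
dest_point <- function(lat, lon, bearing_deg, dist_m) {
  r <- 6371000
  delta <- dist_m / r
  th <- bearing_deg * pi / 180
  p1 <- lat * pi / 180
  l1 <- lon * pi / 180
  p2 <- asin(sin(p1) * cos(delta) + cos(p1) * sin(delta) * cos(th))
  l2 <- l1 + atan2(
    sin(th) * sin(delta) * cos(p1),
    cos(delta) - sin(p1) * sin(p2)
  )
  c(p2 * 180 / pi, l2 * 180 / pi)
}
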