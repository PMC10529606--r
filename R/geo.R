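#' Great-circle distance between points (haversine)
#'
#' Shortest distance over a spherical Earth between pairs of longitude/latitude
#' coordinates. Used throughout the pipeline: the QC speed filter, cumulative
#' trip distance, distance to the colony, and distance to the 0 m isobath.
#'
#' @param lon1,lat1 numeric vectors, decimal degrees (west negative).
#' @param lon2,lat2 numeric vectors, decimal degrees; recycled against the
#'   first pair.
#' @param radius Earth radius in km (default 6371).
#' @return numeric vector of distances in km.
#' @examples
#' great_circle_distance(-59.91, 43.93, -63.57, 44.65) # Sable Island -> Halifax
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius * asin(sqrt(a))
}

#' Local planar (equirectangular) projection about a reference point
#'
#' Converts lon/lat to x/y in km on a plane tangent near `origin`, using
#' cos(latitude) scaling of longitude. Adequate at continental-shelf scale,
#' where the move-persistence model assumes planar displacement steps.
#'
#' @param lon,lat numeric vectors, decimal degrees.
#' @param origin length-2 numeric `c(lon, lat)` of the projection origin.
#' @param radius Earth radius, km.
#' @return for `lonlat_to_km` a two-column matrix (x_km, y_km); for
#'   `km_to_lonlat` a two-column matrix (lon, lat).
#' @export
lonlat_to_km <- function(lon, lat, origin, radius = 6371) {
  to_rad <- pi / 180
  kx <- radius * to_rad * cos(origin[2] * to_rad)
  ky <- radius * to_rad
  cbind(x_km = (lon - origin[1]) * kx, y_km = (lat - origin[2]) * ky)
}

#' @rdname lonlat_to_km
#' @param x,y numeric vectors, km east/north of `origin`.
#' @export
km_to_lonlat <- function(x, y, origin, radius = 6371) {
  to_rad <- pi / 180
  kx <- radius * to_rad * cos(origin[2] * to_rad)
  ky <- radius * to_rad
  cbind(lon = origin[1] + x / kx, lat = origin[2] + y / ky)
}
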