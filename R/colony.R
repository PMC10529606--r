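#' Colony geometry for haulout classification
#'
#' The natal colony is represented as a polyline along the long axis of the
#' island (the island is a 43 km crescent, so distance is measured to the
#' nearest point of the axis rather than to a single centre point). Fixes
#' within `haulout_radius` km of the polyline are classified as hauled out at
#' the colony.
#'
#' @param centre lon/lat of the island centre (default the Sable Island
#'   coordinates 43.93 N, 59.91 W).
#' @param length_km total axis length (default 43 km).
#' @param bearing_deg axis orientation, degrees clockwise from north
#'   (default 90 = east-west).
#' @param haulout_radius radius in km (default 10).
#' @param n_vertices number of vertices the axis is densified to.
#' @return object of class `colony_geometry` with a `vertices` tibble.
#' @export
colony_geometry <- function(centre = c(-59.91, 43.93), length_km = 43,
                            bearing_deg = 90, haulout_radius = 10,
                            n_vertices = 45) {
  stopifnot(length_km > 0, haulout_radius > 0, n_vertices >= 2)
  s <- seq(-length_km / 2, length_km / 2, length.out = n_vertices)
  th <- bearing_deg * pi / 180
  xy <- cbind(s * sin(th), s * cos(th))
  ll <- km_to_lonlat(xy[, 1], xy[, 2], origin = centre)
  structure(list(centre = centre, haulout_radius = haulout_radius,
                 vertices = tibble::tibble(lon = ll[, 1], lat = ll[, 2])),
            class = "colony_geometry")
}

#' Distance from points to the colony polyline
#'
#' @param colony a [colony_geometry()].
#' @param lon,lat coordinate vectors, decimal degrees.
#' @return numeric vector: minimum great-circle distance (km) to the densified
#'   axis vertices.
#' @export
dist_to_colony <- function(colony, lon, lat) {
  vapply(seq_along(lon), function(k) {
    min(great_circle_distance(lon[k], lat[k],
                              colony$vertices$lon, colony$vertices$lat))
  }, numeric(1))
}
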