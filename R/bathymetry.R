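#' Synthetic shelf bathymetry
#'
#' Builds an ETOPO1-style elevation grid (metres, negative below sea level) on
#' a regular lon/lat lattice emulating a continental-shelf ecosystem: a low
#' sandbar island, a surrounding shallow shelf with banks (30-60 m deep) and
#' basins (200-300 m), and abyssal water (>= 1000 m) beyond a shelf-break
#' radius from the island.
#'
#' @param lon_range,lat_range length-2 numeric extents in decimal degrees.
#' @param cell_size grid cell size in degrees (single value, square cells).
#' @param island list with `centre` (lon, lat), `length_km`, `width_km`,
#'   `height_m` (> 0) describing an east-west elongated island.
#' @param banks list of lists, each with `centre`, `radius_km`, `depth_m`
#'   (30-60 m typical).
#' @param basins list of lists, each with `centre`, `radius_km`, `depth_m`
#'   (200-300 m typical).
#' @param shelf_depth_m background shelf depth (m, positive down).
#' @param shelf_break_km radius from the island centre beyond which depth
#'   ramps to at least `abyss_depth_m`.
#' @param abyss_depth_m off-shelf depth floor (default 1200 m).
#' @param noise_sd_m sd of seeded small-scale depth roughness (m); roughness
#'   is not applied on the island or beyond the shelf break so the structural
#'   guarantees hold exactly.
#' @param seed integer seed; the grid is bit-identical for identical inputs.
#' @return object of class `bathy_grid`: list with `lon_axis`, `lat_axis`
#'   (ascending), `elevation` (matrix, rows = lon, cols = lat), `cell_size`,
#'   and the island geometry used.
#' @export
make_bathymetry <- function(lon_range = c(-62, -57.3),
                            lat_range = c(42.6, 45.4),
                            cell_size = 0.05,
                            island = list(centre = c(-59.91, 43.93),
                                          length_km = 43, width_km = 1.5,
                                          height_m = 1.9),
                            banks = list(
                              list(centre = c(-60.8, 43.6), radius_km = 35, depth_m = 40),
                              list(centre = c(-59.0, 44.35), radius_km = 30, depth_m = 35),
                              list(centre = c(-58.2, 43.5), radius_km = 40, depth_m = 55)
                            ),
                            basins = list(
                              list(centre = c(-61.3, 44.6), radius_km = 30, depth_m = 250),
                              list(centre = c(-59.6, 44.8), radius_km = 25, depth_m = 220)
                            ),
                            shelf_depth_m = 100,
                            shelf_break_km = 220,
                            abyss_depth_m = 1200,
                            noise_sd_m = 4,
                            seed = 1L) {
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0 || cell_size <= 0) {
    stop("degenerate grid extent or cell size", call. = FALSE)
  }
  lon_axis <- seq(lon_range[1], lon_range[2], by = cell_size)
  lat_axis <- seq(lat_range[1], lat_range[2], by = cell_size)
  ctr <- island$centre
  xy <- expand.grid(lon = lon_axis, lat = lat_axis)
  km <- lonlat_to_km(xy$lon, xy$lat, origin = ctr)
  r <- sqrt(km[, 1]^2 + km[, 2]^2)

  depth <- rep(shelf_depth_m, nrow(xy))
  bump <- function(d, radius) pmax(0, 1 - (d / radius)^2) # quadratic bump
  for (b in banks) {
    bkm <- lonlat_to_km(xy$lon, xy$lat, origin = b$centre)
    d <- sqrt(bkm[, 1]^2 + bkm[, 2]^2)
    w <- bump(d, b$radius_km)
    depth <- depth - (shelf_depth_m - b$depth_m) * w
  }
  for (b in basins) {
    bkm <- lonlat_to_km(xy$lon, xy$lat, origin = b$centre)
    d <- sqrt(bkm[, 1]^2 + bkm[, 2]^2)
    w <- bump(d, b$radius_km)
    depth <- depth + (b$depth_m - shelf_depth_m) * w
  }
  # shelf break: smooth ramp down to the abyss over 60 km, then clamp
  beyond <- r > shelf_break_km
  ramp <- pmin(1, pmax(0, (r - shelf_break_km) / 60))
  depth <- depth * (1 - ramp) + abyss_depth_m * ramp
  depth[beyond] <- pmax(depth[beyond], abyss_depth_m)

  # island: elongated east-west ellipse raised above sea level; the minor
  # axis is widened to at least one grid cell so the island is resolved
  cell_km <- cell_size * 111.32
  half_width <- max(island$width_km / 2, 0.6 * cell_km)
  on_island <- (km[, 1] / (island$length_km / 2))^2 +
    (km[, 2] / half_width)^2 <= 1
  # ensure the centre cell itself is land even on coarse grids
  i_ctr <- which.min(abs(lon_axis - ctr[1]))
  j_ctr <- which.min(abs(lat_axis - ctr[2]))
  on_island[(j_ctr - 1) * length(lon_axis) + i_ctr] <- TRUE
  # narrow nearshore shoal so haulout sites exist but open water starts
  # within a few km of the island
  near <- !on_island & r <= 12
  depth[near] <- pmin(depth[near], 2 + 2.5 * r[near])

  if (noise_sd_m > 0) {
    set.seed(seed)
    eps <- stats::rnorm(nrow(xy), 0, noise_sd_m)
    ok <- !on_island & !beyond & !near
    depth[ok] <- pmax(depth[ok] + eps[ok], 6)
  }
  elev <- -depth
  elev[on_island] <- island$height_m

  structure(list(lon_axis = lon_axis, lat_axis = lat_axis,
                 elevation = matrix(elev, nrow = length(lon_axis)),
                 cell_size = cell_size, island = island),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat("<bathy_grid> ", length(x$lon_axis), "x", length(x$lat_axis),
      " cells of ", x$cell_size, " deg; elevation ",
      round(min(x$elevation)), "..", round(max(x$elevation)), " m\n", sep = "")
  invisible(x)
}

#' Elevation and depth lookup on a bathymetry grid
#'
#' Nearest-cell lookup of elevation (m, negative below sea level) or water
#' depth (m, positive down = negative elevation). Points outside the grid
#' extent return `NA`.
#'
#' @param bathy a `bathy_grid`.
#' @param lon,lat coordinate vectors, decimal degrees.
#' @return numeric vector.
#' @export
elevation_at <- function(bathy, lon, lat) {
  half <- bathy$cell_size / 2
  i <- findInterval(lon, c(bathy$lon_axis - half, bathy$lon_axis[length(bathy$lon_axis)] + half))
  j <- findInterval(lat, c(bathy$lat_axis - half, bathy$lat_axis[length(bathy$lat_axis)] + half))
  out <- rep(NA_real_, length(lon))
  ok <- i >= 1 & i <= length(bathy$lon_axis) & j >= 1 & j <= length(bathy$lat_axis)
  out[ok] <- bathy$elevation[cbind(i[ok], j[ok])]
  out
}

#' @rdname elevation_at
#' @export
depth_at <- function(bathy, lon, lat) -elevation_at(bathy, lon, lat)

#' Coastline (0 m isobath) cells of a bathymetry grid
#'
#' Cells at or above sea level that have at least one 4-neighbour below sea
#' level; these approximate the 0 m isobath used for distance-to-shore.
#'
#' @param bathy a `bathy_grid`.
#' @return tibble with `lon`, `lat` of coastline cell centres.
#' @export
coastline_cells <- function(bathy) {
  land <- bathy$elevation >= 0
  nb <- function(m, di, dj) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    ri <- seq_len(nrow(m)) + di
    rj <- seq_len(ncol(m)) + dj
    oki <- ri >= 1 & ri <= nrow(m)
    okj <- rj >= 1 & rj <= ncol(m)
    out[oki, okj] <- m[ri[oki], rj[okj]]
    out
  }
  water_nb <- nb(!land, 1, 0) | nb(!land, -1, 0) | nb(!land, 0, 1) | nb(!land, 0, -1)
  coast <- land & water_nb
  idx <- which(coast, arr.ind = TRUE)
  tibble::tibble(lon = bathy$lon_axis[idx[, 1]], lat = bathy$lat_axis[idx[, 2]])
}

#' Distance to shore (0 m isobath)
#'
#' Shortest great-circle distance (km) from each point to any coastline cell
#' centre of the grid.
#'
#' @param bathy a `bathy_grid`.
#' @param lon,lat coordinate vectors, decimal degrees.
#' @param coast optional precomputed [coastline_cells()] tibble.
#' @return numeric vector of distances, km.
#' @export
dist_to_shore <- function(bathy, lon, lat, coast = NULL) {
  if (is.null(coast)) coast <- coastline_cells(bathy)
  if (nrow(coast) == 0) {
    warning("grid contains no land; distance to shore is Inf")
    return(rep(Inf, length(lon)))
  }
  vapply(seq_along(lon), function(k) {
    min(great_circle_distance(lon[k], lat[k], coast$lon, coast$lat))
  }, numeric(1))
}

#' Write / read a bathymetry grid as ESRI ASCII
#'
#' Plain-text ESRI ASCII raster interchange (ncols/nrows header, rows from the
#' northernmost latitude down).
#'
#' @param bathy a `bathy_grid`.
#' @param path output file path.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a `bathy_grid` (without island metadata).
#' @export
write_esri_ascii <- function(bathy, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(bathy$lon_axis)),
    paste("nrows", length(bathy$lat_axis)),
    paste("xllcorner", format(bathy$lon_axis[1] - bathy$cell_size / 2, digits = 12)),
    paste("yllcorner", format(bathy$lat_axis[1] - bathy$cell_size / 2, digits = 12)),
    paste("cellsize", format(bathy$cell_size, digits = 12)),
    "NODATA_value -9999"
  ), con)
  for (j in rev(seq_along(bathy$lat_axis))) {
    writeLines(paste(format(bathy$elevation[, j], digits = 8), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- stats::setNames(hdr$value, tolower(hdr$key))
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  elev <- t(m[rev(seq_len(nrows)), , drop = FALSE]) # -> rows = lon, cols = lat
  structure(list(
    lon_axis = vals[["xllcorner"]] + cs / 2 + cs * (seq_len(ncols) - 1),
    lat_axis = vals[["yllcorner"]] + cs / 2 + cs * (seq_len(nrows) - 1),
    elevation = elev, cell_size = cs, island = NULL
  ), class = "bathy_grid")
}
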