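#' Split a filtered fix stream into modelling tracks
#'
#' Tracks break at every haulout bout and at every inter-fix gap exceeding
#' `max_gap_h` (strictly), so move persistence is never predicted across a
#' haulout or interpolated over a transmission gap. Segments with fewer than
#' `min_fixes` fixes are dropped.
#'
#' @param stream QC-filtered fixes of one animal (time-sorted).
#' @param calls matching [classify_haulout()] output.
#' @param max_gap_h maximum bridged gap, hours (default 48).
#' @param min_fixes minimum fixes per retained track (default 50).
#' @return tibble of the at-sea fixes in retained segments with an added
#'   integer `track` column (numbered 1..n per animal); dropped segments are
#'   reported via a `dropped` attribute (count).
#' @export
split_tracks <- function(stream, calls, max_gap_h = 48, min_fixes = 50) {
  stopifnot(nrow(stream) == nrow(calls))
  at_sea <- !calls$is_haulout
  seg <- integer(nrow(stream))
  cur <- 0L; prev_ok <- FALSE
  for (i in seq_len(nrow(stream))) {
    if (!at_sea[i]) { prev_ok <- FALSE; next }
    gap_ok <- prev_ok &&
      as.numeric(difftime(stream$time[i], stream$time[i - 1],
                          units = "hours")) <= max_gap_h
    if (!gap_ok) cur <- cur + 1L
    seg[i] <- cur
    prev_ok <- TRUE
  }
  keep_ids <- which(tabulate(seg) >= min_fixes)
  out <- stream[seg %in% keep_ids, , drop = FALSE]
  out$track <- match(seg[seg %in% keep_ids], keep_ids)
  n_dropped <- cur - length(keep_ids)
  if (n_dropped > 0) {
    message(n_dropped, " track segment(s) with fewer than ", min_fixes,
            " fixes dropped")
  }
  attr(out, "dropped") <- n_dropped
  tibble::as_tibble(out)
}

#' Linearly interpolate a track onto a regular time grid
#'
#' The grid starts at the first fix, steps by exactly `delta_h` hours, and
#' ends at or before the last fix (no extrapolation); longitude and latitude
#' are each interpolated linearly in time between bracketing fixes.
#'
#' @param track fixes of one track (time-sorted, columns `id`, `track`,
#'   `time`, `lon`, `lat`).
#' @param delta_h time step, hours; the study default is 6 (3, 4 and 8 are the
#'   alternatives examined by [timestep_diagnostics()]).
#' @return tibble `id, track, time, lon, lat` on the regular grid, or `NULL`
#'   (with a message) when the track spans less than `2 * delta_h`.
#' @export
interpolate_track <- function(track, delta_h = 6) {
  span_h <- as.numeric(difftime(track$time[nrow(track)], track$time[1],
                                units = "hours"))
  if (span_h < 2 * delta_h) {
    message("track spans ", round(span_h, 1), " h < 2 * ", delta_h,
            " h; skipped")
    return(NULL)
  }
  grid <- track$time[1] + 3600 * delta_h * (0:floor(span_h / delta_h))
  tt <- as.numeric(track$time)
  lon_i <- stats::approx(tt, track$lon, xout = as.numeric(grid))$y
  lat_i <- stats::approx(tt, track$lat, xout = as.numeric(grid))$y
  track_no <- if ("track" %in% names(track)) track$track[1] else 1L
  tibble::tibble(id = track$id[1], track = track_no, time = grid,
                 lon = lon_i, lat = lat_i)
}

#' Annotate a regular track with environmental and design covariates
#'
#' Adds water-column depth (m; locations at or above sea level are assigned
#' 1 m so the ln transform is defined), `ln_depth`, distance to the 0 m
#' isobath (km), and the week at sea counted from the animal's first at-sea
#' fix.
#'
#' @param rt an interpolated track ([interpolate_track()]).
#' @param bathy a `bathy_grid`.
#' @param first_at_sea POSIXct week origin for this animal.
#' @param coast optional precomputed [coastline_cells()].
#' @param shore_grid optional precomputed [shore_distance_grid()]; when given
#'   distance to shore uses fast nearest-cell lookup.
#' @return `rt` with columns `depth_m`, `ln_depth`, `dist_shore_km`, `week`
#'   added; off-grid locations get NA covariates and are flagged in
#'   `off_grid`.
#' @export
annotate_covariates <- function(rt, bathy, first_at_sea, coast = NULL,
                                shore_grid = NULL) {
  elev <- elevation_at(bathy, rt$lon, rt$lat)
  depth <- -elev
  depth[!is.na(depth) & depth <= 0] <- 1
  dsh <- if (!is.null(shore_grid)) {
    shore_dist_at(bathy, shore_grid, rt$lon, rt$lat)
  } else {
    dist_to_shore(bathy, rt$lon, rt$lat, coast = coast)
  }
  rt$depth_m <- depth
  rt$ln_depth <- log(depth)
  rt$dist_shore_km <- dsh
  rt$week <- week_at_sea(rt$time, first_at_sea)
  rt$off_grid <- is.na(elev)
  rt
}

#' Regularize and annotate all of an animal's tracks
#'
#' Convenience wrapper: [split_tracks()], then [interpolate_track()] and
#' [annotate_covariates()] per track, binding results and copying the pup's
#' intrinsic covariates onto every location.
#'
#' @param stream,calls,bathy,first_at_sea,delta_h,shore_grid see the
#'   underlying functions.
#' @param pup one row of the biometrics table (`sex`, `mass_wean`,
#'   `length_wean`, `postwean_days`).
#' @param max_gap_h,min_fixes passed to [split_tracks()].
#' @return tibble of annotated regular locations (possibly empty).
#' @export
regularize_animal <- function(stream, calls, bathy, pup, first_at_sea,
                              delta_h = 6, max_gap_h = 48, min_fixes = 50,
                              shore_grid = NULL) {
  tr <- split_tracks(stream, calls, max_gap_h = max_gap_h,
                     min_fixes = min_fixes)
  if (nrow(tr) == 0) return(tibble::tibble())
  out <- lapply(split(tr, tr$track), function(one) {
    ri <- interpolate_track(one, delta_h = delta_h)
    if (is.null(ri)) return(NULL)
    annotate_covariates(ri, bathy, first_at_sea, shore_grid = shore_grid)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(out)
  out$sex <- pup$sex
  out$mass <- pup$mass_wean
  out$length <- pup$length_wean
  out$postwean <- pup$postwean_days
  out
}

#' Time-step diagnostics for regularization
#'
#' Fits the intercept-only move-persistence model to tracks regularized at
#' each candidate time step and reports, per step: the number of locations,
#' the standard error of the persistence intercept, the mean plug-in gamma,
#' and the lag-1 autocorrelation of one-step-ahead residuals. The user picks
#' the step (the study used 6 h); no automatic selection is performed.
#'
#' @param streams named list (per animal) of lists with elements `stream`,
#'   `calls`, `first_at_sea`, `pup`.
#' @param bathy a `bathy_grid`.
#' @param deltas candidate steps in hours.
#' @param min_fixes passed through to [split_tracks()].
#' @return tibble: `delta_h`, `n_locations`, `se_intercept`, `mean_gamma`,
#'   `resid_acf1_x`, `resid_acf1_y`, `converged`.
#' @export
timestep_diagnostics <- function(streams, bathy, deltas = c(3, 4, 6, 8),
                                 min_fixes = 50) {
  shore_grid <- shore_distance_grid(bathy)
  out <- lapply(deltas, function(dh) {
    tracks <- dplyr::bind_rows(lapply(streams, function(s) {
      regularize_animal(s$stream, s$calls, bathy, s$pup, s$first_at_sea,
                        delta_h = dh, min_fixes = min_fixes,
                        shore_grid = shore_grid)
    }))
    if (nrow(tracks) == 0) {
      return(tibble::tibble(delta_h = dh, n_locations = 0L,
                            se_intercept = NA_real_, mean_gamma = NA_real_,
                            resid_acf1_x = NA_real_, resid_acf1_y = NA_real_,
                            converged = FALSE))
    }
    md <- build_model_data(tracks)
    fit <- fit_mpmm(md, ~ 1)
    res <- osa_residuals(fit)
    a1 <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 3) return(NA_real_)
      stats::acf(v, lag.max = 1, plot = FALSE)$acf[2]
    }
    tibble::tibble(delta_h = dh, n_locations = nrow(tracks),
                   se_intercept = fit$coefficients$se[1],
                   mean_gamma = mean(fit$gamma$gamma),
                   resid_acf1_x = a1(res$resid_x), resid_acf1_y = a1(res$resid_y),
                   converged = fit$convergence == 0)
  })
  dplyr::bind_rows(out)
}
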