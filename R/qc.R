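#' Fastloc GPS quality-control configuration
#'
#' Thresholds for the three-stage Fastloc filter: fixes computed from fewer
#' than `min_satellites` satellites are removed, then fixes with a Fastloc
#' residual error metric strictly greater than `max_residual`, then a forward
#' speed filter removing fixes implying an apparent swim speed strictly above
#' `max_speed` from the last retained fix.
#'
#' @param min_satellites minimum satellite count retained (default 5, i.e.
#'   fixes with 4 or fewer satellites are removed).
#' @param max_residual maximum Fastloc residual retained (default 30; a value
#'   of exactly 30 is kept).
#' @param max_speed maximum apparent speed in km/h (default 10).
#' @param earth_radius spherical Earth radius in km used for speeds.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_satellites = 5, max_residual = 30, max_speed = 10,
                      earth_radius = 6371) {
  stopifnot(min_satellites > 0, max_residual > 0, max_speed > 0,
            earth_radius > 0)
  structure(list(min_satellites = min_satellites, max_residual = max_residual,
                 max_speed = max_speed, earth_radius = earth_radius),
            class = "qc_config")
}

#' Filter a Fastloc fix stream
#'
#' Applies the three quality filters in order (satellite count, residual,
#' speed), per animal. The speed filter is a single forward sweep: a fix is
#' removed when the great-circle speed from the most recent retained fix
#' exceeds `max_speed`; each removed fix carries the first failing filter as
#' its removal reason.
#'
#' @param stream a data frame of fixes with columns `id`, `time` (POSIXct,
#'   strictly increasing within animal), `lon`, `lat`, `n_sat`, `residual`.
#'   Extra columns are carried through.
#' @param config a [qc_config()].
#' @return a list with elements
#'   * `kept`: the retained fixes, original order preserved;
#'   * `removed`: removed fixes with a `reason` column
#'     (`"satellites"`, `"residual"`, `"speed"`);
#'   * `report`: a one-row tibble with `n_input`, `n_removed_satellites`,
#'     `n_removed_residual`, `n_removed_speed`, `n_kept`.
#' @export
filter_fixes <- function(stream, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  need <- c("id", "time", "lon", "lat", "n_sat", "residual")
  missing_cols <- setdiff(need, names(stream))
  if (length(missing_cols)) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stream <- tibble::as_tibble(stream)
  if (nrow(stream) == 0) {
    rep <- tibble::tibble(n_input = 0L, n_removed_satellites = 0L,
                          n_removed_residual = 0L, n_removed_speed = 0L,
                          n_kept = 0L)
    return(list(kept = stream,
                removed = dplyr::mutate(stream, reason = character(0)),
                report = rep))
  }
  bad_order <- vapply(split(as.numeric(stream$time), stream$id),
                      function(tt) any(diff(tt) <= 0), logical(1))
  if (any(bad_order)) {
    stop("fix times must be strictly increasing within each animal: ",
         paste(names(bad_order)[bad_order], collapse = ", "), call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(stream))
  reason[stream$n_sat < config$min_satellites] <- "satellites"
  fail_res <- is.na(reason) & stream$residual > config$max_residual
  reason[fail_res] <- "residual"

  # speed sweep over survivors, per animal
  for (animal in unique(stream$id)) {
    idx <- which(stream$id == animal & is.na(reason))
    if (length(idx) < 2) next
    last <- idx[1]
    for (j in idx[-1]) {
      dt_h <- as.numeric(difftime(stream$time[j], stream$time[last],
                                  units = "hours"))
      d_km <- great_circle_distance(stream$lon[last], stream$lat[last],
                                    stream$lon[j], stream$lat[j],
                                    radius = config$earth_radius)
      if (dt_h > 0 && d_km / dt_h > config$max_speed) {
        reason[j] <- "speed"
      } else {
        last <- j
      }
    }
  }

  kept <- stream[is.na(reason), , drop = FALSE]
  removed <- stream[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  report <- tibble::tibble(
    n_input = nrow(stream),
    n_removed_satellites = sum(reason == "satellites", na.rm = TRUE),
    n_removed_residual = sum(reason == "residual", na.rm = TRUE),
    n_removed_speed = sum(reason == "speed", na.rm = TRUE),
    n_kept = nrow(kept)
  )
  list(kept = kept, removed = removed, report = report)
}
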