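#' Classify fixes as hauled out
#'
#' A fix is hauled out when any of three conditions holds, recorded in this
#' order of precedence: (i) the tag's own wet/dry logic flagged a haulout,
#' (ii) the water column at the fix is at most `depth_threshold` m deep
#' (depth = negative elevation, nearest-cell lookup), or (iii) the fix lies
#' within the colony haulout radius of the island axis.
#'
#' @param fixes data frame with `lon`, `lat` and (optionally) `tag_haulout`.
#' @param bathy a `bathy_grid`; fixes outside its extent skip the depth rule
#'   with a warning.
#' @param colony a [colony_geometry()].
#' @param depth_threshold haulout depth threshold, m (default 5; exactly 5 m
#'   is hauled out).
#' @return tibble with `is_haulout` (logical) and `reason`
#'   (`"tag_flag"`, `"shallow_depth"`, `"colony_radius"`, `"none"`).
#' @export
classify_haulout <- function(fixes, bathy, colony, depth_threshold = 5) {
  tagf <- if ("tag_haulout" %in% names(fixes)) fixes$tag_haulout else
    rep(FALSE, nrow(fixes))
  dep <- depth_at(bathy, fixes$lon, fixes$lat)
  if (anyNA(dep)) {
    warning(sum(is.na(dep)), " fix(es) outside the bathymetry grid; ",
            "shallow-depth rule skipped for them")
  }
  shallow <- !is.na(dep) & dep <= depth_threshold
  near_colony <- dist_to_colony(colony, fixes$lon, fixes$lat) <=
    colony$haulout_radius
  reason <- rep("none", nrow(fixes))
  reason[near_colony] <- "colony_radius"
  reason[shallow] <- "shallow_depth"
  reason[tagf] <- "tag_flag"
  tibble::tibble(is_haulout = reason != "none", reason = reason)
}

#' Segment a fix stream into trips
#'
#' Maximal runs of consecutive at-sea fixes bounded by haulout fixes (or the
#' stream ends) become candidate bouts; bouts whose at-sea span (last minus
#' first at-sea fix time) exceeds 24 h become trips. A trip whose bounding end
#' is the stream end (tag died at sea) is marked incomplete. Shorter bouts are
#' returned separately and take no part in trip statistics.
#'
#' @param stream QC-filtered fixes of one animal (time-sorted; columns `id`,
#'   `time`, `lon`, `lat`).
#' @param calls matching [classify_haulout()] tibble.
#' @param min_duration_h trip duration threshold, h (default 24, strict).
#' @return list with
#'   * `trips`: tibble, one row per trip — `id`, `trip_no`, `start`, `end`,
#'     `complete`, `n_fixes`, origin/destination haulout coordinates
#'     (`origin_lon` etc., NA when unbounded), and a list-column `fixes`
#'     holding each trip's at-sea fixes;
#'   * `excluded`: same shape for bouts that did not exceed the threshold.
#' @export
segment_trips <- function(stream, calls, min_duration_h = 24) {
  stopifnot(nrow(stream) == nrow(calls))
  empty <- tibble::tibble(id = character(0), trip_no = integer(0),
                          start = as.POSIXct(character(0), tz = "UTC"),
                          end = as.POSIXct(character(0), tz = "UTC"),
                          complete = logical(0), n_fixes = integer(0),
                          origin_lon = numeric(0), origin_lat = numeric(0),
                          dest_lon = numeric(0), dest_lat = numeric(0),
                          fixes = list())
  if (nrow(stream) == 0) return(list(trips = empty, excluded = empty))
  at_sea <- !calls$is_haulout
  r <- rle(at_sea)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  trips <- list(); excl <- list(); trip_no <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    span_h <- as.numeric(difftime(stream$time[i1], stream$time[i0],
                                  units = "hours"))
    complete <- i1 < nrow(stream) # bounded by a haulout fix at the end
    origin <- if (i0 > 1) c(stream$lon[i0 - 1], stream$lat[i0 - 1]) else
      c(NA_real_, NA_real_)
    dest <- if (complete) c(stream$lon[i1 + 1], stream$lat[i1 + 1]) else
      c(NA_real_, NA_real_)
    row <- tibble::tibble(
      id = stream$id[i0], trip_no = NA_integer_,
      start = stream$time[i0], end = stream$time[i1],
      complete = complete, n_fixes = i1 - i0 + 1L,
      origin_lon = origin[1], origin_lat = origin[2],
      dest_lon = dest[1], dest_lat = dest[2],
      fixes = list(stream[i0:i1, , drop = FALSE])
    )
    if (span_h > min_duration_h) {
      trip_no <- trip_no + 1L
      row$trip_no <- trip_no
      trips[[length(trips) + 1]] <- row
    } else {
      excl[[length(excl) + 1]] <- row
    }
  }
  list(trips = if (length(trips)) dplyr::bind_rows(trips) else empty,
       excluded = if (length(excl)) dplyr::bind_rows(excl) else empty)
}

#' Trip metrics
#'
#' For a trip: total duration (days), cumulative great-circle distance over
#' successive at-sea fixes (km), and mean speed (km/h = distance / duration in
#' hours). For complete trips followed by another trip, the subsequent haulout
#' duration (h) is the time from the first hauled-out fix after the trip to
#' the first at-sea fix of the next trip.
#'
#' @param trip one row of [segment_trips()]'s `trips`.
#' @param next_trip_start start time of the animal's next trip (`NULL`/NA when
#'   none; haulout duration is then NA).
#' @param first_haulout_after time of the first haulout-classified fix after
#'   the trip (defaults to the trip's destination boundary fix time).
#' @return one-row tibble: `duration_d`, `distance_km`, `mean_speed_kmh`,
#'   `haulout_duration_h`.
#' @export
trip_metrics <- function(trip, next_trip_start = NULL,
                         first_haulout_after = NULL) {
  fx <- trip$fixes[[1]]
  dur_d <- as.numeric(difftime(trip$end, trip$start, units = "days"))
  dist <- if (nrow(fx) >= 2) {
    sum(great_circle_distance(fx$lon[-nrow(fx)], fx$lat[-nrow(fx)],
                              fx$lon[-1], fx$lat[-1]))
  } else 0
  speed <- if (dur_d > 0 && nrow(fx) >= 2) dist / (dur_d * 24) else NA_real_
  ho <- NA_real_
  if (!is.null(next_trip_start) && !is.na(next_trip_start) && trip$complete) {
    t_ho <- if (!is.null(first_haulout_after)) first_haulout_after else trip$end
    ho <- as.numeric(difftime(next_trip_start, t_ho, units = "hours"))
  }
  tibble::tibble(duration_d = dur_d, distance_km = dist,
                 mean_speed_kmh = speed, haulout_duration_h = ho)
}

#' Trip type: colony return, mixed, or between other haulouts
#'
#' Type A when both the origin and destination haulout sites lie within the
#' colony radius, B when exactly one does, C when neither does; incomplete
#' trips are typed `"incomplete"`.
#'
#' @param trip one row of [segment_trips()]'s `trips`.
#' @param colony a [colony_geometry()].
#' @return character scalar: "A", "B", "C" or "incomplete".
#' @export
classify_trip_type <- function(trip, colony) {
  if (!isTRUE(trip$complete)) return("incomplete")
  near <- function(lon, lat) {
    !is.na(lon) && dist_to_colony(colony, lon, lat) <= colony$haulout_radius
  }
  o <- near(trip$origin_lon, trip$origin_lat)
  d <- near(trip$dest_lon, trip$dest_lat)
  if (o && d) "A" else if (o || d) "B" else "C"
}

#' Build the per-trip summary table for one animal
#'
#' Runs [segment_trips()], computes metrics, types, haulout durations between
#' consecutive trips, and the week at sea at each trip's end (weeks count from
#' 1 at the first at-sea fix of the first trip).
#'
#' @param stream QC-filtered fixes of one animal.
#' @param calls matching [classify_haulout()] output.
#' @param colony a [colony_geometry()].
#' @return list with `trips` (summary tibble: id, trip_no, start, end,
#'   complete, type, duration_d, distance_km, mean_speed_kmh,
#'   haulout_duration_h, week_at_end), `excluded` bouts, and `first_at_sea`
#'   (POSIXct of the week origin, NA when no trips).
#' @export
trip_summaries <- function(stream, calls, colony) {
  seg <- segment_trips(stream, calls)
  trips <- seg$trips
  if (nrow(trips) == 0) {
    return(list(trips = trips, excluded = seg$excluded,
                first_at_sea = as.POSIXct(NA, tz = "UTC")))
  }
  first_at_sea <- trips$start[1]
  ho_times <- stream$time[calls$is_haulout]
  out <- vector("list", nrow(trips))
  for (k in seq_len(nrow(trips))) {
    nxt <- if (k < nrow(trips)) trips$start[k + 1] else NA
    after <- ho_times[ho_times >= trips$end[k]]
    first_ho <- if (length(after)) after[1] else NULL
    m <- trip_metrics(trips[k, ], next_trip_start = nxt,
                      first_haulout_after = first_ho)
    m$type <- classify_trip_type(trips[k, ], colony)
    m$week_at_end <- as.integer(
      floor(as.numeric(difftime(trips$end[k], first_at_sea,
                                units = "days")) / 7) + 1)
    out[[k]] <- m
  }
  list(trips = dplyr::bind_cols(
    trips[, c("id", "trip_no", "start", "end", "complete", "n_fixes")],
    dplyr::bind_rows(out)[, c("type", "duration_d", "distance_km",
                              "mean_speed_kmh", "haulout_duration_h",
                              "week_at_end")]),
    excluded = seg$excluded, first_at_sea = first_at_sea)
}

#' Per-animal covariates derived from trips
#'
#' Post-weaning duration (days from weaning to the first at-sea fix of the
#' first trip), the week-at-sea labelling origin, and trip frequency (complete
#' trips per deployment day).
#'
#' @param pup one row of a biometrics table with `wean_date`.
#' @param trips the `trips` tibble from [trip_summaries()].
#' @param deployment_days tracking days for the frequency denominator.
#' @return one-row tibble: `postwean_days`, `first_at_sea`, `n_trips_complete`,
#'   `trip_frequency` (trips per deployment day).
#' @export
derive_animal_covariates <- function(pup, trips, deployment_days) {
  first_at_sea <- if (nrow(trips)) trips$start[1] else as.POSIXct(NA, tz = "UTC")
  pw <- if (!is.na(first_at_sea) && !is.null(pup$wean_date)) {
    as.numeric(difftime(first_at_sea, pup$wean_date, units = "days"))
  } else NA_real_
  ncomp <- sum(trips$complete)
  tibble::tibble(postwean_days = pw, first_at_sea = first_at_sea,
                 n_trips_complete = ncomp,
                 trip_frequency = ncomp / deployment_days)
}

#' Week-at-sea label for arbitrary times
#'
#' Weeks count from 1 starting at the animal's first at-sea fix; week(t) =
#' floor((t - origin)/7 d) + 1.
#'
#' @param time POSIXct vector.
#' @param first_at_sea the animal's week origin.
#' @return integer vector.
#' @export
week_at_sea <- function(time, first_at_sea) {
  as.integer(floor(as.numeric(difftime(time, first_at_sea,
                                       units = "days")) / 7) + 1)
}
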