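#' Default generative coefficients for synthetic move persistence
#'
#' Named logit-scale coefficients used by the synthetic-track generator:
#' intercept plus the seven covariates of the move-persistence model (female
#' sex indicator, weaning mass kg, weaning length cm, post-weaning duration d,
#' week at sea, distance to shore km, ln water depth). Magnitudes follow the
#' fitted coefficients reported for the study cohort, so synthetic cohorts
#' exercise the model at realistic effect sizes.
#'
#' @return named numeric vector.
#' @export
default_persistence_beta <- function() {
  c(intercept = 11.747, sex = -0.452, mass = 0.0151, length = -0.105,
    postwean = -0.0507, week = -0.0355, dist_shore = -0.00525,
    ln_depth = 0.502)
}

#' Precompute nearest-shore distance for every grid cell
#'
#' Distance (km) from each cell centre to the nearest coastline cell, used
#' for fast distance-to-shore lookups along tracks.
#'
#' @param bathy a `bathy_grid`.
#' @param coast optional precomputed [coastline_cells()].
#' @return matrix aligned with `bathy$elevation`.
#' @export
shore_distance_grid <- function(bathy, coast = NULL) {
  if (is.null(coast)) coast <- coastline_cells(bathy)
  g <- expand.grid(lon = bathy$lon_axis, lat = bathy$lat_axis)
  d <- dist_to_shore(bathy, g$lon, g$lat, coast = coast)
  matrix(d, nrow = length(bathy$lon_axis))
}

shore_dist_at <- function(bathy, grid, lon, lat) {
  half <- bathy$cell_size / 2
  i <- findInterval(lon, c(bathy$lon_axis - half,
                           bathy$lon_axis[length(bathy$lon_axis)] + half))
  j <- findInterval(lat, c(bathy$lat_axis - half,
                           bathy$lat_axis[length(bathy$lat_axis)] + half))
  out <- rep(NA_real_, length(lon))
  ok <- i >= 1 & i <= length(bathy$lon_axis) & j >= 1 & j <= length(bathy$lat_axis)
  out[ok] <- grid[cbind(i[ok], j[ok])]
  out
}

# covariate row on the natural scales of the persistence model
persistence_eta <- function(beta, sex_female, mass, length_cm, postwean,
                            week, dist_shore, ln_depth) {
  get <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  get("intercept") + get("sex") * sex_female + get("mass") * mass +
    get("length") * length_cm + get("postwean") * postwean +
    get("week") * week + get("dist_shore") * dist_shore +
    get("ln_depth") * ln_depth
}

#' Simulate one pup's latent movement path
#'
#' Generates a first-difference correlated random walk in local planar km
#' coordinates: `d_t = gamma_t * d_{t-1} + eps_t`, `eps_t ~ N(0, sigma_step^2 I)`,
#' with `logit(gamma_t) = x_t' beta + b_i` where `b_i ~ N(0, sigma_b^2)` is the
#' pup's random intercept, drawn once. Covariates (week at sea, ln water
#' depth, distance to shore, plus the pup's biometrics) are evaluated along
#' the path from the bathymetry grid. The animal alternates scheduled at-sea
#' bouts and haulouts; during a haulout it is pinned to the nearest shore cell
#' (depth <= 5 m). Near the end of an at-sea bout the innovation is blended
#' gently toward the upcoming haulout site so that haulout entry is continuous
#' rather than a teleport.
#'
#' @param pup one row of a [simulate_cohort()] tibble.
#' @param bathy a [make_bathymetry()] grid.
#' @param beta named logit-scale coefficient vector
#'   (see [default_persistence_beta()]); missing names contribute 0.
#' @param sigma_b sd of the pup random intercept (logit scale).
#' @param sigma_step per-axis innovation sd in km at the 6 h reference step
#'   (default 4). `beta` and `sigma_step` are interpreted at that reference
#'   step; when `step_min` is finer the recursion uses the time-rescaled
#'   persistence `gamma^(step_min/360)` and the matching innovation sd, so
#'   the process aggregates back to the reference dynamics.
#' @param step_min path time step in minutes (15 = tag attempt interval).
#' @param deployment_days days of track after first departure.
#' @param trip_meanlog,trip_sdlog lognormal at-sea bout durations, days
#'   (defaults give mean ~15.9 d, sd ~16.6 d).
#' @param haulout_meanlog,haulout_sdlog lognormal haulout durations, hours
#'   (defaults give mean ~33.6 h, sd ~29 h).
#' @param initial_haulout_h haulout duration preceding first departure.
#' @param seed integer seed.
#' @param shore_grid optional precomputed [shore_distance_grid()].
#' @return list with
#'   * `path`: tibble `time, lon, lat, x_km, y_km, gamma_true, at_sea, week`;
#'   * `truth`: list `beta, sigma_b, b_i, sigma_step, step_min,
#'     haulout_schedule` (tibble of start/end/lon/lat windows).
#' @export
simulate_track <- function(pup, bathy, beta = default_persistence_beta(),
                           sigma_b = 0.2, sigma_step = NULL, step_min = 15,
                           deployment_days = 60,
                           trip_meanlog = log(15.9) - 0.368, trip_sdlog = 0.858,
                           haulout_meanlog = log(33.6) - 0.278,
                           haulout_sdlog = 0.746,
                           initial_haulout_h = 24,
                           seed = 1L, shore_grid = NULL) {
  stopifnot(sigma_b >= 0, step_min > 0, deployment_days > 0)
  if (is.null(sigma_step)) sigma_step <- 4
  ratio <- step_min / 360
  origin <- if (!is.null(bathy$island)) bathy$island$centre else
    c(mean(bathy$lon_axis), mean(bathy$lat_axis))
  if (is.na(elevation_at(bathy, pup$release_lon, pup$release_lat))) {
    stop("release site lies outside the bathymetry grid", call. = FALSE)
  }
  if (is.null(shore_grid)) shore_grid <- shore_distance_grid(bathy)
  set.seed(seed)
  b_i <- if (sigma_b > 0) stats::rnorm(1, 0, sigma_b) else 0

  dt_h <- step_min / 60
  departure <- pup$wean_date + pup$postwean_days * 86400
  t0 <- departure - initial_haulout_h * 3600
  t_end <- departure + deployment_days * 86400
  times <- seq(t0, t_end, by = step_min * 60)
  n <- length(times)

  # schedule alternating haulout / at-sea windows covering [t0, t_end]
  win_start <- t0; hauled <- TRUE
  sched <- list(); cur_end <- departure
  sched[[1]] <- list(start = t0, end = departure)
  while (cur_end < t_end) {
    sea_d <- pmax(stats::rlnorm(1, trip_meanlog, trip_sdlog), 1.05) # > 24 h
    sea_end <- cur_end + sea_d * 86400
    ho_h <- pmax(stats::rlnorm(1, haulout_meanlog, haulout_sdlog), 2)
    sched[[length(sched) + 1]] <- list(start = sea_end,
                                       end = sea_end + ho_h * 3600)
    cur_end <- sea_end + ho_h * 3600
  }
  ho_start <- as.POSIXct(vapply(sched, function(w) as.numeric(w$start), 0),
                         origin = "1970-01-01", tz = "UTC")
  ho_end <- as.POSIXct(vapply(sched, function(w) as.numeric(w$end), 0),
                       origin = "1970-01-01", tz = "UTC")

  nearest_shore_cell <- function(lon, lat) {
    shallow <- which(bathy$elevation >= -5, arr.ind = TRUE)
    slon <- bathy$lon_axis[shallow[, 1]]; slat <- bathy$lat_axis[shallow[, 2]]
    k <- which.min(great_circle_distance(lon, lat, slon, slat))
    c(slon[k], slat[k])
  }

  lon <- numeric(n); lat <- numeric(n)
  gamma_true <- rep(NA_real_, n); at_sea <- logical(n); week <- integer(n)
  ho_lon <- rep(NA_real_, length(ho_start)); ho_lat <- ho_lon

  pos <- c(pup$release_lon, pup$release_lat)
  site0 <- nearest_shore_cell(pos[1], pos[2])
  ho_lon[1] <- site0[1]; ho_lat[1] <- site0[2]
  d_prev <- c(0, 0)
  sexf <- as.numeric(pup$sex == "female")
  lim_lon <- range(bathy$lon_axis); lim_lat <- range(bathy$lat_axis)
  margin <- 2 * bathy$cell_size

  out_win <- 0L; out_dir <- c(1, 0)
  current_win <- function(t) {
    k <- which(t >= ho_start & t < ho_end)
    if (length(k)) k[1] else 0L
  }
  next_win_after <- function(t) {
    k <- which(ho_start >= t)
    if (length(k)) k[1] else 0L
  }

  for (s in seq_len(n)) {
    t <- times[s]
    week[s] <- max(1L, as.integer(floor(as.numeric(difftime(t, departure,
                                                            units = "days")) / 7) + 1))
    w <- current_win(t)
    if (w > 0) {
      if (is.na(ho_lon[w])) {
        site <- nearest_shore_cell(pos[1], pos[2])
        ho_lon[w] <- site[1]; ho_lat[w] <- site[2]
      }
      pos <- c(ho_lon[w], ho_lat[w])
      lon[s] <- pos[1]; lat[s] <- pos[2]
      at_sea[s] <- FALSE
      d_prev <- c(0, 0) # velocity resets while ashore
      next
    }
    # at sea: covariates at current position, then step
    dep <- depth_at(bathy, pos[1], pos[2])
    dep <- if (is.na(dep)) 1000 else max(dep, 1)
    dsh <- shore_dist_at(bathy, shore_grid, pos[1], pos[2])
    if (is.na(dsh)) dsh <- 300
    eta <- persistence_eta(beta, sexf, pup$mass_wean, pup$length_wean,
                           pup$postwean_days, week[s], dsh, log(dep)) + b_i
    g <- min(max(stats::plogis(eta), 1e-6), 0.999)
    gamma_true[s] <- g
    # time rescaling: per-step persistence g^ratio, innovation sd chosen so
    # the stationary velocity (and hence speed) matches the reference step
    g_step <- g^ratio
    sd_t <- sigma_step * ratio * sqrt((1 - g_step^2) / (1 - g^2))
    eps <- stats::rnorm(2, 0, sd_t)
    d <- g_step * d_prev + eps
    # steering toward the next haulout site near the end of the bout
    # outbound push for the first hours after a haulout so the animal clears
    # the colony/shallow zone promptly (real pups leave in directed travel)
    pw <- which(ho_end <= t)
    pushing <- FALSE
    if (length(pw)) {
      pw <- pw[length(pw)]
      since_h <- as.numeric(difftime(t, ho_end[pw], units = "hours"))
      if (since_h <= 18 && !is.na(ho_lon[pw])) {
        pushing <- TRUE
        cur <- lonlat_to_km(pos[1], pos[2], origin)
        site <- lonlat_to_km(ho_lon[pw], ho_lat[pw], origin)
        if (pw != out_win) { # fix one outbound heading per bout
          out_win <- pw
          u0 <- drop(site)
          if (sqrt(sum(u0^2)) < 1) u0 <- stats::rnorm(2) # site at the origin
          th0 <- atan2(u0[2], u0[1]) + stats::runif(1, -0.6, 0.6)
          out_dir <- c(cos(th0), sin(th0)) # offshore of the island, jittered
        }
        u <- drop(cur - site)
        nu <- sqrt(sum(u^2))
        dir <- if (nu > 5) u / nu else out_dir
        d <- 0.6 * d + 0.4 * dir * 2.5 * dt_h
      }
    }
    nw <- next_win_after(t)
    steer_h <- 36
    if (nw > 0) {
      hrs_left <- as.numeric(difftime(ho_start[nw], t, units = "hours"))
      steps_left <- hrs_left / dt_h
      if (hrs_left <= steer_h && steps_left >= 1) {
        if (is.na(ho_lon[nw])) {
          site <- nearest_shore_cell(pos[1], pos[2])
          ho_lon[nw] <- site[1]; ho_lat[nw] <- site[2]
        }
        tgt <- lonlat_to_km(ho_lon[nw], ho_lat[nw], origin)
        cur <- lonlat_to_km(pos[1], pos[2], origin)
        v_req <- (tgt - cur) / steps_left
        wgt <- min(0.6, (steer_h - hrs_left) / steer_h * 0.6 + 0.05)
        d <- (1 - wgt) * d + wgt * v_req
      }
    }
    cur <- lonlat_to_km(pos[1], pos[2], origin)
    cand <- km_to_lonlat(cur[1] + d[1], cur[2] + d[2], origin)
    # keep inside the grid; avoid running aground outside haulout windows
    tries <- 0
    while (tries < 8) {
      off <- cand[1] < lim_lon[1] + margin || cand[1] > lim_lon[2] - margin ||
        cand[2] < lim_lat[1] + margin || cand[2] > lim_lat[2] - margin
      cd <- depth_at(bathy, cand[1], cand[2])
      aground <- !off && !is.na(cd) && cd < 8 && !pushing &&
        !(nw > 0 && as.numeric(difftime(ho_start[nw], t, units = "hours")) <= steer_h)
      if (!off && !aground) break
      d <- -0.5 * d + stats::rnorm(2, 0, sd_t) # turn back
      cand <- km_to_lonlat(cur[1] + d[1], cur[2] + d[2], origin)
      tries <- tries + 1
    }
    if (tries == 8) { # clamp into the grid as a last resort
      cand[1] <- min(max(cand[1], lim_lon[1] + margin), lim_lon[2] - margin)
      cand[2] <- min(max(cand[2], lim_lat[1] + margin), lim_lat[2] - margin)
    }
    pos <- c(cand[1], cand[2])
    lon[s] <- pos[1]; lat[s] <- pos[2]
    at_sea[s] <- TRUE
    d_prev <- d
  }

  km <- lonlat_to_km(lon, lat, origin)
  used <- ho_start <= t_end # windows the path actually reaches
  ho_start <- ho_start[used]; ho_end <- pmin(ho_end[used], t_end)
  ho_lon <- ho_lon[used]; ho_lat <- ho_lat[used]
  list(
    path = tibble::tibble(id = pup$id, time = times, lon = lon, lat = lat,
                          x_km = km[, 1], y_km = km[, 2],
                          gamma_true = gamma_true, at_sea = at_sea,
                          week = week),
    truth = list(beta = beta, sigma_b = sigma_b, b_i = b_i,
                 sigma_step = sigma_step, step_min = step_min,
                 haulout_schedule = tibble::tibble(start = ho_start,
                                                   end = ho_end,
                                                   lon = ho_lon, lat = ho_lat))
  )
}

#' Emulate a Fastloc GPS tag over a latent path
#'
#' Thins the latent path to an irregular fix stream: a location is attempted
#' every path step (15 min by default) and succeeds with probability
#' `p_surface`; fixes are suppressed inside haulout windows once the tag's
#' 20-minute dry-entry criterion is met, with the fixes at the window entry
#' carrying the tag haulout flag; each fix receives a satellite count and a
#' Fastloc residual draw; a small fraction of fixes are displaced into
#' position outliers large enough to exceed the QC speed threshold.
#'
#' @param sim a [simulate_track()] result.
#' @param p_surface per-attempt success probability (default 0.6; together
#'   with the 15-min attempt interval this reproduces inter-fix spacings with
#'   an upper quartile near 2 h).
#' @param n_sat_probs probabilities over satellite counts 4..11 (default puts
#'   mass 0.08 at 4, below the 5-satellite QC threshold).
#' @param residual_mean mean of the exponential residual draw (default 8;
#'   about 2% of draws exceed the QC threshold of 30).
#' @param outlier_rate fraction of fixes displaced into outliers.
#' @param outlier_speed_kmh apparent speed an injected outlier is guaranteed
#'   to exceed from the previous fix (default 12 > the 10 km/h QC threshold).
#' @param battery_life_days tag death time after first fix (must be > 0).
#' @param haulout_entry_min dry minutes before the tag enters the haulout
#'   state and suppresses fixes (default 20).
#' @param seed integer seed.
#' @return tibble of raw fixes: `id, time, lon, lat, n_sat, residual,
#'   tag_haulout`, plus truth-linkage columns `truth_outlier` and
#'   `truth_lowq` (low satellite count or high residual).
#' @export
emulate_tag <- function(sim, p_surface = 0.6,
                        n_sat_probs = c(0.08, 0.12, 0.16, 0.18, 0.16, 0.12,
                                        0.10, 0.08),
                        residual_mean = 8, outlier_rate = 0.01,
                        outlier_speed_kmh = 12,
                        battery_life_days = Inf, haulout_entry_min = 20,
                        seed = 1L) {
  if (battery_life_days <= 0) stop("battery_life_days must be > 0", call. = FALSE)
  stopifnot(length(n_sat_probs) == 8, abs(sum(n_sat_probs) - 1) < 1e-8)
  path <- sim$path
  sched <- sim$truth$haulout_schedule
  set.seed(seed)

  keep <- stats::runif(nrow(path)) < p_surface
  keep[1] <- TRUE
  tag_flag <- rep(FALSE, nrow(path))
  for (k in seq_len(nrow(sched))) {
    win_min <- as.numeric(difftime(sched$end[k], sched$start[k], units = "mins"))
    if (win_min <= haulout_entry_min) next
    entry <- sched$start[k] + haulout_entry_min * 60
    inside <- path$time >= sched$start[k] & path$time < sched$end[k]
    keep[inside & path$time > entry] <- FALSE
    tag_flag[inside & path$time <= entry] <- TRUE
  }
  fixes <- path[keep, c("id", "time", "lon", "lat")]
  fixes$tag_haulout <- tag_flag[keep]
  if (is.finite(battery_life_days)) {
    fixes <- fixes[fixes$time <= fixes$time[1] + battery_life_days * 86400, ]
  }
  m <- nrow(fixes)
  fixes$n_sat <- sample(4:11, m, replace = TRUE, prob = n_sat_probs)
  fixes$residual <- stats::rexp(m, rate = 1 / residual_mean)
  fixes$truth_outlier <- FALSE
  lowq <- fixes$n_sat < 5 | fixes$residual > 30
  if (outlier_rate > 0 && m > 2) {
    out_idx <- which(stats::runif(m) < outlier_rate)
    out_idx <- setdiff(out_idx, 1L)
    for (j in out_idx) {
      # displace far enough to exceed the speed threshold even from the last
      # fix the QC filters will have retained (skip low-quality neighbours)
      prev_good <- max(c(1L, which(!lowq[seq_len(j - 1)] &
                                     !fixes$truth_outlier[seq_len(j - 1)])))
      gap_h <- as.numeric(difftime(fixes$time[j], fixes$time[prev_good],
                                   units = "hours"))
      mag <- max(5, 1.5 * outlier_speed_kmh * gap_h)
      th <- stats::runif(1, 0, 2 * pi)
      ll <- km_to_lonlat(mag * cos(th), mag * sin(th),
                         origin = c(fixes$lon[j], fixes$lat[j]))
      fixes$lon[j] <- ll[1]; fixes$lat[j] <- ll[2]
      fixes$truth_outlier[j] <- TRUE
    }
  }
  fixes$truth_lowq <- fixes$n_sat < 5 | fixes$residual > 30
  tibble::as_tibble(fixes[, c("id", "time", "lon", "lat", "n_sat", "residual",
                              "tag_haulout", "truth_outlier", "truth_lowq")])
}

#' Simulate regular-step displacement data directly from the process model
#'
#' Draws per-animal displacement series exactly from the move-persistence
#' process (no haulouts, no shore steering): positions diffuse over the
#' bathymetry at a fixed time step, environmental covariates are read from the
#' grid at each destination, and `gamma` follows the logit-linear predictor
#' with a per-animal random intercept. This is the clean generative route used
#' for parameter-recovery studies of the fitted model.
#'
#' @param pups a [simulate_cohort()] tibble.
#' @param bathy a [make_bathymetry()] grid.
#' @param beta,sigma_b,sigma_step process parameters as in [simulate_track()];
#'   `sigma_step` is per axis at the model step (default 4 km at 6 h).
#' @param n_steps regular steps per animal.
#' @param delta_h model time step, hours.
#' @param seed integer seed.
#' @return list with `tracks` (tibble: id, track, time, lon, lat, x_km, y_km,
#'   depth_m, ln_depth, dist_shore_km, week, sex, mass, length, postwean,
#'   gamma_true) and `truth` (list with beta, sigma_b, b_i, sigma_step).
#' @export
simulate_model_data <- function(pups, bathy, beta = default_persistence_beta(),
                                sigma_b = 0.2, sigma_step = 4, n_steps = 260,
                                delta_h = 6, seed = 1L) {
  origin <- if (!is.null(bathy$island)) bathy$island$centre else
    c(mean(bathy$lon_axis), mean(bathy$lat_axis))
  shore_grid <- shore_distance_grid(bathy)
  set.seed(seed)
  b_i <- stats::rnorm(nrow(pups), 0, sigma_b)
  lim_lon <- range(bathy$lon_axis); lim_lat <- range(bathy$lat_axis)
  margin <- 2 * bathy$cell_size
  out <- vector("list", nrow(pups))
  for (a in seq_len(nrow(pups))) {
    pup <- pups[a, ]
    sexf <- as.numeric(pup$sex == "female")
    t0 <- pup$wean_date + pup$postwean_days * 86400
    times <- t0 + (seq_len(n_steps) - 1) * delta_h * 3600
    # start offshore of the island so early steps are in open water
    start <- km_to_lonlat(stats::runif(1, -60, 60), stats::runif(1, -80, -20),
                          origin)
    lon <- numeric(n_steps); lat <- numeric(n_steps); gam <- rep(NA_real_, n_steps)
    dep_used <- numeric(n_steps); dsh_used <- numeric(n_steps)
    lon[1] <- start[1]; lat[1] <- start[2]
    d_prev <- stats::rnorm(2, 0, sigma_step)
    pos <- c(lon[1], lat[1])
    dep_used[1] <- max(depth_at(bathy, pos[1], pos[2]), 1)
    dsh_used[1] <- shore_dist_at(bathy, shore_grid, pos[1], pos[2])
    for (s in 2:n_steps) {
      wk <- max(1L, as.integer(floor((s - 1) * delta_h / 24 / 7) + 1))
      dep <- depth_at(bathy, pos[1], pos[2]); dep <- if (is.na(dep)) 1200 else max(dep, 1)
      dsh <- shore_dist_at(bathy, shore_grid, pos[1], pos[2])
      if (is.na(dsh)) dsh <- 300
      dep_used[s] <- dep; dsh_used[s] <- dsh
      eta <- persistence_eta(beta, sexf, pup$mass_wean, pup$length_wean,
                             pup$postwean_days, wk, dsh, log(dep)) + b_i[a]
      g <- stats::plogis(eta)
      d <- g * d_prev + stats::rnorm(2, 0, sigma_step)
      cur <- lonlat_to_km(pos[1], pos[2], origin)
      cand <- km_to_lonlat(cur[1] + d[1], cur[2] + d[2], origin)
      # reflect at the grid boundary (position and step mirrored consistently)
      if (cand[1] < lim_lon[1] + margin || cand[1] > lim_lon[2] - margin) {
        d[1] <- -d[1]
        cand <- km_to_lonlat(cur[1] + d[1], cur[2] + d[2], origin)
      }
      if (cand[2] < lim_lat[1] + margin || cand[2] > lim_lat[2] - margin) {
        d[2] <- -d[2]
        cand <- km_to_lonlat(cur[1] + d[1], cur[2] + d[2], origin)
      }
      pos <- c(cand[1], cand[2])
      lon[s] <- pos[1]; lat[s] <- pos[2]
      gam[s] <- g
      d_prev <- d
    }
    # emit the covariate values that generated each step, so the recovery
    # oracle sees exactly the design the process used
    dep <- dep_used; dsh <- dsh_used
    km <- lonlat_to_km(lon, lat, origin)
    out[[a]] <- tibble::tibble(
      id = pup$id, track = 1L, time = times, lon = lon, lat = lat,
      x_km = km[, 1], y_km = km[, 2],
      depth_m = dep, ln_depth = log(dep), dist_shore_km = dsh,
      week = pmax(1L, as.integer(floor((seq_len(n_steps) - 1) * delta_h / 24 / 7) + 1)),
      sex = pup$sex, mass = pup$mass_wean, length = pup$length_wean,
      postwean = pup$postwean_days, gamma_true = gam
    )
  }
  list(tracks = dplyr::bind_rows(out),
       truth = list(beta = beta, sigma_b = sigma_b, b_i = b_i,
                    sigma_step = sigma_step))
}

#' Simulate a full tagging scenario
#'
#' Builds the synthetic shelf, draws a cohort, simulates each pup's latent
#' path and emulates its tag, returning everything downstream modules need.
#'
#' @param n_pups cohort size.
#' @param deployment_days at-sea tracking duration per pup (single value or
#'   vector recycled across pups; the study mean is ~83 d).
#' @param bathy optional prebuilt bathymetry (default [make_bathymetry()]).
#' @param beta,sigma_b generative persistence parameters.
#' @param step_min latent path step, minutes.
#' @param outlier_rate tag outlier rate.
#' @param seed master seed; per-pup seeds are derived from it.
#' @param ... further arguments passed to [simulate_cohort()].
#' @return list with `bathy`, `colony` ([colony_geometry()] on the synthetic
#'   island), `pups`, `fixes` (all animals' raw fixes), `paths` and `truths`
#'   (per-animal lists).
#' @export
simulate_scenario <- function(n_pups = 6, deployment_days = 40,
                              bathy = NULL, beta = default_persistence_beta(),
                              sigma_b = 0.2, step_min = 15,
                              outlier_rate = 0.01, seed = 1L, ...) {
  if (is.null(bathy)) bathy <- make_bathymetry(seed = seed)
  pups <- simulate_cohort(n_pups = n_pups, seed = seed, ...)
  shore_grid <- shore_distance_grid(bathy)
  set.seed(seed)
  sub <- sample.int(1e6, n_pups * 2)
  deployment_days <- rep_len(deployment_days, n_pups)
  paths <- vector("list", n_pups); truths <- paths; fixes <- paths
  for (a in seq_len(n_pups)) {
    sim <- simulate_track(pups[a, ], bathy, beta = beta, sigma_b = sigma_b,
                          step_min = step_min,
                          deployment_days = deployment_days[a],
                          seed = sub[a], shore_grid = shore_grid)
    paths[[a]] <- sim$path
    truths[[a]] <- sim$truth
    fixes[[a]] <- emulate_tag(sim, outlier_rate = outlier_rate,
                              seed = sub[n_pups + a])
  }
  names(paths) <- names(truths) <- pups$id
  list(bathy = bathy,
       colony = colony_geometry(centre = bathy$island$centre,
                                length_km = bathy$island$length_km),
       pups = pups, fixes = dplyr::bind_rows(fixes),
       paths = paths, truths = truths)
}
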