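#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow from one configuration: simulate (or
#' load) raw Fastloc fixes, quality-control them, classify haulouts and build
#' trips, regularize tracks and annotate covariates, fit the move-persistence
#' model candidates and the trip-characteristic models, and write a report
#' bundle (CSV/JSON) plus a manifest recording the configuration hash and
#' seed.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * either `scenario`: arguments for [simulate_scenario()] (e.g. `n_pups`,
#'     `deployment_days`, `seed`), or `inputs`: list with `fixes` (CSV path),
#'     `biometrics` (CSV path), `bathymetry` (ESRI ASCII path) — exactly one
#'     of the two;
#'   * optional `qc`: arguments for [qc_config()];
#'   * optional `delta_h` (default 6), `min_fixes` (default 50; small
#'     simulated scenarios may lower it), `mpmm_formulas` (character RHS
#'     formulas; default intercept-only vs all covariates);
#'   * `out_dir`: output directory.
#' @param resume skip stages whose outputs exist under an identical manifest
#'   hash (default FALSE).
#' @return invisibly, a list with the main results (`qc_report`, `trip_table`,
#'   `animal_summary`, `mpmm_ranking`, `trip_rankings`, `manifest`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_scen <- !is.null(config$scenario)
  has_inputs <- !is.null(config$inputs)
  if (has_scen == has_inputs) {
    stop("config must supply exactly one of 'scenario' or 'inputs'",
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, cfg_hash) &&
        all(file.exists(file.path(out_dir, unlist(old$outputs))))) {
      message("manifest hash unchanged; all outputs present - skipping rerun")
      return(invisible(readRDS(file.path(out_dir, "results.rds"))))
    }
  }
  log_stage <- function(...) message("[puptrack] ", ...)

  # ---- inputs -------------------------------------------------------------
  if (has_scen) {
    log_stage("simulating scenario")
    scen <- do.call(simulate_scenario, config$scenario)
    bathy <- scen$bathy; colony <- scen$colony
    fixes <- scen$fixes
    pups <- scen$pups
  } else {
    log_stage("loading inputs")
    fixes <- read_fixes_csv(config$inputs$fixes)
    pups <- read_biometrics_csv(config$inputs$biometrics)
    bathy <- read_esri_ascii(config$inputs$bathymetry)
    colony_cfg <- config$colony %||% list()
    colony <- do.call(colony_geometry, colony_cfg)
  }

  # ---- QC -----------------------------------------------------------------
  log_stage("quality control")
  qc <- filter_fixes(fixes, do.call(qc_config, config$qc %||% list()))
  utils::write.csv(drop_truth_cols(qc$kept),
                   file.path(out_dir, "fixes_filtered.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(qc$report),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- haulouts, trips ----------------------------------------------------
  log_stage("trip segmentation")
  shore_grid <- shore_distance_grid(bathy)
  per_animal <- list(); trip_rows <- list(); summ_rows <- list()
  for (a in unique(qc$kept$id)) {
    stream <- qc$kept[qc$kept$id == a, ]
    calls <- classify_haulout(stream, bathy, colony)
    ts <- trip_summaries(stream, calls, colony)
    pup <- pups[pups$id == a, ]
    depl <- as.numeric(difftime(max(stream$time), min(stream$time),
                                units = "days"))
    cov <- derive_animal_covariates(pup, ts$trips, depl)
    per_animal[[a]] <- list(stream = stream, calls = calls,
                            first_at_sea = ts$first_at_sea, pup = pup)
    trip_rows[[a]] <- ts$trips
    summ_rows[[a]] <- dplyr::bind_cols(
      tibble::tibble(id = a, sex = pup$sex,
                     mass = pup$mass_wean, length = pup$length_wean,
                     deployment_d = depl, n_fixes = nrow(stream)), cov[, -2])
  }
  trip_table <- dplyr::bind_rows(trip_rows)
  animal_summary <- dplyr::bind_rows(summ_rows)
  utils::write.csv(trip_table[, setdiff(names(trip_table), "fixes")],
                   file.path(out_dir, "trips.csv"), row.names = FALSE)
  utils::write.csv(animal_summary, file.path(out_dir, "animal_summary.csv"),
                   row.names = FALSE)

  # ---- regularization -----------------------------------------------------
  log_stage("track regularization")
  delta_h <- config$delta_h %||% 6
  min_fixes <- config$min_fixes %||% 50
  tracks <- dplyr::bind_rows(lapply(per_animal, function(s) {
    if (is.na(s$first_at_sea)) return(NULL)
    regularize_animal(s$stream, s$calls, bathy, s$pup, s$first_at_sea,
                      delta_h = delta_h, min_fixes = min_fixes,
                      shore_grid = shore_grid)
  }))
  utils::write.csv(tracks, file.path(out_dir, "tracks_regular.csv"),
                   row.names = FALSE)

  # ---- move persistence ---------------------------------------------------
  mpmm_ranking <- NULL; mpmm_fit_best <- NULL
  if (nrow(tracks) > 0) {
    log_stage("move-persistence model")
    md <- build_model_data(tracks)
    fml <- lapply(config$mpmm_formulas %||%
                    c("~ 1", paste("~", paste(md$covariates, collapse = " + "))),
                  stats::as.formula)
    mpmm_ranking <- model_select(md, fml)
    utils::write.csv(mpmm_ranking, file.path(out_dir, "mpmm_ranking.csv"),
                     row.names = FALSE)
    mpmm_fit_best <- attr(mpmm_ranking, "fits")[[mpmm_ranking$model[1]]]
    utils::write.csv(mpmm_fit_best$coefficients,
                     file.path(out_dir, "mpmm_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(mpmm_fit_best$gamma, file.path(out_dir, "gamma.csv"),
                     row.names = FALSE)
    utils::write.csv(osa_residuals(mpmm_fit_best),
                     file.path(out_dir, "osa_residuals.csv"), row.names = FALSE)
  }

  # ---- trip-characteristic models ----------------------------------------
  log_stage("trip-characteristic models")
  trip_rankings <- list()
  freq_tab <- animal_summary[animal_summary$n_trips_complete > 0 &
                               !is.na(animal_summary$mass), ]
  sets <- trip_candidate_sets()
  if (nrow(freq_tab) >= 8) {
    trip_rankings$frequency <- fit_candidate_set(freq_tab, sets$frequency)
  }
  complete <- trip_table[trip_table$complete, ]
  if (nrow(complete) >= 12) {
    tt <- dplyr::left_join(
      complete,
      animal_summary[, c("id", "sex", "mass", "length")], by = "id")
    tt$week <- tt$week_at_end
    tt$duration <- tt$duration_d
    tt$distance <- tt$distance_km
    tt <- tt[!is.na(tt$mass), ]
    for (nm in c("distance", "duration", "haulout")) {
      dat <- if (nm == "haulout") tt[!is.na(tt$haulout_duration_h), ] else tt
      if (length(unique(dat$id)) >= 3 && nrow(dat) >= 10) {
        trip_rankings[[nm]] <- try(fit_candidate_set(dat, sets[[nm]]),
                                   silent = TRUE)
      }
    }
  }
  for (nm in names(trip_rankings)) {
    if (!inherits(trip_rankings[[nm]], "try-error")) {
      utils::write.csv(trip_rankings[[nm]]$ranking,
                       file.path(out_dir, paste0("ranking_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  outputs <- list.files(out_dir)
  manifest <- list(package = "puptrack",
                   version = as.character(utils::packageVersion("puptrack")),
                   config_hash = cfg_hash, config = config,
                   created = format(Sys.time(), tz = "UTC"),
                   outputs = setdiff(outputs, c("manifest.json", "results.rds")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  res <- list(qc_report = qc$report, trip_table = trip_table,
              animal_summary = animal_summary, mpmm_ranking = mpmm_ranking,
              mpmm_fit = mpmm_fit_best, trip_rankings = trip_rankings,
              manifest = manifest)
  saveRDS(res, file.path(out_dir, "results.rds"))
  invisible(res)
}

drop_truth_cols <- function(d) d[, !grepl("^truth_", names(d)), drop = FALSE]

#' Read / write raw fix streams as CSV
#'
#' Column layout: `id, time (ISO-8601 UTC), lon, lat, n_sat, residual,
#' tag_haulout`.
#'
#' @param path CSV path.
#' @param fixes tibble of fixes.
#' @return `read_fixes_csv` returns a tibble with POSIXct times.
#' @export
read_fixes_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(id = "character"))
  d$time <- as.POSIXct(d$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%dT%H:%M:%S"))
  d$tag_haulout <- as.logical(d$tag_haulout)
  tibble::as_tibble(d)
}

#' @rdname read_fixes_csv
#' @export
write_fixes_csv <- function(fixes, path) {
  d <- drop_truth_cols(fixes)
  d$time <- format(d$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fixes_csv
#' @export
read_biometrics_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(id = "character"))
  d$wean_date <- as.POSIXct(d$wean_date, tz = "UTC")
  tibble::as_tibble(d)
}
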