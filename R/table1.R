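#' Published per-animal deployment summary of the study cohort
#'
#' The deployment summary table for the 23 pups whose tags transmitted (out of
#' 25 instrumented): sex (1 = male, 2 = female), weaning body mass (kg) and
#' length (cm), post-weaning duration (d), deployment duration (d), numbers of
#' Fastloc and Argos locations, and the number of complete trips. One female
#' lacks mass and post-weaning duration (biometrics missing). This table is
#' the input for the descriptive statistics and the trip-frequency analysis.
#'
#' @return tibble with columns `id`, `sex_code`, `sex` ("male"/"female"),
#'   `mass_kg`, `length_cm`, `postwean_d`, `deployment_d`, `n_fastloc`,
#'   `n_argos`, `n_trips`.
#' @export
sable_pups <- function() {
  path <- system.file("extdata", "sable_pups_table1.csv", package = "puptrack")
  d <- utils::read.csv(path, colClasses = c(id = "character"))
  d$sex <- factor(ifelse(d$sex_code == 1, "male", "female"),
                  levels = c("male", "female"))
  tibble::as_tibble(d[, c("id", "sex_code", "sex", "mass_kg", "length_cm",
                          "postwean_d", "deployment_d", "n_fastloc",
                          "n_argos", "n_trips")])
}

#' Per-animal trip-frequency table from the deployment summary
#'
#' One row per pup that made at least one complete trip and has complete
#' biometrics: trip frequency = complete trips / deployment days.
#'
#' @return tibble: `id`, `sex`, `mass`, `length`, `trip_frequency`.
#' @export
sable_trip_frequency <- function() {
  d <- sable_pups()
  d <- d[d$n_trips > 0 & !is.na(d$mass_kg), ]
  tibble::tibble(id = d$id, sex = d$sex, mass = d$mass_kg,
                 length = d$length_cm,
                 trip_frequency = d$n_trips / d$deployment_d)
}
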