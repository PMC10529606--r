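#' Simulate a cohort of newly weaned pups
#'
#' Draws per-animal biometrics for a synthetic cohort: weaning mass (kg) and
#' standard length (cm) from a bivariate normal with configurable correlation,
#' and post-weaning duration (days between weaning and first departure) from a
#' normal truncated below at 1 d. Defaults emulate the study colony's 2016
#' cohort (mass ~ 55 +/- 5.5 kg, length ~ 112 +/- 3 cm, mass-length
#' correlation 0.55, post-weaning fast ~ 21 +/- 6 d).
#'
#' @param n_pups number of pups (>= 1).
#' @param sex_ratio probability a pup is male.
#' @param mass_mean,mass_sd weaning mass distribution, kg.
#' @param length_mean,length_sd weaning length distribution, cm.
#' @param mass_length_cor correlation between mass and length, in (-1, 1).
#' @param postwean_mean,postwean_sd post-weaning duration distribution, days.
#' @param wean_date date of weaning (single Date or POSIXct midnight UTC).
#' @param release_site lon/lat where animals start (defaults to the island
#'   centre of [make_bathymetry()]).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return tibble with columns `id`, `sex` ("male"/"female"), `mass_wean`,
#'   `length_wean`, `wean_date`, `postwean_days`, `release_lon`, `release_lat`.
#' @export
simulate_cohort <- function(n_pups = 22, sex_ratio = 0.5,
                            mass_mean = 55, mass_sd = 5.5,
                            length_mean = 112, length_sd = 3,
                            mass_length_cor = 0.55,
                            postwean_mean = 21, postwean_sd = 6,
                            wean_date = as.Date("2016-01-20"),
                            release_site = c(-59.91, 43.93),
                            seed = 1L) {
  stopifnot(n_pups >= 1)
  if (abs(mass_length_cor) >= 1) {
    stop("mass_length_cor must lie in (-1, 1)", call. = FALSE)
  }
  set.seed(seed)
  sigma <- matrix(c(mass_sd^2,
                    mass_length_cor * mass_sd * length_sd,
                    mass_length_cor * mass_sd * length_sd,
                    length_sd^2), 2, 2)
  bm <- MASS::mvrnorm(n_pups, mu = c(mass_mean, length_mean), Sigma = sigma)
  bm <- matrix(bm, ncol = 2)
  pw <- stats::rnorm(n_pups, postwean_mean, postwean_sd)
  while (any(pw < 1)) { # truncated-below redraw
    pw[pw < 1] <- stats::rnorm(sum(pw < 1), postwean_mean, postwean_sd)
    if (postwean_sd == 0) { pw <- pmax(pw, 1); break }
  }
  tibble::tibble(
    id = sprintf("sim%03d", seq_len(n_pups)),
    sex = ifelse(stats::runif(n_pups) < sex_ratio, "male", "female"),
    mass_wean = pmax(bm[, 1], 25),
    length_wean = pmax(bm[, 2], 80),
    wean_date = as.POSIXct(as.character(wean_date), tz = "UTC"),
    postwean_days = round(pw, 1),
    release_lon = release_site[1],
    release_lat = release_site[2]
  )
}
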