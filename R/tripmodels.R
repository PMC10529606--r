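#' Fit a trip-characteristic linear (mixed) model
#'
#' Gaussian models of trip characteristics fitted by maximum likelihood: a
#' plain linear model when `random_intercept = FALSE` (trip frequency, one row
#' per animal), or a linear mixed model with a per-animal random intercept via
#' lme4 (trip distance, duration and haulout duration, one row per trip).
#' Responses may be ln-transformed. Marginal and conditional R-squared follow
#' the variance-partition formulas
#' `R2m = var_fixed / (var_fixed + var_re + var_res)` and
#' `R2c = (var_fixed + var_re) / (var_fixed + var_re + var_res)`.
#'
#' @param data trip table (complete trips only; animals with missing
#'   biometrics removed by the caller).
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (may include
#'   interactions like `"sex:week"`); empty for the intercept-only model.
#' @param random_intercept add `(1 | id)`.
#' @param ln_transform ln-transform the response (requires positive values).
#' @param id_col grouping column for the random intercept.
#' @return object of class `trip_fit`: `coefficients` tibble (term, estimate,
#'   se, t), `logLik` (ML), `k`, `n`, `AICc`, `sigma_re`, `sigma_res`, `R2m`,
#'   `R2c`, `singular` flag, `model` (the lm/lmerMod object), `fixed`,
#'   `response`.
#' @export
fit_trip_model <- function(data, response, fixed = character(),
                           random_intercept = TRUE, ln_transform = FALSE,
                           id_col = "id") {
  stopifnot(response %in% names(data))
  y <- data[[response]]
  if (ln_transform) {
    bad <- which(!is.na(y) & y <= 0)
    if (length(bad)) {
      stop("ln-transform of '", response, "' undefined for rows: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  d <- as.data.frame(data)
  d$.y <- if (ln_transform) log(y) else y
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (random_intercept) {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 |", id_col, ")"))
    fit <- lme4::lmer(fml, data = d, REML = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_re <- sqrt(vc$vcov[vc$grp == id_col])
    sigma_res <- stats::sigma(fit)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    X <- stats::model.matrix(fit)
    singular <- lme4::isSingular(fit)
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    n <- stats::nobs(fit)
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- stats::lm(fml, data = d)
    sigma_re <- 0
    sigma_res <- sqrt(sum(stats::residuals(fit)^2) / stats::nobs(fit)) # ML
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    X <- stats::model.matrix(fit)
    singular <- FALSE
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    n <- stats::nobs(fit)
  }
  var_fixed <- stats::var(drop(X %*% beta))
  denom <- var_fixed + sigma_re^2 + sigma_res^2
  structure(list(
    coefficients = tibble::tibble(term = names(beta), estimate = unname(beta),
                                  se = unname(se), t = unname(beta / se)),
    logLik = ll, k = k, n = n, AICc = aicc(ll, k, n),
    sigma_re = if (length(sigma_re)) sigma_re else 0, sigma_res = sigma_res,
    R2m = var_fixed / denom, R2c = (var_fixed + sigma_re^2) / denom,
    singular = singular, model = fit, fixed = fixed, response = response,
    ln_transform = ln_transform, random_intercept = random_intercept
  ), class = "trip_fit")
}

#' @export
print.trip_fit <- function(x, digits = 4, ...) {
  cat("Trip model: ", if (x$ln_transform) "ln " else "", x$response, " ~ ",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
      if (x$random_intercept) " + (1 | id)", "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat("logLik =", round(x$logLik, 2), " df =", x$k, " AICc =",
      round(x$AICc, 2), " R2m =", round(x$R2m, 2), " R2c =", round(x$R2c, 2),
      if (x$singular) " [singular]", "\n")
  invisible(x)
}

#' Rank trip models by AICc and confirm by likelihood ratio
#'
#' Produces the AICc ranking (df, LL, AICc, dAICc, Akaike weight) of a
#' candidate set fitted on identical rows, and, when requested, a likelihood
#' ratio test between two nested candidates: `X2 = 2 (LL_big - LL_small)` on
#' `df = k_big - k_small` degrees of freedom.
#'
#' @param fits named list of `trip_fit` objects.
#' @param lr optional length-2 character vector `c(small, big)` naming nested
#'   fits to compare (defaults to lowest-AICc vs highest-LL model).
#' @return list with `ranking` tibble and `lr_test` (tibble: chisq, df, p), or
#'   `lr_test = NULL` when the two models coincide... see Details.
#' @export
rank_and_test <- function(fits, lr = NULL) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) {
      paste("~", if (length(f$fixed)) paste(f$fixed, collapse = " + ") else "1")
    }, character(1))
  }
  if (length(unique(vapply(fits, function(f) f$n, numeric(1)))) != 1) {
    stop("candidates were not fitted on identical rows", call. = FALSE)
  }
  tab <- tibble::tibble(
    model = names(fits),
    df = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1))
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]

  if (is.null(lr)) {
    best <- tab$model[1]
    highest_ll <- tab$model[which.max(tab$logLik)]
    lr <- c(best, highest_ll)
  }
  small <- fits[[lr[1]]]; big <- fits[[lr[2]]]
  if (big$logLik < small$logLik) { tmp <- small; small <- big; big <- tmp }
  if (!all(small$fixed %in% big$fixed)) {
    stop("likelihood-ratio test requires nested models", call. = FALSE)
  }
  chisq <- max(0, 2 * (big$logLik - small$logLik))
  df <- as.numeric(big$k - small$k)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  list(ranking = tab,
       lr_test = tibble::tibble(small = if (identical(small, big)) lr[1] else
         paste("~", if (length(small$fixed)) paste(small$fixed, collapse = " + ") else "1"),
         chisq = chisq, df = df, p = p))
}

#' Descriptive statistics used in the study's results
#'
#' Per-group mean, sample sd, standard error and coefficient of variation;
#' Pearson correlation with its t-based p-value; Welch two-sample t-test.
#'
#' @param x numeric vector.
#' @param by optional grouping vector for `describe_stats`.
#' @return `describe_stats`: tibble with group, n, mean, sd, se, cv_pct;
#'   `pearson_test`: tibble with r, p; `welch_test`: tibble with estimate
#'   difference, t, df, p.
#' @export
describe_stats <- function(x, by = NULL) {
  if (is.null(by)) by <- rep("all", length(x))
  g <- split(x, by)
  dplyr::bind_rows(lapply(names(g), function(nm) {
    v <- g[[nm]][!is.na(g[[nm]])]
    n <- length(v)
    if (n < 2) {
      warning("group '", nm, "' has n < 2; sd undefined")
      return(tibble::tibble(group = nm, n = n, mean = mean(v), sd = NA_real_,
                            se = NA_real_, cv_pct = NA_real_))
    }
    tibble::tibble(group = nm, n = n, mean = mean(v), sd = stats::sd(v),
                   se = stats::sd(v) / sqrt(n),
                   cv_pct = if (mean(v) != 0) stats::sd(v) / mean(v) * 100 else 0)
  }))
}

#' @rdname describe_stats
#' @param y second numeric vector for correlation / second sample.
#' @export
pearson_test <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' @rdname describe_stats
#' @export
welch_test <- function(x, y) {
  tt <- stats::t.test(x, y)
  tibble::tibble(diff = unname(tt$estimate[1] - tt$estimate[2]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Printed candidate model sets for the four trip characteristics
#'
#' The exact fixed-effect candidate lists used in the study's ranking tables:
#' trip frequency (plain linear models at one row per animal) and trip
#' distance, trip duration and haulout duration (animal random-intercept
#' models at one row per trip, ln-transformed responses).
#'
#' @return named list of lists with elements `response`, `ln_transform`,
#'   `random_intercept`, and `candidates` (list of character vectors of fixed
#'   terms).
#' @export
trip_candidate_sets <- function() {
  list(
    frequency = list(
      response = "trip_frequency", ln_transform = FALSE,
      random_intercept = FALSE,
      candidates = list(c("sex", "mass"), "sex", c("sex", "mass", "length"),
                        character())
    ),
    distance = list(
      response = "distance_km", ln_transform = TRUE, random_intercept = TRUE,
      candidates = list(c("sex", "week"), "week", c("sex", "length", "week"),
                        c("sex", "mass", "length", "week"),
                        c("sex", "mass", "length", "week", "sex:week"),
                        character())
    ),
    duration = list(
      response = "duration_d", ln_transform = TRUE, random_intercept = TRUE,
      candidates = list(c("sex", "week"), c("sex", "mass", "week"), "week",
                        c("sex", "mass", "length", "week"),
                        c("sex", "mass", "length", "week", "sex:week"),
                        character())
    ),
    haulout = list(
      response = "haulout_duration_h", ln_transform = TRUE,
      random_intercept = TRUE,
      candidates = list("mass", c("mass", "week"), character(),
                        c("mass", "duration", "week"),
                        c("mass", "length", "duration", "week"),
                        c("sex", "mass", "length", "duration", "week"),
                        c("sex", "mass", "length", "duration", "distance", "week"),
                        c("sex", "mass", "length", "duration", "distance",
                          "week", "sex:duration"),
                        c("sex", "mass", "length", "duration", "distance",
                          "week", "sex:duration", "sex:distance"),
                        c("sex", "mass", "length", "duration", "distance",
                          "week", "sex:duration", "sex:distance", "sex:week"))
    )
  )
}

#' Simulate a trip table from a known linear mixed model
#'
#' Draws per-trip responses directly from the Gaussian animal-random-intercept
#' model used for trip characteristics, for parameter-recovery testing:
#' `y_ij = beta0 + beta_sex female_i + beta_mass mass_i + beta_week week_ij +
#' u_i + e_ij` with `u_i ~ N(0, sigma_re^2)`, `e_ij ~ N(0, sigma_res^2)`.
#' The response is emitted on the natural scale (`exp(y)`) so that fitting
#' with `ln_transform = TRUE` targets the generating coefficients.
#'
#' @param n_animals number of animals.
#' @param trips_per_animal trips per animal (recycled).
#' @param beta named vector with any of `intercept`, `sex`, `mass`, `week`.
#' @param sigma_re,sigma_res random-intercept and residual sds (ln scale).
#' @param seed integer seed.
#' @return tibble: `id`, `sex`, `mass`, `length`, `week`, `response`
#'   (natural scale), `y_ln` (the latent ln-scale draw).
#' @export
simulate_trip_table <- function(n_animals = 18, trips_per_animal = 4,
                                beta = c(intercept = 5, sex = -0.6,
                                         mass = 0, week = 0.1),
                                sigma_re = 0.3, sigma_res = 0.8, seed = 1L) {
  set.seed(seed)
  get <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  tpa <- rep_len(trips_per_animal, n_animals)
  u <- stats::rnorm(n_animals, 0, sigma_re)
  sex <- rep(c("male", "female"), length.out = n_animals)
  mass <- stats::rnorm(n_animals, 55, 5.5)
  len <- stats::rnorm(n_animals, 112, 3)
  rows <- lapply(seq_len(n_animals), function(i) {
    wk <- sort(sample.int(12, tpa[i], replace = TRUE))
    y <- get("intercept") + get("sex") * (sex[i] == "female") +
      get("mass") * mass[i] + get("week") * wk + u[i] +
      stats::rnorm(tpa[i], 0, sigma_res)
    tibble::tibble(id = sprintf("a%02d", i),
                   sex = factor(sex[i], levels = c("male", "female")),
                   mass = mass[i], length = len[i], week = wk,
                   response = exp(y), y_ln = y)
  })
  dplyr::bind_rows(rows)
}

#' Fit a full candidate set for one trip characteristic
#'
#' @param data trip (or per-animal) table.
#' @param set one element of [trip_candidate_sets()].
#' @return output of [rank_and_test()] with the fits attached as `fits`.
#' @export
fit_candidate_set <- function(data, set) {
  fits <- lapply(set$candidates, function(fx) {
    fit_trip_model(data, set$response, fixed = fx,
                   random_intercept = set$random_intercept,
                   ln_transform = set$ln_transform)
  })
  names(fits) <- vapply(set$candidates, function(fx) {
    paste("~", if (length(fx)) paste(fx, collapse = " + ") else "1")
  }, character(1))
  out <- rank_and_test(fits)
  out$fits <- fits
  out
}
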