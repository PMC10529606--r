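# shared fixtures, built once per test run

t_origin <- as.POSIXct("2016-02-01 00:00:00", tz = "UTC")
hrs <- function(x) t_origin + x * 3600

# hand-built grid with exactly known cell values (rows = lon, cols = lat)
toy_bathy <- function() {
  lon_axis <- seq(-60.5, -59.6, by = 0.1)  # 10 cells
  lat_axis <- seq(43.5, 44.4, by = 0.1)    # 10 cells
  elev <- matrix(-80, 10, 10)
  elev[5, 5] <- 1.9     # island cell at (-60.1, 43.9)
  elev[6, 5] <- -5      # exactly 5 m deep
  elev[7, 5] <- -143.7  # the mean pup water depth
  structure(list(lon_axis = lon_axis, lat_axis = lat_axis, elevation = elev,
                 cell_size = 0.1, island = NULL), class = "bathy_grid")
}

fix_stream <- function(t_h, lon, lat, n_sat = 9, residual = 5,
                       id = "a1", tag_haulout = FALSE) {
  tibble::tibble(id = id, time = hrs(t_h), lon = lon, lat = lat,
                 n_sat = rep_len(n_sat, length(t_h)),
                 residual = rep_len(residual, length(t_h)),
                 tag_haulout = rep_len(tag_haulout, length(t_h)))
}

# session-cached expensive objects
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_bathy <- function() cached("default_bathy", make_bathymetry)

# wide shelf used for process-model recovery (tracks rarely reach the edge)
wide_bathy <- function() {
  cached("wide_bathy", function() {
    make_bathymetry(lon_range = c(-64.5, -55), lat_range = c(41, 47))
  })
}

small_scenario <- function() {
  cached("small_scenario", function() {
    simulate_scenario(n_pups = 3, deployment_days = 25, seed = 402)
  })
}

# one medium-scale recovery experiment shared across test files:
# cohort generated at the study's fitted coefficient magnitudes
recovery_experiment <- function() {
  cached("recovery_experiment", function() {
    pups <- simulate_cohort(n_pups = 12, seed = 101)
    smd <- simulate_model_data(pups, wide_bathy(), n_steps = 150, seed = 102)
    md <- build_model_data(smd$tracks)
    list(md = md, truth = smd$truth, fit = fit_mpmm(md))
  })
}

# independent adaptive Gauss-Hermite oracle for the marginal log-likelihood:
# per animal, mode and curvature found numerically, then `nodes`-point GHQ on
# the rescaled integrand (never calls the package's Laplace code)
ghq_loglik <- function(md, beta, sb, sx, sy, formula, nodes = 21) {
  X <- stats::model.matrix(formula, md$steps)
  gh <- pracma::gaussHermite(nodes)
  ll <- 0
  for (a in levels(md$steps$id)) {
    sel <- md$steps$id == a
    s <- md$steps[sel, ]
    eta0 <- drop(X[sel, , drop = FALSE] %*% beta)
    f <- function(bb) {
      g <- stats::plogis(eta0 + bb)
      sum(stats::dnorm(s$dx - g * s$dpx, 0, sx, log = TRUE) +
            stats::dnorm(s$dy - g * s$dpy, 0, sy, log = TRUE)) +
        stats::dnorm(bb, 0, sb, log = TRUE)
    }
    op <- stats::optimize(f, c(-4, 4), maximum = TRUE, tol = 1e-12)
    h <- -(f(op$maximum + 1e-4) - 2 * f(op$maximum) +
             f(op$maximum - 1e-4)) / 1e-8
    shat <- 1 / sqrt(h)
    vals <- vapply(gh$x, function(x) f(op$maximum + sqrt(2) * shat * x) + x^2,
                   numeric(1))
    M <- max(vals)
    ll <- ll + log(sum(gh$w * exp(vals - M))) + M + log(sqrt(2) * shat)
  }
  ll
}

# conditional log-likelihood of the persistence process at fixed b
cond_loglik <- function(md, X, beta, b, sx, sy) {
  g <- stats::plogis(drop(X %*% beta) + b)
  sum(stats::dnorm(md$steps$dx - g * md$steps$dpx, 0, sx, log = TRUE) +
        stats::dnorm(md$steps$dy - g * md$steps$dpy, 0, sy, log = TRUE))
}
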