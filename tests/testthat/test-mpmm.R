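test_that("model data assembly yields the documented step bookkeeping", {
  # one track of 51 regular points -> 50 displacements, 49 usable steps
  tr <- tibble::tibble(id = "a1", track = 1L,
                       time = hrs(6 * (0:50)),
                       lon = -60 + cumsum(rnorm(51, 0, 0.05)),
                       lat = 44 + cumsum(rnorm(51, 0, 0.05)))
  md <- build_model_data(tr)
  expect_equal(nrow(md$steps), 49)
  # two animals -> two factor levels
  tr2 <- dplyr::bind_rows(tr, dplyr::mutate(tr, id = "a2"))
  expect_equal(build_model_data(tr2)$n_animals, 2)
  # displacements recompute from positions: dx of step t is p_t - p_{t-1}
  one <- build_model_data(tr)$steps
  org <- c(mean(tr$lon), mean(tr$lat))
  km <- lonlat_to_km(tr$lon, tr$lat, org)
  expect_equal(one$dx, diff(km[, 1])[2:50], tolerance = 1e-9)
  expect_equal(one$dpx, diff(km[, 1])[1:49], tolerance = 1e-9)
})

test_that("animals with missing biometrics are excluded from model data", {
  pups <- simulate_cohort(n_pups = 3, seed = 14)
  smd <- simulate_model_data(pups, wide_bathy(), n_steps = 10, seed = 15)
  trk <- smd$tracks
  trk$mass[trk$id == pups$id[2]] <- NA
  expect_message(md <- build_model_data(trk), "missing")
  expect_equal(md$n_animals, 2)
})

test_that("the Laplace marginal likelihood matches quadrature and its degenerate limit", {
  pups <- simulate_cohort(n_pups = 2, seed = 2)
  smd <- simulate_model_data(pups, wide_bathy(), n_steps = 30, seed = 3)
  md <- build_model_data(smd$tracks)
  beta <- c(1.2, -0.02); fml <- ~ week
  sx <- 3.8; sy <- 4.1
  # agreement tightens as the random-effect scale shrinks (the approximation
  # error is higher order in sigma_b); the tolerance is for moderate scales
  for (sb in c(0.05, 0.10, 0.15)) {
    nl <- nll_mpmm(md, beta, log(sb), c(log(sx), log(sy)), fml)
    ll <- ghq_loglik(md, beta, sb, sx, sy, fml)
    expect_lt(abs(-nl - ll), 1e-3)
  }
  nl25 <- nll_mpmm(md, beta, log(0.25), c(log(sx), log(sy)), fml)
  expect_lt(abs(-nl25 - ghq_loglik(md, beta, 0.25, sx, sy, fml)), 5e-3)

  # sigma_b -> 0: marginal equals the conditional likelihood at b = 0
  X <- stats::model.matrix(fml, md$steps)
  nl0 <- nll_mpmm(md, beta, log(1e-12), c(log(sx), log(sy)), fml)
  cond <- cond_loglik(md, X, beta, 0, sx, sy)
  expect_lt(abs(nl0 + cond), 1e-6)
  expect_error(nll_mpmm(md, c(NA, 0), log(0.3), c(log(sx), log(sy)), fml),
               "non-finite")
})

test_that("the likelihood is locally optimal near the generating parameters", {
  pups <- simulate_cohort(n_pups = 8, seed = 23)
  smd <- simulate_model_data(pups, wide_bathy(),
                             beta = c(intercept = 1.5, week = -0.05),
                             sigma_b = 0.2, sigma_step = 4,
                             n_steps = 200, seed = 24)
  md <- build_model_data(smd$tracks)
  fml <- ~ week
  at_truth <- nll_mpmm(md, c(1.5, -0.05), log(0.2), c(log(4), log(4)), fml)
  set.seed(25)
  worse <- 0
  n_pert <- 40
  for (r in seq_len(n_pert)) {
    fac <- 1 + sample(c(-0.1, 0.1), 5, replace = TRUE)
    nl <- nll_mpmm(md, c(1.5, -0.05) * fac[1:2], log(0.2 * fac[3]),
                   log(c(4, 4) * fac[4:5]), fml)
    if (nl >= at_truth) worse <- worse + 1
  }
  expect_gte(worse / n_pert, 0.85)
})

test_that("degenerate movement fixtures pin gamma at its limits", {
  # near-straight constant-velocity path -> gamma above 0.99 everywhere
  n <- 120
  set.seed(31)
  km_x <- 5 * (0:(n - 1)) + rnorm(n, 0, 0.01)
  km_y <- 2 * (0:(n - 1)) + rnorm(n, 0, 0.01)
  ll <- km_to_lonlat(km_x, km_y, origin = c(-60, 44))
  tr <- tibble::tibble(id = "a1", track = 1L, time = hrs(6 * (0:(n - 1))),
                       lon = ll[, 1], lat = ll[, 2])
  fit <- fit_mpmm(build_model_data(tr), ~ 1)
  expect_true(all(fit$gamma$gamma > 0.99))
  expect_gt(fit$coefficients$estimate[1], 4)

  # white-noise displacements -> mean gamma below 0.1
  set.seed(32)
  wn <- km_to_lonlat(cumsum(rnorm(200, 0, 4)), cumsum(rnorm(200, 0, 4)),
                     origin = c(-60, 44))
  tr2 <- tibble::tibble(id = c(rep("a1", 100), rep("a2", 100)),
                        track = 1L, time = rep(hrs(6 * (0:99)), 2),
                        lon = wn[, 1], lat = wn[, 2])
  fit2 <- fit_mpmm(build_model_data(tr2), ~ 1)
  expect_lt(mean(fit2$gamma$gamma), 0.1)
})

test_that("fitting recovers generating parameters at realistic effect sizes", {
  exp_ <- recovery_experiment()
  md <- exp_$md
  fit <- exp_$fit
  expect_equal(fit$convergence, 0)
  truth <- default_persistence_beta()
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
  nm <- c("(Intercept)", "sexfemale", "mass", "length", "postwean", "week",
          "dist_shore", "ln_depth")
  tr <- unname(truth)
  sign_ok <- sum(sign(tr) == sign(est[nm]))
  in_ci <- sum(tr >= est[nm] - 1.96 * se[nm] & tr <= est[nm] + 1.96 * se[nm])
  expect_gte(sign_ok, 6)
  expect_gte(in_ci, 5)
  # the strong environmental effects keep their signs individually
  expect_gt(est["ln_depth"], 0)
  expect_lt(est["dist_shore"], 0)
  expect_lt(est["length"], 0)
  # variance components land near truth
  expect_lt(abs(fit$sigma_b - 0.2), 0.15)
  expect_lt(max(abs(fit$sigma_step - 4)) / 4, 0.15)
  # gamma identity: plogis(X beta + b) elementwise
  X <- stats::model.matrix(fit$formula, md$steps)
  g2 <- stats::plogis(drop(X %*% est) + fit$b[as.character(md$steps$id)])
  expect_equal(fit$gamma$gamma, g2, tolerance = 1e-10)
  expect_true(all(fit$gamma$gamma > 0 & fit$gamma$gamma < 1))
})

test_that("behavioural classification uses strict thresholds and counts correctly", {
  g <- c(0.71, 0.70, 0.30, 0.29, 0.5)
  cl <- classify_gamma(g)
  expect_equal(cl$labels,
               c("directed_travel", "intermediate", "intermediate",
                 "area_restricted_search", "intermediate"))
  set.seed(41)
  gv <- runif(500)
  cl2 <- classify_gamma(gv)
  expect_equal(unname(cl2$counts["directed_travel"]), sum(gv > 0.70))
  expect_equal(unname(cl2$counts["area_restricted_search"]), sum(gv < 0.30))
  expect_equal(sum(cl2$counts), 500)
})

test_that("one-step-ahead residuals are white under the true model and not under gamma = 0", {
  pups <- simulate_cohort(n_pups = 6, seed = 51)
  smd <- simulate_model_data(pups, wide_bathy(),
                             beta = c(intercept = 1.5), sigma_b = 0.1,
                             sigma_step = 4, n_steps = 150, seed = 52)
  md <- build_model_data(smd$tracks)
  fit <- fit_mpmm(md, ~ 1)
  res <- osa_residuals(fit)
  n <- nrow(res)
  a1 <- function(v) stats::acf(v, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(a1(res$resid_x)), 2.5 / sqrt(n))
  expect_lt(abs(a1(res$resid_y)), 2.5 / sqrt(n))
  expect_lt(abs(mean(res$resid_x)), 3 / sqrt(n))
  expect_lt(abs(mean(res$resid_y)), 3 / sqrt(n))
  # misspecification: forcing gamma = 0 leaves the persistence in the residuals
  raw_x <- md$steps$dx / sd(md$steps$dx)
  expect_gt(a1(raw_x), 0.3)
})

test_that("model selection reports coherent AICc, weights and limits", {
  pups <- simulate_cohort(n_pups = 5, seed = 61)
  smd <- simulate_model_data(pups, wide_bathy(), n_steps = 80, seed = 62)
  md <- build_model_data(smd$tracks)
  tab <- model_select(md, list(~ 1, ~ ln_depth, ~ week + ln_depth))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$dAICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$AICc[i], aicc(tab$logLik[i], tab$df[i], nrow(md$steps)),
                 tolerance = 1e-9)
  }
  # AICc -> AIC as n grows
  expect_equal(aicc(-100, 5, 1e9), -2 * (-100) + 2 * 5, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), "undefined")
})

test_that("variance inflation factors match their closed forms", {
  n <- 400
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  # exactly orthogonal pair via residualization
  x1 <- z1
  x2 <- residuals(lm(z2 ~ z1))
  md0 <- structure(list(steps = tibble::tibble(a = x1, b = x2),
                        covariates = c("a", "b"), n_animals = 1),
                   class = "mpmm_data")
  expect_equal(unname(vif_covariates(md0, c("a", "b"))), c(1, 1),
               tolerance = 1e-10)
  # known correlation 0.6 -> VIF = 1/(1 - 0.36) = 1.5625
  u <- x2 / sd(x2)
  v <- 0.6 * (x1 - mean(x1)) / sd(x1) + sqrt(1 - 0.36) * (u - mean(u)) / sd(u)
  md1 <- structure(list(steps = tibble::tibble(a = x1, b = v),
                        covariates = c("a", "b"), n_animals = 1),
                   class = "mpmm_data")
  expect_equal(unname(vif_covariates(md1, c("a", "b"))),
               rep(1 / (1 - cor(x1, v)^2), 2), tolerance = 1e-8)
  # duplicated covariate is flagged infinite
  md2 <- structure(list(steps = tibble::tibble(a = x1, b = x1, c = z3),
                        covariates = c("a", "b", "c"), n_animals = 1),
                   class = "mpmm_data")
  expect_warning(vifs <- vif_covariates(md2, c("a", "b", "c")), "collinear")
  expect_true(is.infinite(vifs[["a"]]))
})

test_that("leave-one-out refits are stable under an homogeneous cohort", {
  pups <- simulate_cohort(n_pups = 8, seed = 11)
  smd <- simulate_model_data(pups, wide_bathy(), sigma_b = 0,
                             n_steps = 100, seed = 12)
  md <- build_model_data(smd$tracks)
  cv <- loo_cv(md, ~ week + ln_depth)
  expect_equal(cv$n_refits, 8)
  expect_true(all(cv$summary$est_trend_pct >= 85))
  # quantile band brackets the full-model estimate for the stable terms
  full <- cv$full_fit$coefficients
  expect_true(all(cv$summary$q5 <= full$estimate + 1e-9 |
                    cv$summary$q95 >= full$estimate - 1e-9))
  expect_error(loo_cv(subset_model_data(md, levels(md$steps$id)[1:2])),
               "3 animals")
})
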