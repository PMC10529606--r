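#' Assemble move-persistence model data from regularized tracks
#'
#' Computes per-track planar displacements and aligns them with covariates.
#' Within each track, positions are projected to km on an equirectangular
#' plane about the track centroid; displacements `d_t = p_t - p_{t-1}` exist
#' from the second location, and likelihood-contributing steps (which need the
#' predecessor displacement) from the third. Covariates are taken at each
#' step's destination time. Animals with missing biometrics are excluded with
#' a message.
#'
#' @param tracks tibble of annotated regular locations (from
#'   [regularize_animal()]-style output or [simulate_model_data()]): columns
#'   `id`, `track`, `time`, `lon`, `lat`, plus any of `sex`, `mass`, `length`,
#'   `postwean`, `week`, `dist_shore_km` (or `dist_shore`), `ln_depth`.
#' @return object of class `mpmm_data`: list with `steps` (one row per usable
#'   step: displacement `dx, dy`, predecessor `dpx, dpy`, covariates, `id` as
#'   factor, `track`), `covariates` (names available), `n_animals`.
#' @export
build_model_data <- function(tracks) {
  tracks <- tibble::as_tibble(tracks)
  if ("dist_shore_km" %in% names(tracks) && !"dist_shore" %in% names(tracks)) {
    tracks$dist_shore <- tracks$dist_shore_km
  }
  covs <- intersect(c("sex", "mass", "length", "postwean", "week",
                      "dist_shore", "ln_depth"), names(tracks))
  num_covs <- setdiff(covs, "sex")
  if (length(num_covs)) {
    bad_animal <- vapply(split(tracks[num_covs], tracks$id),
                         function(d) anyNA(d), logical(1))
    if (any(bad_animal)) {
      message("excluding animal(s) with missing covariates: ",
              paste(names(bad_animal)[bad_animal], collapse = ", "))
      tracks <- tracks[!tracks$id %in% names(bad_animal)[bad_animal], ]
    }
  }
  if (!"track" %in% names(tracks)) tracks$track <- 1L
  pieces <- split(tracks, interaction(tracks$id, tracks$track, drop = TRUE))
  steps <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$time), ]
    m <- nrow(tr)
    if (m < 3) return(NULL)
    org <- c(mean(tr$lon), mean(tr$lat))
    km <- lonlat_to_km(tr$lon, tr$lat, origin = org)
    dx <- diff(km[, 1]); dy <- diff(km[, 2]) # length m - 1, indexed 2..m
    use <- 2:(m - 1) # displacement indices with a predecessor
    out <- tr[use + 1, intersect(c("id", "track", "time", covs), names(tr))]
    out$dx <- dx[use]; out$dy <- dy[use]
    out$dpx <- dx[use - 1]; out$dpy <- dy[use - 1]
    out
  })
  steps <- dplyr::bind_rows(steps)
  if (nrow(steps) == 0) stop("no usable tracks (need >= 3 regular locations)",
                             call. = FALSE)
  if ("sex" %in% names(steps)) {
    steps$sex <- factor(steps$sex, levels = c("male", "female"))
  }
  steps$id <- factor(steps$id)
  steps <- steps[order(steps$id, steps$track, steps$time), ]
  structure(list(steps = steps, covariates = covs,
                 n_animals = nlevels(steps$id)),
            class = "mpmm_data")
}

#' @export
print.mpmm_data <- function(x, ...) {
  cat("<mpmm_data> ", nrow(x$steps), " steps, ", x$n_animals, " animals; ",
      "covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict model data to a subset of animals
#'
#' @param md an `mpmm_data`.
#' @param keep character vector of animal ids to retain.
#' @return an `mpmm_data` on the subset.
#' @export
subset_model_data <- function(md, keep) {
  steps <- md$steps[md$steps$id %in% keep, ]
  steps$id <- droplevels(steps$id)
  structure(list(steps = steps, covariates = md$covariates,
                 n_animals = nlevels(steps$id)), class = "mpmm_data")
}

# design matrix for a persistence formula on mpmm_data steps
mpmm_design <- function(md, formula) {
  stats::model.matrix(formula, data = md$steps)
}

# Laplace-approximated marginal log-likelihood contribution of one animal.
# Inner Newton over the scalar random intercept b with analytic first and
# second derivatives of
#   f(b) = sum_t log N(d_t | gamma_t d_{t-1}, diag(sx^2, sy^2)) + log N(b | 0, sb^2),
#   logit(gamma_t) = eta0_t + b.
laplace_animal <- function(eta0, dx, dy, dpx, dpy, sx, sy, sb) {
  condll <- function(b) {
    g <- stats::plogis(eta0 + b)
    rx <- dx - g * dpx; ry <- dy - g * dpy
    sum(stats::dnorm(rx, 0, sx, log = TRUE) +
          stats::dnorm(ry, 0, sy, log = TRUE))
  }
  if (sb < 1e-8) { # degenerate random effect
    return(structure(condll(0), bhat = 0))
  }
  fgh <- function(b) {
    g <- stats::plogis(eta0 + b)
    gg <- g * (1 - g)
    rx <- dx - g * dpx; ry <- dy - g * dpy
    f <- sum(stats::dnorm(rx, 0, sx, log = TRUE) +
               stats::dnorm(ry, 0, sy, log = TRUE)) +
      stats::dnorm(b, 0, sb, log = TRUE)
    rxp <- -gg * dpx; ryp <- -gg * dpy
    rxpp <- -gg * (1 - 2 * g) * dpx; rypp <- -gg * (1 - 2 * g) * dpy
    f1 <- -sum(rx * rxp) / sx^2 - sum(ry * ryp) / sy^2 - b / sb^2
    f2 <- -sum(rxp^2 + rx * rxpp) / sx^2 - sum(ryp^2 + ry * rypp) / sy^2 -
      1 / sb^2
    list(f = f, f1 = f1, f2 = f2)
  }
  b <- 0
  cur <- fgh(b)
  for (it in 1:60) {
    step <- if (cur$f2 < 0) -cur$f1 / cur$f2 else sign(cur$f1) * sb
    step <- max(min(step, 5 * sb + 1), -(5 * sb + 1))
    newb <- b + step
    newv <- fgh(newb)
    halve <- 0
    while (newv$f < cur$f - 1e-12 && halve < 30) {
      step <- step / 2
      newb <- b + step
      newv <- fgh(newb)
      halve <- halve + 1
    }
    conv <- abs(newv$f1) < 1e-9 || abs(step) < 1e-12
    b <- newb; cur <- newv
    if (conv) break
  }
  if (cur$f2 >= 0) { # fall back to a bracketed search
    opt <- stats::optimize(function(bb) fgh(bb)$f, c(b - 10 * sb, b + 10 * sb),
                           maximum = TRUE)
    b <- opt$maximum
    cur <- fgh(b)
    if (cur$f2 >= 0) return(structure(Inf, bhat = b))
  }
  structure(cur$f + 0.5 * log(2 * pi) - 0.5 * log(-cur$f2), bhat = b)
}

# negative marginal log-likelihood given design matrix X and parameters
mpmm_nll_core <- function(md, X, beta, log_sigma_b, log_sigma,
                          random_intercept = TRUE, want_b = FALSE) {
  if (!random_intercept) log_sigma_b <- 0
  if (any(!is.finite(c(beta, log_sigma_b, log_sigma)))) {
    stop("non-finite parameter value", call. = FALSE)
  }
  eta0 <- drop(X %*% beta)
  sx <- exp(log_sigma[1]); sy <- exp(log_sigma[2])
  sb <- if (random_intercept) exp(log_sigma_b) else 0
  st <- md$steps
  ids <- levels(st$id)
  ll <- 0
  bhat <- stats::setNames(numeric(length(ids)), ids)
  for (a in ids) {
    sel <- st$id == a
    li <- laplace_animal(eta0[sel], st$dx[sel], st$dy[sel],
                         st$dpx[sel], st$dpy[sel], sx, sy, sb)
    if (!is.finite(li)) {
      warning("inner optimization failed for animal ", a)
      return(Inf)
    }
    bhat[a] <- if (sb > 0) attr(li, "bhat") else 0
    ll <- ll + as.numeric(li)
  }
  if (want_b) return(list(nll = -ll, bhat = bhat))
  -ll
}

#' Negative marginal log-likelihood of the move-persistence mixed model
#'
#' Marginal over per-animal random intercepts by the Laplace method: an inner
#' Newton optimization of the scalar intercept per animal plus the usual
#' log-determinant correction.
#'
#' @param md an [build_model_data()] object.
#' @param beta fixed-effect coefficients matching the design matrix of
#'   `formula` (intercept first).
#' @param log_sigma_b log sd of the random intercepts.
#' @param log_sigma_step length-2 log innovation sds (x, y axes), km.
#' @param formula RHS formula over the covariates (default all available).
#' @return scalar negative log-likelihood.
#' @export
nll_mpmm <- function(md, beta, log_sigma_b, log_sigma_step,
                     formula = NULL) {
  if (is.null(formula)) {
    formula <- stats::reformulate(md$covariates)
  }
  X <- mpmm_design(md, formula)
  if (length(beta) != ncol(X)) {
    stop("beta has length ", length(beta), " but the design matrix has ",
         ncol(X), " columns", call. = FALSE)
  }
  mpmm_nll_core(md, X, beta, log_sigma_b, log_sigma_step)
}

#' Fit the move-persistence mixed-effects model
#'
#' Maximum-likelihood fit of `d_t = gamma_t d_{t-1} + eps_t` with
#' `logit(gamma_t) = x_t' beta + b_i`, `b_i ~ N(0, sigma_b^2)`,
#' `eps_t ~ N(0, diag(sigma_x^2, sigma_y^2))`. Optimization is two-stage for
#' robustness (a derivative-free Nelder-Mead pass generating initial values,
#' then bounds-free quasi-Newton refinement with `nlminb`), with internal
#' standardization of covariate columns for conditioning. Standard errors come
#' from the inverse observed information; Wald z p-values are reported.
#'
#' @param md an [build_model_data()] object.
#' @param formula RHS formula over covariates, e.g.
#'   `~ sex + mass + length + postwean + week + dist_shore + ln_depth`
#'   or `~ 1` for the intercept-only model.
#' @param random_intercept include per-animal random intercepts (default TRUE,
#'   as in all candidate models of the study).
#' @param start optional `mpmm_fit` whose estimates warm-start the fit (used
#'   by [loo_cv()]).
#' @param control list: `nm_maxit` (Nelder-Mead iterations, default 300),
#'   `trace` (default 0).
#' @return object of class `mpmm_fit`: `coefficients` tibble (term, estimate,
#'   se, z, p), `sigma_b`, `sigma_step` (x, y), `b` (plug-in intercept modes),
#'   `gamma` tibble (id, track, time, gamma), `logLik`, `k`, `n`, `AICc`,
#'   `convergence` (0 = ok), `formula`, and the `md` used.
#' @export
fit_mpmm <- function(md, formula = NULL, random_intercept = TRUE,
                     start = NULL, control = list()) {
  if (is.null(formula)) formula <- stats::reformulate(md$covariates)
  nm_maxit <- control$nm_maxit %||% 300
  X <- mpmm_design(md, formula)
  p <- ncol(X)
  st <- md$steps

  # internal standardization (columns other than the intercept)
  ctr <- rep(0, p); scl <- rep(1, p)
  for (j in seq_len(p)) {
    if (colnames(X)[j] == "(Intercept)") next
    s <- stats::sd(X[, j])
    if (s > 0) { ctr[j] <- mean(X[, j]); scl[j] <- s }
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  # moment-based starting values
  r0 <- sum(st$dx * st$dpx + st$dy * st$dpy) / sum(st$dpx^2 + st$dpy^2)
  r0 <- min(max(r0, 0.05), 0.95)
  beta_s0 <- c(stats::qlogis(r0), rep(0, p - 1))
  sx0 <- stats::sd(st$dx - r0 * st$dpx)
  sy0 <- stats::sd(st$dy - r0 * st$dpy)
  th0 <- c(beta_s0,
           if (random_intercept) log(0.25),
           log(max(sx0, 1e-3)), log(max(sy0, 1e-3)))
  if (!is.null(start) && inherits(start, "mpmm_fit")) {
    bn <- start$coefficients$estimate
    names(bn) <- start$coefficients$term
    common <- intersect(colnames(X), names(bn))
    b_nat <- stats::setNames(rep(0, p), colnames(X))
    b_nat[common] <- bn[common]
    b_s <- b_nat * scl
    if ("(Intercept)" %in% colnames(X)) {
      b_s[1] <- b_nat[1] + sum(b_nat[-1] * ctr[-1])
    }
    th0 <- c(b_s,
             if (random_intercept) log(max(start$sigma_b, 1e-4)),
             log(start$sigma_step))
  }

  nb <- if (random_intercept) p + 1 else p
  obj <- function(th) {
    val <- try(mpmm_nll_core(md, Xs, th[seq_len(p)],
                             if (random_intercept) th[p + 1] else -Inf,
                             th[(nb + 1):(nb + 2)],
                             random_intercept = random_intercept),
               silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e10 else val
  }

  nm <- stats::optim(th0, obj, method = "Nelder-Mead",
                     control = list(maxit = nm_maxit, reltol = 1e-7))
  opt <- stats::nlminb(nm$par, obj,
                       control = list(iter.max = 400, eval.max = 800))
  th <- opt$par
  conv <- opt$convergence

  H <- try(stats::optimHess(th, obj), silent = TRUE)
  cov_all <- if (!inherits(H, "try-error")) {
    ch <- try(chol(H), silent = TRUE)
    if (inherits(ch, "try-error")) NULL else chol2inv(ch)
  } else NULL

  # transform standardized beta back to the natural scale
  A <- diag(1 / scl)
  if ("(Intercept)" %in% colnames(X)) {
    A[1, ] <- 0; A[1, 1] <- 1
    A[1, -1] <- -ctr[-1] / scl[-1]
  }
  beta_nat <- drop(A %*% th[seq_len(p)])
  se_nat <- rep(NA_real_, p)
  if (!is.null(cov_all)) {
    covb <- A %*% cov_all[seq_len(p), seq_len(p), drop = FALSE] %*% t(A)
    se_nat <- sqrt(pmax(diag(covb), 0))
  }
  z <- beta_nat / se_nat
  coefs <- tibble::tibble(term = colnames(X), estimate = beta_nat,
                          se = se_nat, z = z,
                          p = 2 * stats::pnorm(-abs(z)))

  nl <- mpmm_nll_core(md, Xs, th[seq_len(p)],
                      if (random_intercept) th[p + 1] else -Inf,
                      th[(nb + 1):(nb + 2)],
                      random_intercept = random_intercept, want_b = TRUE)
  sigma_b <- if (random_intercept) exp(th[p + 1]) else 0
  sigma_step <- exp(th[(nb + 1):(nb + 2)])
  eta0 <- drop(X %*% beta_nat)
  gamma <- stats::plogis(eta0 + nl$bhat[as.character(st$id)])
  n <- nrow(st)
  k <- p + as.integer(random_intercept) + 2
  ll <- -nl$nll
  structure(list(
    coefficients = coefs, sigma_b = sigma_b, sigma_step = sigma_step,
    b = nl$bhat,
    gamma = tibble::tibble(id = st$id, track = st$track, time = st$time,
                           gamma = gamma),
    logLik = ll, k = k, n = n, AICc = aicc(ll, k, n),
    convergence = conv, message = opt$message, formula = formula, md = md,
    vcov = cov_all, scaling = list(centre = ctr, scale = scl)
  ), class = "mpmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mpmm_fit <- function(x, digits = 4, ...) {
  cat("Move-persistence mixed-effects model (Laplace ML)\n")
  cat("formula: ~", paste(attr(stats::terms(x$formula), "term.labels"),
                          collapse = " + "), "\n")
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat("sigma_b =", signif(x$sigma_b, digits),
      "; sigma_step =", paste(signif(x$sigma_step, digits), collapse = ", "),
      "km\n")
  cat("logLik =", round(x$logLik, 2), " k =", x$k, " n =", x$n,
      " AICc =", round(x$AICc, 2), "\n")
  invisible(x)
}

#' Behavioural classification of move-persistence estimates
#'
#' gamma above 0.70 indicates directed travel, below 0.30 area-restricted
#' search; values in between (inclusive) are intermediate. Inequalities are
#' strict, so gamma = 0.30 or 0.70 is intermediate.
#'
#' @param fit an `mpmm_fit`, or a numeric gamma vector.
#' @param lower,upper thresholds (defaults 0.30 and 0.70).
#' @return list with `labels` (character vector), `counts` (named overall
#'   tally), and, for fits, `by_animal` (tibble of per-animal counts).
#' @export
classify_gamma <- function(fit, lower = 0.30, upper = 0.70) {
  g <- if (inherits(fit, "mpmm_fit")) fit$gamma$gamma else fit
  lab <- ifelse(g > upper, "directed_travel",
                ifelse(g < lower, "area_restricted_search", "intermediate"))
  counts <- c(directed_travel = sum(lab == "directed_travel"),
              intermediate = sum(lab == "intermediate"),
              area_restricted_search = sum(lab == "area_restricted_search"))
  out <- list(labels = lab, counts = counts)
  if (inherits(fit, "mpmm_fit")) {
    out$by_animal <- dplyr::count(
      tibble::tibble(id = fit$gamma$id, label = lab), .data$id, .data$label)
  }
  out
}

#' One-step-ahead residuals of a fitted persistence model
#'
#' Standardized per-axis forecast errors
#' `(d_t - gamma_t d_{t-1}) / sigma_step`, with plug-in random intercepts.
#' Used to check the whiteness and normality assumptions.
#'
#' @param fit an `mpmm_fit`.
#' @return tibble: `id`, `track`, `time`, `resid_x`, `resid_y`.
#' @export
osa_residuals <- function(fit) {
  st <- fit$md$steps
  g <- fit$gamma$gamma
  tibble::tibble(
    id = st$id, track = st$track, time = st$time,
    resid_x = (st$dx - g * st$dpx) / fit$sigma_step[1],
    resid_y = (st$dy - g * st$dpy) / fit$sigma_step[2]
  )
}

#' Fit and rank candidate persistence models by AICc
#'
#' @param md an `mpmm_data`.
#' @param formulas list of RHS formulas (>= 2); all are fitted with random
#'   intercepts by ML.
#' @param ... passed to [fit_mpmm()].
#' @return tibble ranked by AICc: `model`, `df`, `logLik`, `AICc`, `dAICc`,
#'   `weight`, with the fits in attribute `"fits"`. Non-converged candidates
#'   are dropped from the ranking with a warning.
#' @export
model_select <- function(md, formulas, ...) {
  stopifnot(length(formulas) >= 2)
  fits <- lapply(formulas, function(f) {
    try(fit_mpmm(md, f, ...), silent = TRUE)
  })
  lab <- vapply(formulas, function(f) {
    tl <- attr(stats::terms(f), "term.labels")
    paste("~", if (length(tl)) paste(tl, collapse = " + ") else "1")
  }, character(1))
  ok <- vapply(fits, function(f) inherits(f, "mpmm_fit") && f$convergence == 0,
               logical(1))
  if (!any(ok)) stop("all candidate models failed", call. = FALSE)
  if (any(!ok)) warning("dropped non-converged candidate(s): ",
                        paste(lab[!ok], collapse = "; "))
  tab <- tibble::tibble(
    model = lab[ok],
    df = vapply(fits[ok], function(f) f$k, numeric(1)),
    logLik = vapply(fits[ok], function(f) f$logLik, numeric(1)),
    AICc = vapply(fits[ok], function(f) f$AICc, numeric(1))
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  attr(tab, "fits") <- stats::setNames(fits[ok], lab[ok])
  tab
}

#' Variance inflation factors of persistence covariates
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary regression of covariate j on the
#' remaining covariates (sex entered as a 0/1 indicator). Values below 2 were
#' taken in the study as showing no multicollinearity concern.
#'
#' @param md an `mpmm_data`.
#' @param covariates covariate names (default all available, >= 2 required).
#' @return named numeric vector; perfectly collinear covariates report `Inf`
#'   with a warning.
#' @export
vif_covariates <- function(md, covariates = NULL) {
  covariates <- covariates %||% md$covariates
  stopifnot(length(covariates) >= 2)
  st <- md$steps
  Xd <- lapply(covariates, function(nm) {
    v <- st[[nm]]
    if (is.factor(v) || is.character(v)) as.numeric(factor(v)) - 1 else
      as.numeric(v)
  })
  names(Xd) <- covariates
  Xd <- as.data.frame(Xd)
  out <- vapply(covariates, function(nm) {
    r2 <- suppressWarnings({ # lm warns about perfect fits; we report Inf
      fit <- stats::lm(stats::reformulate(setdiff(covariates, nm),
                                          response = nm), data = Xd)
      summary(fit)$r.squared
    })
    if (r2 > 1 - 1e-10) {
      warning("covariate '", nm, "' is perfectly collinear")
      Inf
    } else 1 / (1 - r2)
  }, numeric(1))
  out
}

#' Leave-one-out cross-validation of a persistence model
#'
#' Refits the model once per left-out animal (warm-started at the full-model
#' estimates) and summarizes coefficient stability: per-coefficient 5% and
#' 95% quantiles of the refit estimates, and the percentage of refits whose
#' estimate falls inside the full model's 95% Wald confidence interval.
#'
#' @param md an `mpmm_data` with at least 3 animals.
#' @param formula RHS formula of the model.
#' @param full_fit optional prefitted full model (refitted here if NULL).
#' @param ... passed to [fit_mpmm()].
#' @return list with `summary` tibble (`term`, `q5`, `q95`, `est_trend_pct`),
#'   `estimates` (refit-by-term matrix), `n_refits`, and `full_fit`.
#' @export
loo_cv <- function(md, formula = NULL, full_fit = NULL, ...) {
  if (md$n_animals < 3) stop("need at least 3 animals", call. = FALSE)
  if (is.null(formula)) formula <- stats::reformulate(md$covariates)
  if (is.null(full_fit)) full_fit <- fit_mpmm(md, formula, ...)
  ids <- levels(md$steps$id)
  est <- list()
  for (a in ids) {
    sub <- subset_model_data(md, setdiff(ids, a))
    f <- try(fit_mpmm(sub, formula, start = full_fit, ...), silent = TRUE)
    if (inherits(f, "try-error") || f$convergence != 0) {
      message("leave-out refit failed for animal ", a, "; skipped")
      next
    }
    est[[a]] <- stats::setNames(f$coefficients$estimate,
                                f$coefficients$term)
  }
  if (!length(est)) stop("all leave-one-out refits failed", call. = FALSE)
  em <- do.call(rbind, est)
  full <- full_fit$coefficients
  lo <- full$estimate - 1.96 * full$se
  hi <- full$estimate + 1.96 * full$se
  summ <- tibble::tibble(
    term = full$term,
    q5 = apply(em, 2, stats::quantile, probs = 0.05)[full$term],
    q95 = apply(em, 2, stats::quantile, probs = 0.95)[full$term],
    est_trend_pct = vapply(seq_along(full$term), function(j) {
      100 * mean(em[, full$term[j]] >= lo[j] & em[, full$term[j]] <= hi[j])
    }, numeric(1))
  )
  list(summary = summ, estimates = em, n_refits = nrow(em),
       full_fit = full_fit)
}
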