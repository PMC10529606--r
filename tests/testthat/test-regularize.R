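no_haulout <- function(n) tibble::tibble(is_haulout = rep(FALSE, n),
                                         reason = rep("none", n))

test_that("track splitting breaks at long gaps and drops short segments", {
  t_h <- c(0:59, 60:119 + 50)           # 50 h gap after fix 60
  s <- fix_stream(t_h, lon = rep(-60, 120), lat = rep(44, 120))
  tr <- split_tracks(s, no_haulout(120), min_fixes = 50)
  expect_equal(as.integer(table(tr$track)), c(60L, 60L))
  # a 47.9 h gap is bridged (strictly greater than 48 h splits)
  t_h2 <- c(0:59, 60:119 + 47.9 - 1)
  tr2 <- split_tracks(fix_stream(t_h2, rep(-60, 120), rep(44, 120)),
                      no_haulout(120), min_fixes = 50)
  expect_equal(length(unique(tr2$track)), 1)
  # a 49-fix segment is dropped
  s3 <- fix_stream(seq(0, 48, length.out = 49), rep(-60, 49), rep(44, 49))
  expect_message(tr3 <- split_tracks(s3, no_haulout(49), min_fixes = 50),
                 "dropped")
  expect_equal(nrow(tr3), 0)
  # haulout fixes break tracks
  calls <- no_haulout(120)
  calls$is_haulout[61] <- TRUE
  tr4 <- split_tracks(fix_stream(0:119, rep(-60, 120), rep(44, 120)),
                      calls, min_fixes = 50)
  expect_equal(length(unique(tr4$track)), 2)
  expect_false(61 %in% which(fix_stream(0:119, rep(-60, 120),
                                        rep(44, 120))$time %in% tr4$time))
})

test_that("linear interpolation is exact on the grid and colinear between fixes", {
  # grid time coinciding with an observed fix reproduces the observation
  s <- fix_stream(c(0, 6, 12, 18, 24), lon = c(-60, -60.2, -60.1, -59.9, -59.8),
                  lat = c(44, 44.1, 44.3, 44.2, 44.4))
  ri <- interpolate_track(s, delta_h = 6)
  expect_equal(ri$lon, s$lon)
  expect_equal(ri$lat, s$lat)
  # two fixes 12 h apart: the 6 h point is the coordinate-wise average
  s2 <- fix_stream(c(0, 12), lon = c(-60, -59), lat = c(44, 44.5))
  ri2 <- interpolate_track(s2, delta_h = 6)
  expect_equal(ri2$lon[2], -59.5)
  expect_equal(ri2$lat[2], 44.25)
  # random fixture: every interpolated point lies on its bracketing segment
  set.seed(5)
  t_h <- sort(runif(40, 0, 100))
  s3 <- fix_stream(t_h, lon = -60 + cumsum(rnorm(40, 0, 0.05)),
                   lat = 44 + cumsum(rnorm(40, 0, 0.03)))
  ri3 <- interpolate_track(s3, delta_h = 6)
  for (i in seq_len(nrow(ri3))) {
    j <- findInterval(as.numeric(ri3$time[i]), as.numeric(s3$time),
                      rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(s3) - 1)
    # colinearity: cross product of (P - A) and (B - A) vanishes
    ax <- s3$lon[j]; ay <- s3$lat[j]; bx <- s3$lon[j + 1]; by <- s3$lat[j + 1]
    cross <- (ri3$lon[i] - ax) * (by - ay) - (ri3$lat[i] - ay) * (bx - ax)
    expect_lt(abs(cross), 1e-10)
  }
  # a track spanning less than 2 * delta is skipped
  expect_message(short <- interpolate_track(fix_stream(c(0, 10),
                                                       c(-60, -60), c(44, 44)),
                                            delta_h = 6), "skipped")
  expect_null(short)
})

test_that("the interpolation grid is delta-regular and refinement-consistent", {
  set.seed(6)
  t_h <- sort(c(0, runif(30, 0, 90), 90))
  s <- fix_stream(t_h, lon = -60 + cumsum(rnorm(32, 0, 0.04)),
                  lat = 44 + cumsum(rnorm(32, 0, 0.04)))
  ri6 <- interpolate_track(s, delta_h = 6)
  expect_true(all(abs(diff(as.numeric(ri6$time)) - 6 * 3600) < 1e-6))
  span_h <- diff(range(t_h))
  expect_equal(nrow(ri6), floor(span_h / 6) + 1)
  # interpolating at 3 h then subsampling every 2nd point equals 6 h exactly
  ri3 <- interpolate_track(s, delta_h = 3)
  sub <- ri3[seq(1, nrow(ri3), by = 2), ]
  expect_equal(sub$lon[seq_len(nrow(ri6))], ri6$lon)
  expect_equal(sub$lat[seq_len(nrow(ri6))], ri6$lat)
})

test_that("covariate annotation applies the depth floor, ln transform and week origin", {
  b <- toy_bathy()
  rt <- tibble::tibble(id = "a1", track = 1L, time = hrs(c(0, 6, 12)),
                       lon = c(-59.9, -60.1, -60.0), lat = rep(43.9, 3))
  out <- annotate_covariates(rt, b, first_at_sea = hrs(0))
  expect_equal(out$depth_m[1], 143.7)
  expect_equal(out$ln_depth[1], log(143.7), tolerance = 1e-12)
  expect_equal(round(out$ln_depth[1], 3), 4.968)
  # the island cell (elevation +1.9 m) gets depth 1 m, ln_depth 0
  expect_equal(out$depth_m[2], 1)
  expect_equal(out$ln_depth[2], 0)
  expect_equal(out$week, c(1L, 1L, 1L))
  # a location on a coastline cell has zero distance to shore
  co <- coastline_cells(b)
  rt2 <- tibble::tibble(id = "a1", track = 1L, time = hrs(0),
                        lon = co$lon[1], lat = co$lat[1])
  expect_equal(annotate_covariates(rt2, b, hrs(0))$dist_shore_km, 0)
  # week origin: 8 days after the first at-sea fix is week 2
  rt3 <- tibble::tibble(id = "a1", track = 2L, time = hrs(8 * 24),
                        lon = -59.9, lat = 43.9)
  expect_equal(annotate_covariates(rt3, b, hrs(0))$week, 2L)
})

test_that("time-step diagnostics report fit quality per candidate step without choosing one", {
  scen <- small_scenario()
  qc <- filter_fixes(scen$fixes)
  streams <- lapply(scen$pups$id[1:2], function(a) {
    s <- qc$kept[qc$kept$id == a, ]
    cl <- classify_haulout(s, scen$bathy, scen$colony)
    ts <- trip_summaries(s, cl, scen$colony)
    list(stream = s, calls = cl, first_at_sea = ts$first_at_sea,
         pup = scen$pups[scen$pups$id == a, ])
  })
  diag <- timestep_diagnostics(streams, scen$bathy, deltas = c(6, 8),
                               min_fixes = 40)
  expect_equal(diag$delta_h, c(6, 8))
  expect_true(all(diag$n_locations > 0))
  # finer steps give more locations; both fits converge with gamma in (0,1)
  expect_gt(diag$n_locations[1], diag$n_locations[2])
  expect_true(all(diag$converged))
  expect_true(all(diag$mean_gamma > 0 & diag$mean_gamma < 1))
  expect_true(all(is.finite(diag$resid_acf1_x)))
})

test_that("distance to shore varies smoothly along a track (Lipschitz in displacement)", {
  b <- default_bathy()
  co <- coastline_cells(b)
  set.seed(8)
  lon <- seq(-60.5, -58.5, length.out = 25)
  lat <- rep(44.2, 25)
  d <- dist_to_shore(b, lon, lat, coast = co)
  gc <- great_circle_distance(lon[-25], lat[-25], lon[-1], lat[-1])
  cell_diag <- b$cell_size * 111.32 * sqrt(2)
  expect_true(all(abs(diff(d)) <= gc + cell_diag))
})
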