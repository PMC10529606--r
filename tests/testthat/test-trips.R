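test_that("the tag's haulout flag takes precedence over the other rules", {
  b <- toy_bathy()
  col <- colony_geometry(centre = c(-50, 47)) # far away: colony rule inert
  # tag-flagged fix over 80 m of water, far from any colony
  ct <- classify_haulout(fix_stream(0, -59.7, 44.3, tag_haulout = TRUE), b, col)
  expect_true(ct$is_haulout)
  expect_equal(ct$reason, "tag_flag")
  # tag flag also wins when the shallow rule would apply too
  cb <- classify_haulout(fix_stream(0, -60.0, 43.9, tag_haulout = TRUE), b, col)
  expect_equal(cb$reason, "tag_flag")
})

test_that("shallow-depth and colony-radius rules use their thresholds exactly", {
  b <- toy_bathy()
  col <- colony_geometry(centre = c(-60.1, 43.9), length_km = 1,
                         haulout_radius = 10)
  # depth exactly 5 m is a haulout
  c5 <- classify_haulout(fix_stream(0, -60.0, 43.9), b, col)
  expect_true(c5$is_haulout)
  expect_equal(c5$reason, "shallow_depth")
  # deep water but ~8.9 km from the colony axis -> colony_radius
  near <- km_to_lonlat(0, 8.9, origin = c(-60.1, 43.9))
  cn <- classify_haulout(fix_stream(0, near[1], near[2]), b, col)
  expect_equal(cn$reason, "colony_radius")
  # deep and far -> at sea
  cf <- classify_haulout(fix_stream(0, -59.7, 44.3), b, col)
  expect_false(cf$is_haulout)
  expect_equal(cf$reason, "none")
  # off-grid fixes warn and skip the depth rule
  expect_warning(classify_haulout(fix_stream(0, -70, 43.9), b, col),
                 "outside")
})

test_that("trip segmentation applies the strict 24 h rule and completeness", {
  mk_calls <- function(flags) tibble::tibble(is_haulout = flags,
                                             reason = ifelse(flags, "tag_flag", "none"))
  # haulout, 30 h at sea, haulout -> one complete trip
  s <- fix_stream(c(0, 5, 10, 20, 35, 36), lon = rep(-60, 6), lat = rep(44, 6))
  seg <- segment_trips(s, mk_calls(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)))
  expect_equal(nrow(seg$trips), 1)
  expect_true(seg$trips$complete)
  expect_equal(seg$trips$n_fixes, 4)
  # exactly 24 h and below is excluded
  s2 <- fix_stream(c(0, 5, 29, 30), lon = rep(-60, 4), lat = rep(44, 4))
  seg2 <- segment_trips(s2, mk_calls(c(TRUE, FALSE, FALSE, TRUE)))
  expect_equal(nrow(seg2$trips), 0)
  expect_equal(nrow(seg2$excluded), 1)
  # stream ending at sea -> incomplete trip
  s3 <- fix_stream(c(0, 5, 45), lon = rep(-60, 3), lat = rep(44, 3))
  seg3 <- segment_trips(s3, mk_calls(c(TRUE, FALSE, FALSE)))
  expect_equal(nrow(seg3$trips), 1)
  expect_false(seg3$trips$complete)
  # empty stream
  seg4 <- segment_trips(s3[0, ], mk_calls(logical(0)))
  expect_equal(nrow(seg4$trips), 0)
})

test_that("trip metrics follow their definitions and match a brute-force distance oracle", {
  # two fixes 24 h apart, placed ~48 km apart
  p2 <- km_to_lonlat(0, 48, origin = c(-60, 44))
  trip <- tibble::tibble(
    id = "a1", trip_no = 1L, start = hrs(0), end = hrs(24), complete = TRUE,
    n_fixes = 2L, origin_lon = -60, origin_lat = 44,
    dest_lon = p2[1], dest_lat = p2[2],
    fixes = list(fix_stream(c(0, 24), c(-60, p2[1]), c(44, p2[2]))))
  m <- trip_metrics(trip)
  expect_equal(m$duration_d, 1)
  expect_equal(m$distance_km, 48, tolerance = 0.01)
  expect_equal(m$mean_speed_kmh, m$distance_km / 24)
  # subsequent haulout duration of exactly 33.6 h
  m2 <- trip_metrics(trip, next_trip_start = hrs(24 + 33.6),
                     first_haulout_after = hrs(24))
  expect_equal(m2$haulout_duration_h, 33.6)
  # zig-zag fixture: cumulative distance equals an independent haversine sum
  set.seed(12)
  lon <- -60 + cumsum(runif(5, -0.3, 0.3)); lat <- 44 + cumsum(runif(5, -0.2, 0.2))
  zig <- trip
  zig$fixes <- list(fix_stream(seq(0, 48, length.out = 5), lon, lat))
  oracle <- sum(vapply(1:4, function(i) {
    geosphere::distHaversine(c(lon[i], lat[i]), c(lon[i + 1], lat[i + 1]),
                             r = 6371)
  }, numeric(1)))
  expect_equal(trip_metrics(zig)$distance_km, oracle, tolerance = 1e-9)
})

test_that("trip types reflect colony membership of both endpoints", {
  col <- colony_geometry(centre = c(-59.91, 43.93))
  off <- km_to_lonlat(80, 40, origin = c(-59.91, 43.93))
  base <- tibble::tibble(id = "a1", trip_no = 1L, start = hrs(0), end = hrs(48),
                         complete = TRUE, n_fixes = 2L,
                         origin_lon = -59.91, origin_lat = 43.93,
                         dest_lon = -59.91, dest_lat = 43.93, fixes = list(NULL))
  expect_equal(classify_trip_type(base, col), "A")
  b2 <- base; b2$dest_lon <- off[1]; b2$dest_lat <- off[2]
  expect_equal(classify_trip_type(b2, col), "B")
  b3 <- b2; b3$origin_lon <- off[1]; b3$origin_lat <- off[2]
  expect_equal(classify_trip_type(b3, col), "C")
  b4 <- base; b4$complete <- FALSE
  expect_equal(classify_trip_type(b4, col), "incomplete")
})

test_that("week labelling and per-animal covariates follow their definitions", {
  first <- hrs(0)
  expect_equal(week_at_sea(first + 6.9 * 86400, first), 1L)
  expect_equal(week_at_sea(first + 7.1 * 86400, first), 2L)
  pup <- tibble::tibble(id = "a1", wean_date = as.POSIXct("2016-01-01", tz = "UTC"))
  trips <- tibble::tibble(start = as.POSIXct("2016-01-22", tz = "UTC"),
                          complete = TRUE)
  cov <- derive_animal_covariates(pup, trips, deployment_days = 69)
  expect_equal(cov$postwean_days, 21)
  # Table 1 arithmetic: 4 complete trips over 69 tracking days
  trips4 <- tibble::tibble(start = hrs(1:4), complete = rep(TRUE, 4))
  expect_equal(derive_animal_covariates(pup, trips4, 69)$trip_frequency,
               4 / 69, tolerance = 1e-12)
  none <- derive_animal_covariates(pup, trips4[0, ], 69)
  expect_true(is.na(none$postwean_days))
  expect_equal(none$trip_frequency, 0)
})

test_that("every at-sea fix lands in exactly one trip or excluded bout", {
  scen <- small_scenario()
  qc <- filter_fixes(scen$fixes)
  a <- unique(qc$kept$id)[1]
  stream <- qc$kept[qc$kept$id == a, ]
  calls <- classify_haulout(stream, scen$bathy, scen$colony)
  seg <- segment_trips(stream, calls)
  all_fix_times <- c(
    unlist(lapply(seg$trips$fixes, function(f) as.numeric(f$time))),
    unlist(lapply(seg$excluded$fixes, function(f) as.numeric(f$time))))
  at_sea_times <- as.numeric(stream$time[!calls$is_haulout])
  expect_setequal(all_fix_times, at_sea_times)
  expect_equal(length(all_fix_times), length(at_sea_times)) # no double count
  # chronology: trips disjoint and ordered
  tr <- seg$trips
  if (nrow(tr) > 1) {
    expect_true(all(diff(as.numeric(tr$start)) > 0))
    expect_true(all(as.numeric(tr$start[-1]) > as.numeric(tr$end[-nrow(tr)])))
  }
})

test_that("trips recovered with truth-based calls match the simulator's schedule", {
  scen <- small_scenario()
  qc <- filter_fixes(scen$fixes)
  for (a in names(scen$truths)[1:2]) {
    stream <- qc$kept[qc$kept$id == a, ]
    sched <- scen$truths[[a]]$haulout_schedule
    in_window <- vapply(seq_len(nrow(stream)), function(i) {
      any(stream$time[i] >= sched$start & stream$time[i] < sched$end)
    }, logical(1))
    calls <- tibble::tibble(is_haulout = in_window,
                            reason = ifelse(in_window, "tag_flag", "none"))
    seg <- segment_trips(stream, calls)
    max_gap_h <- max(as.numeric(diff(stream$time), units = "hours"))
    for (k in seq_len(nrow(seg$trips))) {
      tr <- seg$trips[k, ]
      # the trip start should sit within one (largest) fix interval of a
      # scheduled haulout end, and the end within one interval of a start
      d_start <- min(abs(as.numeric(difftime(tr$start, sched$end, units = "hours"))))
      expect_lte(d_start, max_gap_h + 0.26)
      if (tr$complete) {
        d_end <- min(abs(as.numeric(difftime(tr$end, sched$start, units = "hours"))))
        expect_lte(d_end, max_gap_h + 0.26)
      }
    }
  }
})

test_that("the published deployment table reproduces the study's trip tallies", {
  d <- sable_pups()
  expect_equal(nrow(d), 23)
  expect_equal(sum(d$n_trips), 80)          # 80 complete trips in total
  makers <- d[d$n_trips > 0, ]
  expect_equal(nrow(makers), 19)            # by 19 pups
  expect_equal(sum(makers$sex == "male"), 9)
  expect_equal(sum(makers$sex == "female"), 10)
  expect_equal(nrow(sable_trip_frequency()), 18) # one lacks biometrics
})
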