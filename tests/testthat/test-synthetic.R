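test_that("generation is deterministic given the scenario seed", {
  sc <- scenario_config(n_participants = 1, n_days = 1, seed = 123)
  a <- generate_gps_day(sc, 1, 1, "qstarz")
  b <- generate_gps_day(sc, 1, 1, "qstarz")
  expect_identical(a, b)
  truth <- generate_day_truth(sc, 1, 1)
  sch <- build_accel_schedule(truth, sc)
  s1 <- generate_accel_stream(sc, "wrist", sch, device = "watch_s2")
  s2 <- generate_accel_stream(sc, "wrist", sch, device = "watch_s2")
  expect_identical(s1, s2)
  d1 <- generate_diary(sc, truth, sch)
  expect_identical(d1, generate_diary(sc, truth, sch))
  # a different seed changes the data
  sc2 <- scenario_config(n_participants = 1, n_days = 1, seed = 124)
  expect_false(identical(generate_gps_day(sc2, 1, 1, "qstarz")$track, a$track))
})

test_that("noise-free tracks never exceed the passive speed ceiling", {
  sc <- scenario_config(gps_noise_sd = 0, dropout_prob = 0, seed = 55)
  g <- generate_gps_day(sc, 2, 1, "qstarz")
  tr <- g$track
  n <- nrow(tr)
  sp <- haversine_m(tr$lat[-n], tr$lon[-n], tr$lat[-1], tr$lon[-1]) /
    diff(tr$time) * 3.6
  expect_lte(max(sp), sc$leg_speed_passive[2] + 1e-6)
})

test_that("planted dwells put the promised fix count near the POI", {
  sc <- scenario_config(
    gps_noise_sd = 0, dropout_prob = 0,
    stop_dwell_min = c(10, 10), seed = 77
  )
  g <- generate_gps_day(sc, 1, 1, "qstarz")
  iv <- g$truth$intervals
  poi_stops <- iv[iv$kind == "stop" & !is.na(iv$poi) & iv$poi > 0, ]
  skip_if(nrow(poi_stops) == 0, "day stayed home under this seed")
  s <- poi_stops[1, ]
  d <- haversine_m(s$from_lat, s$from_lon, g$track$lat, g$track$lon)
  inside <- d <= 75 & g$track$time >= s$start & g$track$time <= s$end
  # 10 min dwell at 5 s interval: at least 120 consecutive fixes within 75 m
  r <- rle(inside)
  expect_gte(max(r$lengths[r$values]), 120)
})

test_that("planted structure respects the detection thresholds", {
  sc <- scenario_config(seed = 31)
  for (d in 1:3) {
    truth <- generate_day_truth(sc, 3, d)
    iv <- truth$intervals
    expect_true(all(diff(iv$start) > 0))
    expect_equal(iv$start[-1], iv$end[-nrow(iv)]) # tiles the timeline
    stops <- iv[iv$kind == "stop", ]
    expect_true(all(stops$end - stops$start > 5 * 60))
    trips <- truth$trips
    if (nrow(trips)) {
      expect_true(all(trips$end - trips$start > 3 * 60))
      span <- haversine_m(
        trips$from_lat, trips$from_lon,
        trips$to_lat, trips$to_lon
      )
      expect_true(all(span >= 100))
    }
  }
})

test_that("unknown device identifiers are rejected", {
  sc <- scenario_config(seed = 1)
  expect_error(generate_gps_day(sc, 1, 1, "nokia"), "unknown GPS device")
  truth <- generate_day_truth(sc, 1, 1)
  sch <- build_accel_schedule(truth, sc)
  expect_error(
    generate_accel_stream(sc, "wrist", sch, device = "nokia"),
    "unknown accelerometer"
  )
})

test_that("static postures keep unit gravity and the right axis convention", {
  sc <- scenario_config(accel_noise_sd = 0, seed = 8)
  sch <- data.frame(
    start = c(0, 300), end = c(300, 600),
    activity = c("stand", "sit"), cadence = NA, steps = NA,
    is_task = FALSE, task = NA
  )
  th <- generate_accel_stream(sc, "thigh", sch, device = "actigraph")$stream
  vm <- sqrt(rowSums(th$data^2))
  expect_equal(range(vm), c(1, 1), tolerance = 1e-12)
  stand <- th$data[1:(300 * 30), ]
  expect_equal(mean(stand[, 1]), 1, tolerance = 1e-12) # longitudinal axis
  expect_equal(mean(abs(stand[, 3])), 0, tolerance = 1e-12)
  sit <- th$data[(300 * 30 + 1):(600 * 30), ]
  expect_equal(mean(sit[, 3]), 1, tolerance = 1e-12)
  expect_equal(mean(abs(sit[, 1])), 0, tolerance = 1e-12)
})

test_that("walking bouts carry one oscillation peak per planted step", {
  sc <- scenario_config(accel_noise_sd = 0, seed = 8)
  sch <- simple_schedule(pre_s = 60, walk_s = 50, post_s = 60, cadence = 2)
  w <- generate_accel_stream(sc, "wrist", sch, device = "actigraph")$stream
  seg <- w$data[(60 * 30 + 1):(110 * 30), 3] # walking samples, z axis
  seg <- seg - mean(seg)
  d <- diff(seg)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  peaks <- peaks[seg[peaks] > 0.3]
  expect_equal(length(peaks), 100) # 50 s at 2 Hz cadence
})

test_that("overlapping schedules are rejected", {
  sc <- scenario_config(seed = 8)
  sch <- data.frame(
    start = c(0, 200), end = c(300, 500),
    activity = c("sit", "stand"), cadence = NA, steps = NA,
    is_task = FALSE, task = NA
  )
  expect_error(generate_accel_stream(sc, "thigh", sch), "overlap")
})

test_that("diaries report truth exactly when the error SD is zero", {
  sc <- scenario_config(seed = 21)
  truth <- generate_day_truth(sc, 1, 1)
  sch <- build_accel_schedule(truth, sc, tasks = TRUE)
  d0 <- generate_diary(sc, truth, sch, report_error_sd_min = 0)
  acts <- d0[d0$entry != "wear", ]
  expect_equal(acts$start, sch$start[sch$activity != "nonwear"])
  wt <- d0[d0$entry == "task" & d0$activity == "walk", ]
  expect_equal(wt$steps, sch$steps[sch$task %in% "walk"])
  expect_true(all(wt$steps >= 50 & wt$steps <= 100))
})

test_that("diary time jitter has the half-normal mean offset", {
  sc <- scenario_config(n_days = 1, seed = 99)
  offs <- unlist(lapply(1:40, function(p) {
    truth <- generate_day_truth(sc, p, 1)
    sch <- build_accel_schedule(truth, sc, tasks = TRUE)
    d <- generate_diary(sc, truth, sch, report_error_sd_min = 2)
    truth_times <- c(sch$start[sch$activity != "nonwear"], truth$day_start)
    rep_times <- c(d$start[d$entry != "wear"], d$start[d$entry == "wear"])
    (rep_times - truth_times) / 60
  }))
  # |N(0, 2)| has mean 2 * sqrt(2/pi) ~ 1.596 min
  expect_equal(mean(abs(offs)), 2 * sqrt(2 / pi), tolerance = 0.1)
})
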