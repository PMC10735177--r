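# A straight out-dwell-back day built in planar meters: 15 min out at ~8 km/h,
# 10 min dwell, 15 min back; 5 s fixes.
make_out_back <- function(leg_m = 2000, leg_s = 900, dwell_s = 600, by = 5) {
  t_out <- seq(0, leg_s, by = by)
  t_dwell <- seq(leg_s + by, leg_s + dwell_s, by = by)
  t_back <- seq(leg_s + dwell_s + by, 2 * leg_s + dwell_s, by = by)
  x <- c(
    t_out / leg_s * leg_m,
    rep(leg_m, length(t_dwell)),
    leg_m - (t_back - leg_s - dwell_s) / leg_s * leg_m
  )
  track_from_xy(x, rep(0, length(x)), c(t_out, t_dwell, t_back))
}

test_that("a dwell flanked by two long legs segments as move, stop, move", {
  tr <- make_out_back()
  seg <- detect_segments(tr, trip_params())
  expect_equal(seg$kind, c("move", "stop", "move"))
  expect_true(all(diff(seg$start) > 0))
  # stop centroid sits at the dwell location (2 km east)
  d <- haversine_m(
    seg$centroid_lat[2], seg$centroid_lon[2],
    tr$lat[1], tr$lon[1]
  )
  expect_equal(d, 2000, tolerance = 1e-3)
})

test_that("a dwell below the 5-minute threshold does not become a stop", {
  # fast legs (24 km/h) so the within-radius approach time is negligible
  tr <- make_out_back(leg_m = 6000, dwell_s = 240) # 4 min dwell
  seg <- detect_segments(tr, trip_params())
  expect_false(any(seg$kind == "stop" &
    seg$duration_min >= 4 & seg$duration_min < 5))
  expect_equal(sum(seg$kind == "move"), 1) # one continuous journey
})

test_that("a >60 min transmission gap splits one physical dwell into two stops", {
  by <- 5
  t1 <- seq(0, 1200, by = by)
  t2 <- seq(1200 + 61 * 60, 1200 + 61 * 60 + 1200, by = by)
  x <- rep(0, length(t1) + length(t2))
  tr <- track_from_xy(x, x, c(t1, t2))
  seg <- detect_segments(tr, trip_params())
  expect_equal(seg$kind, c("stop", "stop"))
  tr2 <- track_from_xy(x, x, c(t1, t2 - 31 * 60)) # 30 min gap: one stop
  seg2 <- detect_segments(tr2, trip_params())
  expect_equal(seg2$kind, "stop")
})

test_that("segments partition the retained fixes without overlap", {
  sc <- scenario_config(gps_noise_sd = 5, dropout_prob = 0.02, seed = 91)
  for (d in 1:2) {
    tr <- clean_track(generate_gps_day(sc, 1, d, "qstarz")$track)
    seg <- detect_segments(tr)
    expect_true(all(seg$i0 <= seg$i1))
    expect_true(all(seg$i0[-1] > seg$i1[-nrow(seg)])) # disjoint, ordered
    # moves never touch moves; adjacent stops only across data gaps
    kinds <- seg$kind
    adjacent_moves <- kinds[-1] == "move" & kinds[-length(kinds)] == "move"
    expect_false(any(adjacent_moves))
  }
})

test_that("compiled stay-point scan matches the plain-R reference", {
  set.seed(37)
  p <- trip_params()
  for (rep in 1:15) {
    # random dwell/leg structure, 6-10 s sampling, modest noise
    by <- sample(6:10, 1)
    segs_m <- c(0, cumsum(sample(c(300, 800, 1500), 3, TRUE)))
    tt <- xx <- numeric(0)
    t <- 0
    for (k in 1:3) {
      dwell <- sample(c(120, 420, 900), 1)
      td <- seq(t, t + dwell, by = by)
      tt <- c(tt, td)
      xx <- c(xx, rep(segs_m[k], length(td)))
      leg_t <- seq(max(tt) + by, max(tt) + 300, by = by)
      xx <- c(xx, segs_m[k] + (leg_t - leg_t[1] + by) / 300 * (segs_m[k + 1] - segs_m[k]))
      tt <- c(tt, leg_t)
      t <- max(tt) + by
    }
    xx <- xx + rnorm(length(xx), 0, 3)
    yy <- rnorm(length(xx), 0, 3)
    lat0 <- 43.26
    kx <- 6371000 * pi / 180 * cos(lat0 * pi / 180)
    ky <- 6371000 * pi / 180
    ours <- mobilitykit:::.staypoint_scan(
      xx, yy, tt,
      p$stop_radius_m, p$stop_min_duration_s, p$stop_gap_break_s
    )
    ref <- r_staypoints(
      xx, yy, tt,
      p$stop_radius_m, p$stop_min_duration_s, p$stop_gap_break_s
    )
    expect_equal(unname(ours), unname(ref))
  }
})

test_that("trip summaries add up and respect the mode threshold", {
  p <- trip_params()
  mk_leg <- function(speed_kmh, dur_s, by = 5) {
    t <- seq(0, dur_s, by = by)
    x <- t * speed_kmh / 3.6
    list(t = t, x = x)
  }
  day <- function(speed_kmh, dur_s) {
    l <- mk_leg(speed_kmh, dur_s)
    # flank with 10-min dwells so the leg is the only move
    t_pre <- seq(-600, -5, by = 5)
    t_post <- seq(max(l$t) + 5, max(l$t) + 600, by = 5)
    tr <- track_from_xy(
      c(rep(0, length(t_pre)), l$x, rep(max(l$x), length(t_post))),
      rep(0, length(t_pre) + length(l$t) + length(t_post)),
      c(t_pre, l$t, t_post)
    )
    summarize_trips(detect_segments(tr, p), tr, p)
  }
  fast <- day(40, 900)
  expect_equal(fast$frequency, 1)
  expect_equal(fast$trips$mode, "passive")
  expect_equal(fast$trips$p90_speed_kmh, 40, tolerance = 1e-6)
  slow <- day(4.5, 900)
  expect_equal(slow$trips$mode, "active")
  # two moves of 12 and 18 min -> frequency 2, total duration 30 min
  seg <- data.frame(
    kind = c("move", "stop", "move"),
    start = c(0, 720, 2000), end = c(720, 1990, 3080),
    duration_min = c(12, NA, 18), i0 = c(1, 2, 4), i1 = c(1, 3, 4),
    n_points = 1, centroid_lat = 0, centroid_lon = 0, span_m = 500
  )
  tr <- gps_track(c(0, 720, 1990, 2000), rep(0, 4), rep(0, 4), speed = rep(1, 4))
  two <- summarize_trips(seg, tr, p)
  expect_equal(two$frequency, 2)
  expect_equal(two$duration_min, 30)
})

test_that("travel mode flips sharply at the 25 km/h p90 threshold", {
  p <- trip_params()
  seg <- data.frame(
    kind = "move", start = 0, end = 600, duration_min = 10,
    i0 = 1, i1 = 3, n_points = 3, centroid_lat = 0, centroid_lon = 0,
    span_m = 500
  )
  for (sp in c(24.999, 25, 25.001)) {
    tr <- gps_track(c(0, 300, 600), rep(0, 3), rep(0, 3), speed = rep(sp, 3))
    mode <- summarize_trips(seg, tr, p)$trips$mode
    expect_equal(mode, if (sp >= 25) "passive" else "active")
  }
})
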