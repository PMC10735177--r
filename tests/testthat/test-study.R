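test_that("the orchestrator reproduces direct module calls (no hidden state)", {
  sc <- scenario_config(n_participants = 1, n_days = 1, seed = 71)
  cfg <- study_config(scenario = sc)
  rep <- run_study(cfg)
  expect_equal(nrow(rep$per_day), 1)

  truth <- generate_day_truth(sc, 1, 1)
  a <- generate_gps_day(sc, 1, 1, cfg$ref_gps, truth = truth)
  b <- generate_gps_day(sc, 1, 1, cfg$test_gps, truth = truth)
  al <- align_devices(
    clean_track(a$track, cfg$trip), clean_track(b$track, cfg$trip),
    min_hours = cfg$min_gps_hours
  )
  trips <- summarize_trips(detect_segments(al$a, cfg$trip), al$a, cfg$trip)
  ls <- lifespace_metrics(al$a, sc$home)
  expect_equal(rep$per_day$trip_frequency_ref, trips$frequency)
  expect_equal(rep$per_day$trip_duration_min_ref, trips$duration_min)
  expect_equal(rep$per_day$max_home_distance_m_ref, ls$max_home_distance_m)
  expect_equal(rep$per_day$mch_area_m2_ref, ls$mch_area_m2)
})

test_that("two devices sampling the same truth at 5 s agree exactly without noise", {
  sc <- scenario_config(
    n_participants = 2, n_days = 1,
    gps_noise_sd = 0, dropout_prob = 0, seed = 72
  )
  cfg <- study_config(
    scenario = sc, test_gps = "watch_pro_stay", # also a 5 s interval
    with_accel = FALSE
  )
  rep <- run_study(cfg)
  for (m in c(
    "trip_frequency", "trip_duration_min", "max_home_distance_m",
    "mch_area_m2"
  )) {
    expect_equal(
      rep$per_day[[paste0(m, "_test")]],
      rep$per_day[[paste0(m, "_ref")]]
    )
  }
})

test_that("days without enough joint coverage are excluded and logged", {
  sc <- scenario_config(n_participants = 1, n_days = 1, seed = 73)
  cfg <- study_config(scenario = sc, min_gps_hours = 24, with_accel = FALSE)
  rep <- run_study(cfg)
  expect_equal(nrow(rep$per_day), 0)
  expect_true(any(grepl("EXCLUDED", rep$log)))
})

test_that("report files are written in the documented layout", {
  sc <- scenario_config(n_participants = 3, n_days = 1, seed = 74)
  rep <- run_study(study_config(scenario = sc, with_accel = FALSE))
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "per_day_metrics.csv")))
  expect_true(file.exists(file.path(dir, "agreement.csv")))
  expect_true(file.exists(file.path(dir, "report.md")))
  expect_true(file.exists(file.path(dir, "log.txt")))
  md <- readLines(file.path(dir, "report.md"))
  expect_true(any(grepl("trip_frequency", md)))
})

test_that("simulate_cohort writes loadable device files", {
  # a one-hour wear window keeps the raw accel CSVs small
  sc <- scenario_config(
    n_participants = 1, n_days = 1, wear_hours = c(8, 9), seed = 75
  )
  dir <- withr::local_tempdir()
  simulate_cohort(sc, dir)
  files <- list.files(dir)
  expect_true("p01_d1_gps_qstarz.csv" %in% files)
  expect_true("p01_d1_truth.json" %in% files)
  expect_true("p01_d1_diary.csv" %in% files)
  tr <- read_qstarz_csv(file.path(dir, "p01_d1_gps_qstarz.csv"))
  expect_gt(nrow(tr), 500)
  st <- read_accel_csv(file.path(dir, "p01_d1_accel_thigh_actigraph.csv"))
  expect_equal(st$placement, "thigh")
})
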