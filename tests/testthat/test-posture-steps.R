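protocol_schedule <- function(participant = 1L, day = 1L) {
  # 5-min sit, 5-min stand, then a dwell, as in the posture protocol
  out <- data.frame(
    start = c(0, 300, 600),
    end = c(300, 600, 1500),
    activity = c("sit", "stand", "sit"),
    cadence = NA_real_, steps = NA_real_,
    is_task = c(TRUE, TRUE, FALSE), task = c("sit", "stand", NA)
  )
  attr(out, "participant") <- participant
  attr(out, "day") <- day
  out
}

test_that("posture classification refuses wrist-worn streams", {
  sc <- scenario_config(seed = 2)
  sch <- protocol_schedule()
  w <- generate_accel_stream(sc, "wrist", sch, device = "actigraph")$stream
  expect_error(classify_posture(w), "thigh")
})

test_that("synthetic sit and stand tasks classify correctly at 0.05 g noise", {
  sc <- scenario_config(accel_noise_sd = 0.05, seed = 10)
  hits <- c(sitting_lying = 0, standing = 0)
  tots <- c(sitting_lying = 0, standing = 0)
  for (p in 1:5) {
    sch <- protocol_schedule(participant = p)
    th <- generate_accel_stream(sc, "thigh", sch, device = "actigraph")$stream
    pred <- classify_posture(th)
    pa <- posture_accuracy(pred, mobilitykit:::schedule_postures(sch), trim_s = 45)
    for (cl in c("sitting_lying", "standing")) {
      row <- pa[pa$class == cl, ]
      if (nrow(row)) {
        hits[cl] <- hits[cl] + row$n_correct
        tots[cl] <- tots[cl] + row$n_epochs
      }
    }
  }
  expect_gte(hits[["sitting_lying"]] / tots[["sitting_lying"]], 0.95)
  expect_gte(hits[["standing"]] / tots[["standing"]], 0.95)
})

test_that("the 45 s trim leaves three full epochs of a 5-minute task", {
  sc <- scenario_config(accel_noise_sd = 0, seed = 11)
  sch <- protocol_schedule()
  th <- generate_accel_stream(sc, "thigh", sch, device = "actigraph")$stream
  pred <- classify_posture(th)
  pa <- posture_accuracy(
    pred,
    data.frame(start = 0, end = 300, posture = "sitting_lying"),
    trim_s = 45
  )
  expect_equal(pa$n_epochs[pa$class == "overall"], 3)
})

test_that("posture accuracy counts are arithmetic on labeled epochs", {
  pred <- data.frame(
    epoch_start = seq(0, 540, by = 60),
    posture = c(rep("standing", 9), "sitting_lying")
  )
  pa <- posture_accuracy(
    pred,
    data.frame(start = -45, end = 645, posture = "standing"),
    trim_s = 45
  )
  expect_equal(pa$accuracy_pct[pa$class == "standing"], 90)
  all_right <- posture_accuracy(
    pred[1:9, ],
    data.frame(start = -45, end = 585, posture = "standing"),
    trim_s = 45
  )
  expect_equal(all_right$accuracy_pct[all_right$class == "overall"], 100)
})

test_that("steps are recovered within two of truth and scale-invariantly", {
  sc <- scenario_config(accel_noise_sd = 0.05, seed = 20)
  sch <- simple_schedule(pre_s = 30, walk_s = 40, post_s = 30, cadence = 2)
  w <- generate_accel_stream(sc, "wrist", sch, device = "actigraph")$stream
  window <- c(sch$start[2], sch$end[2])
  n1 <- count_steps(w, window)
  expect_lte(abs(n1 - 80), 2)
  # doubling the amplitude leaves the count unchanged (adaptive threshold)
  w2 <- w
  w2$data <- w$data * 2
  expect_equal(count_steps(w2, window), n1)
  # static signal counts no steps
  still <- accel_stream(
    cbind(numeric(3000), numeric(3000), rep(1, 3000)), 30, 0, "wrist"
  )
  expect_equal(count_steps(still), 0L)
  # empty window
  expect_equal(count_steps(w, c(1e6, 1e6 + 10)), 0L)
})
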