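#' Build a posture/activity schedule from a planted day plan
#'
#' Tiles the wear window with activity blocks consistent with the GPS truth:
#' home and POI dwells are mostly sitting with occasional standing bouts,
#' active trips are walking, passive trips are sitting (vehicle). The first
#' home dwell additionally hosts the standardized protocol tasks: a 5-min sit
#' task, a 5-min stand task and a self-counted walk task of 50-100 steps.
#' Optionally a device-off (non-wear) block of 100 min is planted in the final
#' home dwell to exercise wear-time detection.
#'
#' @param truth A \code{day_truth}.
#' @param config A \code{scenario_config}.
#' @param tasks Insert the protocol task blocks (default TRUE).
#' @param plant_nonwear Plant a 100-min non-wear block (default FALSE).
#' @return Data frame of class \code{accel_schedule}: \code{start}, \code{end}
#'   (epoch s), \code{activity} (sit/stand/lie/walk/nonwear), \code{cadence}
#'   (Hz, walking only), \code{steps} (true step count, walking only),
#'   \code{is_task} and \code{task} (sit/stand/walk task labels).
#' @export
build_accel_schedule <- function(truth, config, tasks = TRUE,
                                 plant_nonwear = FALSE) {
  with_seed(substream_seed(config$seed, truth$participant, truth$day, 2L), {
    rows <- list()
    add <- function(start, end, activity, cadence = NA_real_, steps = NA_real_,
                    is_task = FALSE, task = NA_character_) {
      if (end - start < 1) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        start = start, end = end, activity = activity, cadence = cadence,
        steps = steps, is_task = is_task, task = task
      )
    }
    fill_dwell <- function(t0, t1) {
      # sitting with a standing bout roughly every half hour
      t <- t0
      while (t < t1) {
        sit_len <- min(stats::runif(1, 15, 30) * 60, t1 - t)
        add(t, t + sit_len, "sit")
        t <- t + sit_len
        if (t < t1) {
          stand_len <- min(stats::runif(1, 2, 6) * 60, t1 - t)
          add(t, t + stand_len, "stand")
          t <- t + stand_len
        }
      }
    }

    iv <- truth$intervals
    first_dwell_done <- FALSE
    last_stop <- max(which(iv$kind == "stop"))
    for (r in seq_len(nrow(iv))) {
      t0 <- iv$start[r]
      t1 <- iv$end[r]
      if (iv$kind[r] == "move") {
        if (iv$mode[r] == "active") {
          cad <- stats::runif(1, 1.6, 2.0)
          add(t0, t1, "walk", cadence = cad, steps = round((t1 - t0) * cad))
        } else {
          add(t0, t1, "sit")
        }
        next
      }
      if (tasks && !first_dwell_done && t1 - t0 > 20 * 60) {
        first_dwell_done <- TRUE
        add(t0, t0 + 300, "sit", is_task = TRUE, task = "sit")
        add(t0 + 300, t0 + 600, "stand", is_task = TRUE, task = "stand")
        n_steps <- sample(50:100, 1)
        cad <- stats::runif(1, 1.7, 2.0)
        walk_len <- n_steps / cad
        add(t0 + 630, t0 + 630 + walk_len, "walk",
          cadence = cad, steps = n_steps, is_task = TRUE, task = "walk"
        )
        fill_dwell(t0 + 630 + walk_len, t1)
        next
      }
      if (plant_nonwear && r == last_stop && t1 - t0 > 130 * 60) {
        add(t0, t1 - 100 * 60, "sit")
        add(t1 - 100 * 60, t1, "nonwear")
        next
      }
      fill_dwell(t0, t1)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("accel_schedule", "data.frame")
    attr(out, "participant") <- truth$participant
    attr(out, "day") <- truth$day
    out
  })
}

#' Simulate a raw tri-axial accelerometer stream
#'
#' Generates acceleration in g at the device rate from a posture/activity
#' schedule. The gravity vector encodes posture through the placement's axis
#' convention: on the thigh the longitudinal (x) axis is vertical while
#' standing or walking and horizontal (gravity on z) while sitting or lying;
#' on the wrist gravity stays on z throughout. Walking bouts superimpose a
#' sinusoid-plus-harmonic oscillation at the scheduled cadence, giving exactly
#' one detectable peak per true step. Worn blocks carry Gaussian sensor noise;
#' non-wear blocks are perfectly motionless so their epoch counts are zero.
#'
#' @param config A \code{scenario_config}.
#' @param placement "wrist" or "thigh".
#' @param schedule An \code{accel_schedule}; entries must tile the timeline
#'   without overlap.
#' @param device Name present in \code{config$accel_rate}.
#' @param walk_amp Walking oscillation amplitude, g.
#' @param seed_channel Integer distinguishing RNG substreams for devices that
#'   share a schedule.
#' @return List with \code{stream} (an \code{accel_stream}) and \code{truth}
#'   (the schedule, i.e. per-sample posture/activity ground truth).
#' @export
generate_accel_stream <- function(config, placement = c("wrist", "thigh"),
                                  schedule, device = "actigraph",
                                  walk_amp = 0.6, seed_channel = 30L) {
  placement <- match.arg(placement)
  if (!device %in% names(config$accel_rate)) {
    stop(sprintf("unknown accelerometer device '%s'", device))
  }
  if (is.null(schedule) || nrow(schedule) == 0) stop("empty schedule")
  sch <- schedule[order(schedule$start), , drop = FALSE]
  if (nrow(sch) > 1 && any(sch$start[-1] < sch$end[-nrow(sch)] - 1e-9)) {
    stop("schedule entries overlap")
  }
  rate <- config$accel_rate[[device]]
  t0 <- sch$start[1]
  t1 <- sch$end[nrow(sch)]
  n <- floor((t1 - t0) * rate)
  tt <- t0 + (seq_len(n) - 1) / rate

  ax <- numeric(n)
  ay <- numeric(n)
  az <- numeric(n)
  noisy <- rep(TRUE, n)
  # samples are time-ordered: each schedule row owns a contiguous index range
  bnd <- findInterval(sch$start - 1e-9, tt) + 1L
  bnd[1] <- 1L
  ends <- c(bnd[-1] - 1L, n)
  for (r in seq_len(nrow(sch))) {
    if (ends[r] < bnd[r]) next
    sel <- bnd[r]:ends[r]
    act <- sch$activity[r]
    if (placement == "thigh") {
      g <- switch(act,
        stand = , walk = c(1, 0, 0), # thigh vertical
        sit = , lie = , nonwear = c(0, 0, 1) # thigh horizontal
      )
    } else {
      g <- c(0, 0, 1)
    }
    ax[sel] <- g[1]
    ay[sel] <- g[2]
    az[sel] <- g[3]
    if (act == "walk") {
      cad <- sch$cadence[r]
      ph <- 2 * pi * cad * (tt[sel] - sch$start[r])
      # fundamental peaks once per step; small second harmonic for shape
      osc <- walk_amp * (sin(ph) + 0.25 * sin(2 * ph + 0.7))
      if (placement == "thigh") {
        ax[sel] <- ax[sel] + osc
        ay[sel] <- ay[sel] + 0.3 * walk_amp * cos(ph)
      } else {
        az[sel] <- az[sel] + osc
        ay[sel] <- ay[sel] + 0.4 * walk_amp * cos(ph)
      }
    }
    if (act == "nonwear") noisy[sel] <- FALSE
  }

  participant <- attr(schedule, "participant") %||% 0L
  day <- attr(schedule, "day") %||% 0L
  with_seed(substream_seed(config$seed, participant, day, seed_channel), {
    if (config$accel_noise_sd > 0 && any(noisy)) {
      k <- sum(noisy)
      ax[noisy] <- ax[noisy] + stats::rnorm(k, 0, config$accel_noise_sd)
      ay[noisy] <- ay[noisy] + stats::rnorm(k, 0, config$accel_noise_sd)
      az[noisy] <- az[noisy] + stats::rnorm(k, 0, config$accel_noise_sd)
    }
    list(
      stream = accel_stream(
        data = cbind(x = ax, y = ay, z = az), rate = rate,
        start = t0, placement = placement, device = device
      ),
      truth = sch
    )
  })
}

#' Simulate a self-report diary for one participant-day
#'
#' Produces the diary rows a participant would log: one row per meaningful
#' activity bout (posture or walking), the protocol task rows with the
#' self-counted steps of the walk task, and wear on/off times. Start and end
#' times are jittered with Gaussian reporting error.
#'
#' @param config A \code{scenario_config}.
#' @param truth The \code{day_truth} for the day.
#' @param schedule The day's \code{accel_schedule} (activity ground truth).
#' @param report_error_sd_min SD of the reporting error on times, minutes.
#' @return Data frame of class \code{diary_table}: \code{date}, \code{entry}
#'   (activity/task/wear), \code{activity}, \code{start}, \code{end} (epoch
#'   s, jittered), \code{steps} (walk task only).
#' @export
generate_diary <- function(config, truth, schedule, report_error_sd_min = 2) {
  with_seed(substream_seed(config$seed, truth$participant, truth$day, 3L), {
    jit <- function(t) t + stats::rnorm(length(t), 0, report_error_sd_min * 60)
    date <- as.Date(as.POSIXct(truth$day_start, origin = "1970-01-01", tz = "UTC"))
    rows <- data.frame(
      date = date,
      entry = ifelse(schedule$is_task, "task", "activity"),
      activity = schedule$activity,
      start = jit(schedule$start),
      end = jit(schedule$end),
      steps = schedule$steps
    )
    rows <- rows[rows$activity != "nonwear", , drop = FALSE]
    wear <- data.frame(
      date = date, entry = "wear", activity = "worn",
      start = jit(truth$day_start), end = jit(truth$day_end),
      steps = NA_real_
    )
    out <- rbind(rows, wear)
    rownames(out) <- NULL
    class(out) <- c("diary_table", "data.frame")
    out
  })
}
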