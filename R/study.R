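#' Study configuration for the end-to-end validation runner
#'
#' Bundles the synthetic scenario with every pipeline parameter block and the
#' device roles: which GPS device is the reference (gold-standard logger) and
#' which is under test, and likewise for the wrist accelerometers. The thigh
#' posture stream always comes from the reference accelerometer.
#'
#' @param scenario A \code{scenario_config}.
#' @param trip A \code{trip_params}.
#' @param wear A \code{wear_params}.
#' @param intensity An \code{intensity_params}.
#' @param posture A \code{posture_params}.
#' @param ref_gps,test_gps Device names in \code{scenario$gps_interval}.
#' @param ref_accel,test_accel Device names in \code{scenario$accel_rate}.
#' @param min_gps_hours Minimum joint GPS coverage for a valid day.
#' @param with_accel Run the accelerometer arm (default TRUE).
#' @return List of class \code{study_config}.
#' @export
study_config <- function(scenario = scenario_config(),
                         trip = trip_params(),
                         wear = wear_params(),
                         intensity = intensity_params(),
                         posture = posture_params(),
                         ref_gps = "qstarz", test_gps = "watch_s2",
                         ref_accel = "actigraph", test_accel = "watch_s2",
                         min_gps_hours = 8,
                         with_accel = TRUE) {
  stopifnot(
    ref_gps %in% names(scenario$gps_interval),
    test_gps %in% names(scenario$gps_interval),
    ref_accel %in% names(scenario$accel_rate),
    test_accel %in% names(scenario$accel_rate)
  )
  structure(
    list(
      scenario = scenario, trip = trip, wear = wear,
      intensity = intensity, posture = posture,
      ref_gps = ref_gps, test_gps = test_gps,
      ref_accel = ref_accel, test_accel = test_accel,
      min_gps_hours = min_gps_hours, with_accel = with_accel
    ),
    class = "study_config"
  )
}

# map activity labels to the two-posture scheme; nonwear rows are dropped
schedule_postures <- function(schedule) {
  keep <- schedule$activity != "nonwear"
  data.frame(
    start = schedule$start[keep],
    end = schedule$end[keep],
    posture = ifelse(schedule$activity[keep] %in% c("sit", "lie"),
      "sitting_lying", "standing"
    )
  )
}

#' Per-class posture accuracy against labeled windows
#'
#' Compares per-epoch posture predictions with labeled task or diary windows.
#' Each window is trimmed by \code{trim_s} at both ends (transition removal)
#' and only epochs fully inside a trimmed window are evaluated.
#'
#' @param pred Data frame from \code{\link{classify_posture}}
#'   (\code{epoch_start}, \code{posture}).
#' @param windows Data frame with \code{start}, \code{end}, \code{posture}.
#' @param trim_s Seconds trimmed from each window end.
#' @param epoch_s Epoch length, seconds.
#' @return Data frame: one row per class plus an "overall" row, with
#'   \code{n_epochs}, \code{n_correct}, \code{accuracy_pct} (NA when a class
#'   has no evaluable epochs).
#' @export
posture_accuracy <- function(pred, windows, trim_s = 45, epoch_s = 60) {
  truth <- rep(NA_character_, nrow(pred))
  for (r in seq_len(nrow(windows))) {
    w0 <- windows$start[r] + trim_s
    w1 <- windows$end[r] - trim_s
    sel <- pred$epoch_start >= w0 & (pred$epoch_start + epoch_s) <= w1
    truth[sel] <- windows$posture[r]
  }
  ok <- !is.na(truth)
  classes <- sort(unique(truth[ok]))
  rows <- lapply(c(classes, "overall"), function(cl) {
    sel <- if (cl == "overall") ok else ok & truth == cl
    n <- sum(sel)
    nc <- sum(pred$posture[sel] == truth[sel])
    data.frame(
      class = cl, n_epochs = n, n_correct = nc,
      accuracy_pct = if (n > 0) nc / n * 100 else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Run the full synthetic validation study
#'
#' For every participant-day: plants the ground-truth day, simulates the
#' reference and test GPS devices from the same truth, cleans and aligns
#' them, segments stops/trips and computes life-space metrics per device;
#' simulates the wrist accelerometers and the thigh stream, computes counts,
#' Choi wear time, intensity minutes, walk-task steps and posture labels.
#' Days with insufficient joint GPS coverage are excluded and logged. Device
#' agreement is then summarised per metric across retained participant-days.
#' Deterministic: the same configuration (including its seed) reproduces the
#' report exactly.
#'
#' @param config A \code{study_config}.
#' @return List of class \code{validation_report}: \code{per_day} (wide data
#'   frame of per-day metrics for both devices), \code{agreement} (data
#'   frame: one row per compared metric), \code{posture} (per-class accuracy
#'   pooled over days), \code{protocol_totals} (per-participant totals across
#'   the protocol days), \code{log} (character), \code{config}.
#' @export
run_study <- function(config) {
  sc <- config$scenario
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  day_rows <- list()
  step_rows <- list()
  posture_days <- list()

  for (p in seq_len(sc$n_participants)) {
    for (d in seq_len(sc$n_days)) {
      truth <- generate_day_truth(sc, p, d)
      ref <- generate_gps_day(sc, p, d, device = config$ref_gps, truth = truth)
      tst <- generate_gps_day(sc, p, d, device = config$test_gps, truth = truth)

      ref_tr <- clean_track(ref$track, config$trip)
      tst_tr <- clean_track(tst$track, config$trip)
      note(
        "p%02d d%d: %d/%d fixes kept (%s), %d/%d (%s)",
        p, d, nrow(ref_tr), nrow(ref$track), config$ref_gps,
        nrow(tst_tr), nrow(tst$track), config$test_gps
      )
      al <- align_devices(ref_tr, tst_tr, min_hours = config$min_gps_hours)
      if (!al$valid) {
        note(
          "p%02d d%d: EXCLUDED, joint GPS coverage %.1f h < %g h",
          p, d, al$overlap_hours, config$min_gps_hours
        )
        next
      }

      gps_side <- function(tr) {
        seg <- detect_segments(tr, config$trip)
        trips <- summarize_trips(seg, tr, config$trip)
        ls <- lifespace_metrics(tr, sc$home)
        c(
          trip_frequency = trips$frequency,
          trip_duration_min = trips$duration_min,
          active_min = trips$active_min,
          passive_min = trips$passive_min,
          max_home_distance_m = ls$max_home_distance_m,
          mch_perimeter_m = ls$mch_perimeter_m,
          mch_area_m2 = ls$mch_area_m2
        )
      }
      mref <- gps_side(al$a)
      mtst <- gps_side(al$b)
      row <- data.frame(participant = p, day = d, true_trips = truth$n_trips)
      for (nm in names(mref)) {
        row[[paste0(nm, "_ref")]] <- unname(mref[nm])
        row[[paste0(nm, "_test")]] <- unname(mtst[nm])
      }

      if (config$with_accel) {
        schedule <- build_accel_schedule(truth, sc, tasks = TRUE)
        wr_ref <- generate_accel_stream(sc, "wrist", schedule,
          device = config$ref_accel, seed_channel = 31L
        )
        wr_tst <- generate_accel_stream(sc, "wrist", schedule,
          device = config$test_accel, seed_channel = 32L
        )
        thigh <- generate_accel_stream(sc, "thigh", schedule,
          device = config$ref_accel, seed_channel = 33L
        )

        ep_ref <- compute_counts(wr_ref$stream)
        ep_tst <- compute_counts(wr_tst$stream)
        n_ep <- min(nrow(ep_ref), nrow(ep_tst))
        full <- !ep_ref$partial[seq_len(n_ep)] & !ep_tst$partial[seq_len(n_ep)]
        vm_ref <- ep_ref$vm[seq_len(n_ep)][full]
        vm_tst <- ep_tst$vm[seq_len(n_ep)][full]

        wear_ref <- detect_nonwear(vm_ref, config$wear)
        wear_tst <- detect_nonwear(vm_tst, config$wear)
        joint_wear <- wear_ref$wear & wear_tst$wear
        int_ref <- classify_intensity(vm_ref, config$intensity, wear = joint_wear)
        int_tst <- classify_intensity(vm_tst, config$intensity, wear = joint_wear)

        row$wear_min_ref <- wear_ref$wear_min
        row$wear_min_test <- wear_tst$wear_min
        row$sedentary_min_ref <- int_ref$sedentary_min
        row$sedentary_min_test <- int_tst$sedentary_min
        row$non_sedentary_min_ref <- int_ref$non_sedentary_min
        row$non_sedentary_min_test <- int_tst$non_sedentary_min
        row$mean_cpm_ref <- mean(vm_ref[joint_wear])
        row$mean_cpm_test <- mean(vm_tst[joint_wear])

        wt <- schedule[schedule$is_task %in% TRUE & schedule$task %in% "walk", ]
        if (nrow(wt) == 1) {
          step_rows[[length(step_rows) + 1L]] <- data.frame(
            participant = p, day = d,
            steps_true = wt$steps,
            steps_device = count_steps(
              wr_tst$stream,
              window = c(wt$start, wt$end)
            )
          )
        }

        pp <- classify_posture(thigh$stream, config$posture)
        pa <- posture_accuracy(pp, schedule_postures(schedule),
          trim_s = config$posture$task_trim_s
        )
        posture_days[[length(posture_days) + 1L]] <-
          pa[pa$class != "overall", , drop = FALSE]
      }

      day_rows[[length(day_rows) + 1L]] <- row
    }
  }

  per_day <- if (length(day_rows)) {
    do.call(rbind, lapply(day_rows, function(r) {
      # pad rows from GPS-only days so rbind keeps one schema
      miss <- setdiff(names(day_rows[[which.max(lengths(day_rows))]]), names(r))
      for (m in miss) r[[m]] <- NA_real_
      r
    }))
  } else {
    data.frame()
  }
  note("retained %d participant-days", nrow(per_day))

  metrics <- c(
    "trip_frequency", "trip_duration_min", "active_min", "passive_min",
    "max_home_distance_m", "mch_perimeter_m", "mch_area_m2"
  )
  if (config$with_accel) {
    metrics <- c(metrics, "sedentary_min", "non_sedentary_min", "mean_cpm", "wear_min")
  }
  empty_agreement <- data.frame(
    measure = character(), n = integer(), bias = numeric(),
    loa_low = numeric(), loa_high = numeric(), rho = numeric(),
    pct_agreement_raw = numeric(), pct_agreement_sym = numeric(),
    test = character(), p_value = numeric()
  )
  agreement <- do.call(rbind, lapply(metrics, function(m) {
    a <- per_day[[paste0(m, "_test")]]
    b <- per_day[[paste0(m, "_ref")]]
    if (is.null(a) || sum(!(is.na(a) | is.na(b))) < 3) return(NULL)
    s <- agreement_summary(a, b, measure = m)
    data.frame(
      measure = m, n = s$n, bias = s$bias,
      loa_low = s$loa_low, loa_high = s$loa_high,
      rho = s$rho, pct_agreement_raw = s$pct_agreement_raw,
      pct_agreement_sym = s$pct_agreement_sym,
      test = s$test_method, p_value = s$p_value
    )
  }))
  if (is.null(agreement)) agreement <- empty_agreement

  steps <- if (length(step_rows)) do.call(rbind, step_rows) else data.frame()
  if (nrow(steps) >= 2) {
    sba <- bland_altman(steps$steps_device, steps$steps_true)
    note(
      "steps: n = %d walk tasks, bias = %.2f, LoA [%.2f, %.2f]",
      sba$n, sba$bias, sba$loa_low, sba$loa_high
    )
  }

  posture <- if (length(posture_days)) {
    pooled <- do.call(rbind, posture_days)
    agg <- stats::aggregate(pooled[c("n_epochs", "n_correct")],
      by = list(class = pooled$class), FUN = sum
    )
    agg <- rbind(agg, data.frame(
      class = "overall",
      n_epochs = sum(agg$n_epochs), n_correct = sum(agg$n_correct)
    ))
    agg$accuracy_pct <- ifelse(agg$n_epochs > 0,
      agg$n_correct / agg$n_epochs * 100, NA_real_
    )
    agg
  } else {
    data.frame()
  }

  totals <- if (nrow(per_day)) {
    agg <- stats::aggregate(
      per_day[c("trip_frequency_ref", "trip_frequency_test",
                "trip_duration_min_ref", "trip_duration_min_test")],
      by = list(participant = per_day$participant), FUN = sum
    )
    names(agg) <- sub("$", "", names(agg))
    agg
  } else {
    data.frame()
  }

  out <- list(
    per_day = per_day, agreement = agreement, steps = steps,
    posture = posture, protocol_totals = totals,
    log = log, config = config
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d participant-days retained\n", nrow(x$per_day)
  ))
  if (nrow(x$agreement)) {
    cat("Device agreement (test vs reference):\n")
    print.data.frame(
      x$agreement[c("measure", "n", "bias", "loa_low", "loa_high", "rho",
                    "pct_agreement_sym", "p_value")],
      row.names = FALSE, digits = 3
    )
  }
  if (nrow(x$steps) >= 2) {
    ba <- bland_altman(x$steps$steps_device, x$steps$steps_true)
    cat(sprintf(
      "Walk-task steps: n = %d, bias = %.2f steps, LoA [%.2f, %.2f]\n",
      ba$n, ba$bias, ba$loa_low, ba$loa_high
    ))
  }
  if (nrow(x$posture)) {
    cat("Posture accuracy (%):\n")
    print.data.frame(x$posture, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits per-day metrics, the agreement table, step and posture results and
#' the per-participant protocol totals as CSV, the processing log as text,
#' and a Markdown summary.
#'
#' @param report A \code{validation_report}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$per_day, file.path(dir, "per_day_metrics.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$agreement, file.path(dir, "agreement.csv"),
    row.names = FALSE
  )
  if (nrow(report$steps)) {
    utils::write.csv(report$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  }
  if (nrow(report$posture)) {
    utils::write.csv(report$posture, file.path(dir, "posture.csv"),
      row.names = FALSE
    )
  }
  if (nrow(report$protocol_totals)) {
    utils::write.csv(report$protocol_totals,
      file.path(dir, "protocol_totals.csv"),
      row.names = FALSE
    )
  }
  writeLines(report$log, file.path(dir, "log.txt"))

  md <- c(
    "# Device validation report", "",
    sprintf("Participant-days retained: %d", nrow(report$per_day)), "",
    "## Agreement (test vs reference)", "",
    "| measure | n | bias | LoA low | LoA high | rho | % agreement | p |",
    "|---|---|---|---|---|---|---|---|"
  )
  if (nrow(report$agreement)) {
    md <- c(md, apply(report$agreement, 1, function(r) {
      sprintf(
        "| %s | %s | %.3g | %.3g | %.3g | %.3g | %.1f | %.3g |",
        r[["measure"]], r[["n"]], as.numeric(r[["bias"]]),
        as.numeric(r[["loa_low"]]), as.numeric(r[["loa_high"]]),
        as.numeric(r[["rho"]]), as.numeric(r[["pct_agreement_sym"]]),
        as.numeric(r[["p_value"]])
      )
    }))
  }
  if (nrow(report$posture)) {
    md <- c(md, "", "## Posture accuracy", "")
    md <- c(md, apply(report$posture, 1, function(r) {
      sprintf(
        "- %s: %.1f%% (%s epochs)",
        r[["class"]], as.numeric(r[["accuracy_pct"]]), r[["n_epochs"]]
      )
    }))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Write a synthetic cohort to disk in the device file formats
#'
#' Materialises the scenario as the files a field deployment would produce:
#' per participant-day a Qstarz-style CSV per GPS device, raw accelerometer
#' CSVs (both wrists and thigh), the diary CSV, and the ground-truth JSON.
#'
#' @param scenario A \code{scenario_config}.
#' @param dir Output directory.
#' @param gps_devices,accel_devices Device names to materialise.
#' @return The directory, invisibly.
#' @export
simulate_cohort <- function(scenario, dir,
                            gps_devices = c("qstarz", "watch_s2"),
                            accel_devices = c("actigraph", "watch_s2")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in seq_len(scenario$n_participants)) {
    for (d in seq_len(scenario$n_days)) {
      truth <- generate_day_truth(scenario, p, d)
      stub <- file.path(dir, sprintf("p%02d_d%d", p, d))
      write_truth_json(truth, paste0(stub, "_truth.json"))
      for (dev in gps_devices) {
        g <- generate_gps_day(scenario, p, d, device = dev, truth = truth)
        write_qstarz_csv(g$track, sprintf("%s_gps_%s.csv", stub, dev))
      }
      schedule <- build_accel_schedule(truth, scenario, tasks = TRUE)
      ch <- 40L
      for (dev in accel_devices) {
        a <- generate_accel_stream(scenario, "wrist", schedule,
          device = dev, seed_channel = ch
        )
        write_accel_csv(a$stream, sprintf("%s_accel_wrist_%s.csv", stub, dev))
        ch <- ch + 1L
      }
      th <- generate_accel_stream(scenario, "thigh", schedule,
        device = accel_devices[1], seed_channel = ch
      )
      write_accel_csv(th$stream, sprintf("%s_accel_thigh_%s.csv", stub, accel_devices[1]))
      write_diary_csv(
        generate_diary(scenario, truth, schedule),
        sprintf("%s_diary.csv", stub)
      )
    }
  }
  invisible(dir)
}
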