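#' Scenario configuration for the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: a home location, a set
#' of points of interest (POIs), how many out-of-home outings are planted per
#' day, walking- and vehicle-speed ranges, dwell times, device-specific GPS
#' sampling intervals and accelerometer rates, positional noise and dropout,
#' and a daily wear window. One outing plants two trips (out and back), with a
#' dwell at the POI between them.
#'
#' Defaults mirror a typical older-adult validation deployment: a 5 s
#' reference logger and a 20 s smartwatch (10 s / 5 s alternative watch
#' configurations are also defined); 30 Hz research accelerometer against a
#' 25 Hz (or 50 Hz) watch; walking legs at 3-6 km/h, vehicle legs at
#' 30-60 km/h; POI dwells of at least 6 min so every planted stop exceeds the
#' 5-min detection threshold; wear from 08:00 to 20:00.
#'
#' @param n_participants,n_days Cohort size and days per participant.
#' @param home \code{c(lat, lon)} degrees.
#' @param poi_list Data frame with \code{lat}, \code{lon} (one row per POI);
#'   default: four POIs at 0.8-10 km from home.
#' @param outings_per_day Integer range \code{c(min, max)} of outings planted
#'   per day (each outing = 2 trips).
#' @param leg_speed_active,leg_speed_passive Speed ranges, km/h.
#' @param active_max_dist_m POIs within this distance are reached on foot.
#' @param stop_dwell_min Range of POI dwell, minutes (min must exceed 5).
#' @param gps_noise_sd Positional noise SD, meters.
#' @param gps_interval Named numeric: sampling interval (s) per GPS device.
#' @param dropout_prob Per-fix Bernoulli dropout probability.
#' @param accel_rate Named numeric: sampling rate (Hz) per accelerometer.
#' @param accel_noise_sd Accelerometer noise SD, g.
#' @param wear_hours \code{c(start, end)} clock hours of the daily wear window.
#' @param stop_radius_m Stop radius used to annotate detectable trip windows
#'   in the ground truth (should match the detector's \code{stop_radius_m}).
#' @param start_date Date of day 1 (timestamps are tz-naive local time).
#' @param seed Integer seed; fully determines all generated data.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_participants = 10,
                            n_days = 3,
                            home = c(43.2609, -79.9192),
                            poi_list = NULL,
                            outings_per_day = c(1, 2),
                            leg_speed_active = c(3, 6),
                            leg_speed_passive = c(30, 60),
                            active_max_dist_m = 2000,
                            stop_dwell_min = c(6, 25),
                            gps_noise_sd = 3,
                            gps_interval = c(
                              qstarz = 5, watch_s2 = 20,
                              watch_pro_periodic = 10, watch_pro_stay = 5
                            ),
                            dropout_prob = 0.02,
                            accel_rate = c(actigraph = 30, watch_s2 = 25, watch_pro = 50),
                            accel_noise_sd = 0.05,
                            wear_hours = c(8, 20),
                            stop_radius_m = 75,
                            start_date = as.Date("2021-03-01"),
                            seed = 20210301) {
  if (is.null(poi_list)) {
    poi <- rbind(
      dest_point(home[1], home[2], 40, 800),
      dest_point(home[1], home[2], 130, 1500),
      dest_point(home[1], home[2], 220, 6000),
      dest_point(home[1], home[2], 310, 10000)
    )
    poi_list <- data.frame(lat = poi[, 1], lon = poi[, 2])
  }
  cfg <- list(
    n_participants = n_participants, n_days = n_days,
    home = home, poi_list = poi_list,
    outings_per_day = outings_per_day,
    leg_speed_active = leg_speed_active,
    leg_speed_passive = leg_speed_passive,
    active_max_dist_m = active_max_dist_m,
    stop_dwell_min = stop_dwell_min,
    gps_noise_sd = gps_noise_sd,
    gps_interval = gps_interval,
    dropout_prob = dropout_prob,
    accel_rate = accel_rate,
    accel_noise_sd = accel_noise_sd,
    wear_hours = wear_hours,
    stop_radius_m = stop_radius_m,
    start_date = start_date,
    seed = as.integer(seed)
  )
  stopifnot(
    n_participants >= 1, n_days >= 1,
    all(gps_interval > 0), all(accel_rate > 0),
    all(leg_speed_active > 0), all(leg_speed_passive > 0),
    stop_dwell_min[1] > 5, gps_noise_sd >= 0,
    dropout_prob >= 0, dropout_prob < 1,
    wear_hours[2] > wear_hours[1]
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d participants x %d days, %d POIs, seed %d\n",
    x$n_participants, x$n_days, nrow(x$poi_list), x$seed
  ))
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic substream seed for (participant, day, channel); kept < 2^31
substream_seed <- function(seed, participant, day, channel = 0L) {
  (as.double(seed) + 7919 * participant + 104729 * day + 15485863 * channel) %%
    2147483647
}

#' Plant the ground-truth day plan for one participant-day
#'
#' Builds the true timeline the sensors will observe: a stop at home, then 1-2
#' outings, each an out-leg to a POI, a dwell there, and a return leg, with
#' home dwells between. POIs within \code{active_max_dist_m} are visited on
#' foot at a walking speed; farther POIs by vehicle. Every planted stop dwells
#' longer than 5 min within a point location, and every planted trip exceeds
#' 3 min and 100 m, so a correct detector must recover all of them from
#' noise-free data. The plan is fully determined by the scenario seed and the
#' (participant, day) indices and is shared by all devices.
#'
#' @param config A \code{scenario_config}.
#' @param participant,day 1-based indices.
#' @return List of class \code{day_truth}: \code{intervals} (start, end, kind
#'   stop/move, mode, lat/lon endpoints), \code{trips} (the move intervals),
#'   \code{n_trips}, \code{day_start}, \code{day_end}.
#' @export
generate_day_truth <- function(config, participant, day) {
  day0 <- as.numeric(as.POSIXct(config$start_date, tz = "UTC")) +
    (day - 1) * 86400
  t_start <- day0 + config$wear_hours[1] * 3600
  t_end <- day0 + config$wear_hours[2] * 3600
  home <- config$home

  with_seed(substream_seed(config$seed, participant, day, 1L), {
    n_out <- sample(seq(config$outings_per_day[1], config$outings_per_day[2]), 1)
    iv <- list()
    t <- t_start
    add <- function(start, end, kind, mode, from, to, poi = NA_integer_) {
      iv[[length(iv) + 1L]] <<- data.frame(
        start = start, end = end, kind = kind, mode = mode,
        from_lat = from[1], from_lon = from[2],
        to_lat = to[1], to_lon = to[2], poi = poi
      )
    }
    for (k in seq_len(n_out)) {
      # dwell at home before departing
      dwell_home <- stats::runif(1, 40, 90) * 60
      depart <- t + dwell_home
      p <- sample(nrow(config$poi_list), 1)
      poi <- c(config$poi_list$lat[p], config$poi_list$lon[p])
      dist <- haversine_m(home[1], home[2], poi[1], poi[2])
      active <- dist <= config$active_max_dist_m
      rng <- if (active) config$leg_speed_active else config$leg_speed_passive
      v_out <- stats::runif(1, rng[1], rng[2])
      v_back <- stats::runif(1, rng[1], rng[2])
      leg_out <- dist / (v_out / 3.6)
      leg_back <- dist / (v_back / 3.6)
      dwell_poi <- stats::runif(1, config$stop_dwell_min[1], config$stop_dwell_min[2]) * 60
      arrive_back <- depart + leg_out + dwell_poi + leg_back
      if (arrive_back > t_end - 45 * 60) break # outing would not fit; keep the day home-bound
      mode <- if (active) "active" else "passive"
      add(t, depart, "stop", "none", home, home)
      add(depart, depart + leg_out, "move", mode, home, poi, p)
      add(depart + leg_out, depart + leg_out + dwell_poi, "stop", "none", poi, poi, p)
      add(depart + leg_out + dwell_poi, arrive_back, "move", mode, poi, home, p)
      t <- arrive_back
    }
    add(t, t_end, "stop", "none", home, home)
    intervals <- do.call(rbind, iv)
    rownames(intervals) <- NULL
    trips <- intervals[intervals$kind == "move", , drop = FALSE]
    rownames(trips) <- NULL
    out <- list(
      intervals = intervals, trips = trips, n_trips = nrow(trips),
      day_start = t_start, day_end = t_end,
      home = home, participant = participant, day = day
    )
    class(out) <- "day_truth"
    out
  })
}

# true position (lat, lon) at arbitrary times, from a day_truth plan
truth_position <- function(truth, times) {
  iv <- truth$intervals
  lat <- numeric(length(times))
  lon <- numeric(length(times))
  idx <- findInterval(times, iv$start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(iv)] <- nrow(iv)
  for (r in unique(idx)) {
    sel <- idx == r
    if (iv$kind[r] == "stop") {
      lat[sel] <- iv$from_lat[r]
      lon[sel] <- iv$from_lon[r]
    } else {
      f <- (times[sel] - iv$start[r]) / (iv$end[r] - iv$start[r])
      f <- pmin(pmax(f, 0), 1)
      lat[sel] <- iv$from_lat[r] + f * (iv$to_lat[r] - iv$from_lat[r])
      lon[sel] <- iv$from_lon[r] + f * (iv$to_lon[r] - iv$from_lon[r])
    }
  }
  cbind(lat = lat, lon = lon)
}

#' Simulate one participant-day GPS track for a device
#'
#' Samples the planted day plan at the device's fix interval along piecewise
#' constant-speed legs, applies isotropic Gaussian positional noise in the
#' local tangent plane and i.i.d. Bernoulli dropouts. The returned ground
#' truth carries, per planted trip, both the physical leg times and the
#' detectable move window on this device's sampling grid: the fixes strictly
#' outside the \code{stop_radius_m} neighbourhoods of the flanking dwell
#' locations, which is the window a correct stop/trip detector reports.
#'
#' @param config A \code{scenario_config}.
#' @param participant,day 1-based indices.
#' @param device Name present in \code{config$gps_interval}.
#' @param truth Optional precomputed \code{day_truth} (so several devices
#'   share one plan); generated from the scenario seed when NULL.
#' @return List with \code{track} (a \code{gps_track}) and \code{truth} (the
#'   \code{day_truth}, with a \code{detectable} data frame added).
#' @export
generate_gps_day <- function(config, participant, day, device = "qstarz",
                             truth = NULL) {
  if (!device %in% names(config$gps_interval)) {
    stop(sprintf("unknown GPS device '%s'", device))
  }
  interval <- config$gps_interval[[device]]
  if (is.null(truth)) truth <- generate_day_truth(config, participant, day)

  times <- seq(truth$day_start, truth$day_end, by = interval)
  pos <- truth_position(truth, times)

  dev_channel <- 10L + match(device, names(config$gps_interval))
  track <- with_seed(substream_seed(config$seed, participant, day, dev_channel), {
    keep <- stats::runif(length(times)) >= config$dropout_prob
    keep[1] <- TRUE # the logger always records its first fix
    lat <- pos[keep, "lat"]
    lon <- pos[keep, "lon"]
    if (config$gps_noise_sd > 0) {
      m_per_deg <- 6371000 * pi / 180
      ny <- stats::rnorm(length(lat), 0, config$gps_noise_sd)
      nx <- stats::rnorm(length(lat), 0, config$gps_noise_sd)
      lat <- lat + ny / m_per_deg
      lon <- lon + nx / (m_per_deg * cos(lat * pi / 180))
    }
    gps_track(times[keep], lat, lon,
      device = device,
      id = sprintf("p%02d_d%d", participant, day)
    )
  })

  # detectable move window per trip on this device's grid
  det <- lapply(seq_len(nrow(truth$trips)), function(r) {
    tr <- truth$trips[r, ]
    sel <- times >= tr$start & times <= tr$end
    tt <- times[sel]
    pp <- truth_position(truth, tt)
    d_from <- haversine_m(tr$from_lat, tr$from_lon, pp[, "lat"], pp[, "lon"])
    d_to <- haversine_m(tr$to_lat, tr$to_lon, pp[, "lat"], pp[, "lon"])
    out_idx <- which(d_from > config$stop_radius_m & d_to > config$stop_radius_m)
    if (length(out_idx) == 0) {
      data.frame(det_start = NA_real_, det_end = NA_real_, mode = tr$mode)
    } else {
      data.frame(
        det_start = tt[min(out_idx)], det_end = tt[max(out_idx)],
        mode = tr$mode
      )
    }
  })
  truth$detectable <- if (length(det)) do.call(rbind, det) else
    data.frame(det_start = numeric(), det_end = numeric(), mode = character())

  list(track = track, truth = truth)
}

#' @export
print.day_truth <- function(x, ...) {
  cat(sprintf(
    "<day_truth> participant %d day %d: %d planted trips, %d intervals\n",
    x$participant, x$day, x$n_trips, nrow(x$intervals)
  ))
  invisible(x)
}
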