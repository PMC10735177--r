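#' Construct a GPS track
#'
#' A \code{gps_track} is a data frame with one row per logged fix, columns
#' \code{time} (POSIXct or numeric seconds), \code{lat}, \code{lon}
#' (decimal degrees), optional logged \code{speed} (km/h), plus \code{device}
#' and \code{id} attributes. Timestamps must be strictly increasing.
#'
#' @param time POSIXct or numeric epoch seconds.
#' @param lat,lon Decimal degrees.
#' @param speed Optional logged speed in km/h (NA where absent).
#' @param device Device identifier string.
#' @param id Participant/day identifier string.
#' @return A \code{gps_track} data frame.
#' @export
gps_track <- function(time, lat, lon, speed = NULL, device = "gps", id = "") {
  time <- as.numeric(time)
  n <- length(time)
  if (length(lat) != n || length(lon) != n) {
    stop("time, lat and lon must have equal length")
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    stop("coordinates out of range")
  }
  if (is.null(speed)) speed <- rep(NA_real_, n)
  out <- data.frame(time = time, lat = lat, lon = lon, speed = as.numeric(speed))
  class(out) <- c("gps_track", "data.frame")
  attr(out, "device") <- device
  attr(out, "id") <- id
  out
}

#' @export
print.gps_track <- function(x, ...) {
  cat(sprintf(
    "<gps_track> %d fixes, device '%s'%s\n", nrow(x),
    attr(x, "device") %||% "?",
    if (nrow(x)) sprintf(
      ", %s to %s",
      format(as.POSIXct(x$time[1], origin = "1970-01-01", tz = "UTC")),
      format(as.POSIXct(x$time[nrow(x)], origin = "1970-01-01", tz = "UTC"))
    ) else ""
  ))
  invisible(x)
}

#' Stop/trip detection parameters
#'
#' Defaults follow the stay-point detection settings used for older-adult
#' mobility studies: a stop is at least 5 min within a 75 m radius of the
#' running median position; a gap over 60 min splits a stop; a move (trip)
#' must exceed 3 min and span at least 100 m; trips whose 90th-percentile
#' speed is at least 25 km/h are passive (motorized); fixes implying over
#' 160 km/h are discarded as positional errors.
#'
#' @param max_speed_kmh Cleaning threshold, km/h.
#' @param stop_min_duration_s Minimum stop dwell, seconds.
#' @param stop_radius_m Maximum distance from the running median, meters.
#' @param stop_gap_break_s Data gap that splits a stop, seconds.
#' @param move_min_duration_s Minimum trip duration, seconds.
#' @param move_min_span_m Minimum distance between a trip's farthest points, meters.
#' @param passive_speed_percentile Percentile of point speeds used for mode.
#' @param passive_speed_threshold_kmh Passive-mode speed threshold, km/h.
#' @return A list of class \code{trip_params}.
#' @export
trip_params <- function(max_speed_kmh = 160,
                        stop_min_duration_s = 5 * 60,
                        stop_radius_m = 75,
                        stop_gap_break_s = 60 * 60,
                        move_min_duration_s = 3 * 60,
                        move_min_span_m = 100,
                        passive_speed_percentile = 90,
                        passive_speed_threshold_kmh = 25) {
  p <- list(
    max_speed_kmh = max_speed_kmh,
    stop_min_duration_s = stop_min_duration_s,
    stop_radius_m = stop_radius_m,
    stop_gap_break_s = stop_gap_break_s,
    move_min_duration_s = move_min_duration_s,
    move_min_span_m = move_min_span_m,
    passive_speed_percentile = passive_speed_percentile,
    passive_speed_threshold_kmh = passive_speed_threshold_kmh
  )
  if (any(unlist(p) <= 0)) stop("all trip parameters must be positive")
  if (p$passive_speed_percentile > 100) stop("percentile must be in (0, 100]")
  class(p) <- "trip_params"
  p
}

# point-to-point speeds (km/h) from consecutive fixes; first is NA
derived_speed_kmh <- function(track) {
  n <- nrow(track)
  if (n < 2) return(rep(NA_real_, n))
  d <- haversine_m(
    track$lat[-n], track$lon[-n],
    track$lat[-1], track$lon[-1]
  )
  dt <- diff(track$time)
  c(NA_real_, d / dt * 3.6)
}

#' Remove implausible GPS fixes
#'
#' Drops fixes whose speed exceeds \code{max_speed_kmh}. The logged speed is
#' used when present; otherwise speed is derived from the haversine distance
#' and time gap to the previous retained point, so a single bad fix does not
#' cast suspicion on its successor.
#'
#' @param track A \code{gps_track}.
#' @param params A \code{trip_params} list.
#' @return The cleaned \code{gps_track}; the number of removed fixes is stored
#'   in attribute \code{n_removed}.
#' @export
clean_track <- function(track, params = trip_params()) {
  n <- nrow(track)
  if (n == 0) {
    attr(track, "n_removed") <- 0L
    return(track)
  }
  if (n > 1 && any(diff(track$time) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  keep <- rep(TRUE, n)
  last <- 1L # first fix has no speed and is retained
  if (n > 1) {
    for (i in 2:n) {
      sp <- track$speed[i]
      if (is.na(sp)) {
        d <- haversine_m(track$lat[last], track$lon[last], track$lat[i], track$lon[i])
        sp <- d / (track$time[i] - track$time[last]) * 3.6
      }
      if (sp > params$max_speed_kmh) {
        keep[i] <- FALSE
      } else {
        last <- i
      }
    }
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  attr(out, "device") <- attr(track, "device")
  attr(out, "id") <- attr(track, "id")
  attr(out, "n_removed") <- sum(!keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
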