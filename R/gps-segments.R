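#' Segment a GPS track into stops and moves
#'
#' Classic greedy stay-point detection. A forward scan grows a
#' candidate stop from an anchor fix for as long as every member fix lies
#' within \code{stop_radius_m} of the running median position; the candidate
#' becomes a stop once its time span reaches \code{stop_min_duration_s}. A
#' data gap longer than \code{stop_gap_break_s} between consecutive fixes
#' terminates the candidate, so one physical dwell interrupted by a long
#' signal loss yields two stop segments. Runs of fixes between stops become
#' move segments only when they last more than \code{move_min_duration_s} and
#' their farthest two fixes are at least \code{move_min_span_m} apart;
#' sub-threshold runs are merged into the flanking stops (stop-greedy
#' tie-break), so stop and move labels alternate within contiguous data.
#'
#' @param track A cleaned, time-sorted \code{gps_track}.
#' @param params A \code{trip_params} list.
#' @return A data frame of class \code{gps_segments}: one row per segment with
#'   \code{kind} ("stop"/"move"), \code{start}, \code{end} (epoch seconds),
#'   \code{duration_min}, \code{i0}, \code{i1} (fix index range),
#'   \code{n_points}, \code{centroid_lat}, \code{centroid_lon} (median
#'   position, stops), and \code{span_m} (farthest-pair distance).
#' @export
detect_segments <- function(track, params = trip_params()) {
  n <- nrow(track)
  empty <- data.frame(
    kind = character(), start = numeric(), end = numeric(),
    duration_min = numeric(), i0 = integer(), i1 = integer(),
    n_points = integer(), centroid_lat = numeric(), centroid_lon = numeric(),
    span_m = numeric()
  )
  class(empty) <- c("gps_segments", "data.frame")
  if (n < 2) return(empty)

  # local equirectangular projection: medians commute with the projection
  # (it is monotone per axis) and planar distances are exact to O((d/R)^2)
  lat0 <- mean(track$lat)
  kx <- 6371000 * pi / 180 * cos(lat0 * pi / 180)
  ky <- 6371000 * pi / 180
  px <- track$lon * kx
  py <- track$lat * ky
  tm <- track$time

  ranges <- .staypoint_scan(
    px, py, tm,
    params$stop_radius_m, params$stop_min_duration_s, params$stop_gap_break_s
  )
  stops <- lapply(seq_len(nrow(ranges)), function(k) ranges[k, ])

  seg_span <- function(i0, i1) {
    idx <- i0:i1
    if (length(idx) < 2) return(0)
    h <- grDevices::chull(px[idx], py[idx])
    hx <- px[idx][h]
    hy <- py[idx][h]
    sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  }
  mk_seg <- function(kind, i0, i1) {
    idx <- i0:i1
    data.frame(
      kind = kind, start = tm[i0], end = tm[i1],
      duration_min = (tm[i1] - tm[i0]) / 60,
      i0 = i0, i1 = i1, n_points = length(idx),
      centroid_lat = stats::median(track$lat[idx]),
      centroid_lon = stats::median(track$lon[idx]),
      span_m = seg_span(i0, i1)
    )
  }
  run_is_move <- function(i0, i1) {
    (tm[i1] - tm[i0]) > params$move_min_duration_s &&
      seg_span(i0, i1) >= params$move_min_span_m
  }

  if (length(stops) == 0) {
    # no stop anywhere: the whole track is one candidate move
    if (run_is_move(1L, n)) {
      out <- mk_seg("move", 1L, n)
      class(out) <- c("gps_segments", "data.frame")
      return(out)
    }
    return(empty)
  }

  segs <- list()
  s <- stops[[1L]]
  # leading run before the first stop
  if (s[1] > 1L) {
    if (run_is_move(1L, s[1] - 1L)) {
      segs[[length(segs) + 1L]] <- mk_seg("move", 1L, s[1] - 1L)
    } else {
      s[1] <- 1L
    }
  }
  k <- 2L
  while (k <= length(stops)) {
    nxt <- stops[[k]]
    gap_i0 <- s[2] + 1L
    gap_i1 <- nxt[1] - 1L
    if (gap_i0 > gap_i1) {
      if (tm[nxt[1]] - tm[s[2]] > params$stop_gap_break_s) {
        # genuine data gap: one physical dwell becomes two stops
        segs[[length(segs) + 1L]] <- mk_seg("stop", s[1], s[2])
        s <- nxt
      } else {
        # contiguous stops (an outlier fix ended the first scan): merge
        s <- c(s[1], nxt[2])
      }
    } else if (run_is_move(gap_i0, gap_i1)) {
      segs[[length(segs) + 1L]] <- mk_seg("stop", s[1], s[2])
      segs[[length(segs) + 1L]] <- mk_seg("move", gap_i0, gap_i1)
      s <- nxt
    } else {
      # sub-threshold run: absorb run and following stop into the current stop
      s <- c(s[1], nxt[2])
    }
    k <- k + 1L
  }
  # trailing run after the last stop
  if (s[2] < n) {
    if (run_is_move(s[2] + 1L, n)) {
      segs[[length(segs) + 1L]] <- mk_seg("stop", s[1], s[2])
      segs[[length(segs) + 1L]] <- mk_seg("move", s[2] + 1L, n)
    } else {
      segs[[length(segs) + 1L]] <- mk_seg("stop", s[1], n)
    }
  } else {
    segs[[length(segs) + 1L]] <- mk_seg("stop", s[1], s[2])
  }

  out <- do.call(rbind, segs)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gps_segments", "data.frame")
  out
}

#' @export
print.gps_segments <- function(x, ...) {
  cat(sprintf(
    "<gps_segments> %d segments (%d stops, %d moves)\n",
    nrow(x), sum(x$kind == "stop"), sum(x$kind == "move")
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarise move segments as trips
#'
#' Each move segment becomes a trip with its duration, 90th-percentile point
#' speed and travel mode: passive (motorized) when the speed percentile is at
#' or above \code{passive_speed_threshold_kmh}, active otherwise. Point speeds
#' use the logged speed where available, else consecutive-fix derived speed.
#'
#' @param segments Output of \code{\link{detect_segments}}.
#' @param track The \code{gps_track} the segments index into.
#' @param params A \code{trip_params} list.
#' @return List of class \code{trip_summary} with \code{trips} (data frame:
#'   start, end, duration_min, p90_speed_kmh, mode), \code{frequency} (trip
#'   count), \code{duration_min} (total trip minutes), and minutes by mode
#'   (\code{active_min}, \code{passive_min}).
#' @export
summarize_trips <- function(segments, track, params = trip_params()) {
  moves <- segments[segments$kind == "move", , drop = FALSE]
  trips <- lapply(seq_len(nrow(moves)), function(r) {
    i0 <- moves$i0[r]
    i1 <- moves$i1[r]
    idx <- i0:i1
    sp <- track$speed[idx]
    if (all(is.na(sp)) && length(idx) > 1) {
      d <- haversine_m(
        track$lat[idx[-length(idx)]], track$lon[idx[-length(idx)]],
        track$lat[idx[-1]], track$lon[idx[-1]]
      )
      sp <- d / diff(track$time[idx]) * 3.6
    }
    sp <- sp[!is.na(sp)]
    p90 <- if (length(sp)) unname(stats::quantile(sp, params$passive_speed_percentile / 100)) else 0
    data.frame(
      start = moves$start[r], end = moves$end[r],
      duration_min = moves$duration_min[r],
      span_m = moves$span_m[r],
      p90_speed_kmh = p90,
      mode = if (p90 >= params$passive_speed_threshold_kmh) "passive" else "active"
    )
  })
  trips <- if (length(trips)) do.call(rbind, trips) else data.frame(
    start = numeric(), end = numeric(), duration_min = numeric(),
    span_m = numeric(), p90_speed_kmh = numeric(), mode = character()
  )
  out <- list(
    trips = trips,
    frequency = nrow(trips),
    duration_min = sum(trips$duration_min),
    active_min = sum(trips$duration_min[trips$mode == "active"]),
    passive_min = sum(trips$duration_min[trips$mode == "passive"])
  )
  class(out) <- "trip_summary"
  out
}

#' @export
print.trip_summary <- function(x, ...) {
  cat(sprintf(
    "<trip_summary> %d trips, %.1f min total (%.1f active, %.1f passive)\n",
    x$frequency, x$duration_min, x$active_min, x$passive_min
  ))
  invisible(x)
}
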