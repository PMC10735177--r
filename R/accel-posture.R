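#' Thigh-posture classification parameters
#'
#' @param gravity_lowpass_hz Low-pass cutoff isolating gravity, Hz.
#' @param stand_angle_deg Thigh inclination (degrees from vertical) below
#'   which a low-movement epoch is standing.
#' @param move_threshold VM counts/min above which an epoch is treated as
#'   stepping and inherits the standing class.
#' @param task_trim_s Seconds trimmed from each end of a labeled task window
#'   before evaluation (transition removal).
#' @param long_axis Column index of the thigh longitudinal axis (1 = x).
#' @return List of class \code{posture_params}.
#' @export
posture_params <- function(gravity_lowpass_hz = 0.5, stand_angle_deg = 45,
                           move_threshold = 100, task_trim_s = 45,
                           long_axis = 1L) {
  if (stand_angle_deg <= 0 || stand_angle_deg >= 90) {
    stop("stand_angle_deg must be in (0, 90)")
  }
  structure(
    list(
      gravity_lowpass_hz = gravity_lowpass_hz,
      stand_angle_deg = stand_angle_deg,
      move_threshold = move_threshold,
      task_trim_s = task_trim_s,
      long_axis = as.integer(long_axis)
    ),
    class = "posture_params"
  )
}

#' Classify sitting/lying vs standing from a thigh-worn stream
#'
#' Inclinometer-style classification: a zero-phase low-pass filter isolates
#' the gravity component; thigh inclination is the angle between the
#' longitudinal axis and vertical. Epochs with movement below
#' \code{move_threshold} counts are standing when the mean inclination is
#' under \code{stand_angle_deg} and sitting/lying otherwise; high-movement
#' (stepping) epochs inherit the standing class, since stepping is upright.
#'
#' @param stream A thigh-worn \code{accel_stream}.
#' @param params A \code{posture_params} list.
#' @param epoch_s Epoch length, seconds.
#' @return Data frame: \code{epoch_start}, \code{inclination_deg} (epoch
#'   mean), \code{vm} (movement counts), \code{posture}
#'   ("sitting_lying"/"standing").
#' @export
classify_posture <- function(stream, params = posture_params(), epoch_s = 60) {
  if (stream$placement != "thigh") {
    stop("posture classification requires a thigh-worn stream; got wrist")
  }
  work <- if (abs(stream$rate - 30) > 1e-9) resample_stream(stream, 30) else stream
  lp <- signal::butter(2, params$gravity_lowpass_hz / (30 / 2), type = "low")
  grav <- vapply(
    1:3,
    function(a) .iir_filtfilt(lp$b, lp$a, work$data[, a]),
    numeric(nrow(work$data))
  )
  gnorm <- sqrt(rowSums(grav^2))
  gnorm[gnorm == 0] <- 1
  cosang <- pmin(pmax(grav[, params$long_axis] / gnorm, -1), 1)
  incl <- acos(abs(cosang)) * 180 / pi # fold: device may be worn either way up

  ep <- compute_counts(work, epoch_s = epoch_s)
  n_ep <- nrow(ep)
  per_epoch <- epoch_s * 30
  gsize <- diff(c(seq(0, length(incl) - 1, by = per_epoch), length(incl)))
  incl_ep <- .group_sum(incl, per_epoch) / gsize

  posture <- ifelse(
    ep$vm >= params$move_threshold | incl_ep < params$stand_angle_deg,
    "standing", "sitting_lying"
  )
  data.frame(
    epoch_start = ep$epoch_start,
    inclination_deg = incl_ep,
    vm = ep$vm,
    posture = posture
  )
}

#' Count steps from a wrist-worn stream
#'
#' Band-passes the dynamic vector-magnitude signal in the gait band
#' (0.5-4 Hz) and counts local maxima above an adaptive, amplitude-relative
#' threshold, with a minimum inter-peak interval; one peak is one step.
#' Scaling the raw signal leaves the count unchanged.
#'
#' @param stream An \code{accel_stream} (any placement; wrist in the study
#'   protocol).
#' @param window Optional \code{c(start, end)} epoch seconds restricting the
#'   count (e.g. a diary-declared walk task); NULL counts the whole stream.
#' @param min_step_interval_s Minimum time between consecutive steps.
#' @param rel_threshold Peak threshold as a fraction of the window's robust
#'   signal amplitude.
#' @return Integer step count.
#' @export
count_steps <- function(stream, window = NULL, min_step_interval_s = 0.3,
                        rel_threshold = 0.4) {
  tt <- stream_times(stream)
  sel <- if (is.null(window)) rep(TRUE, length(tt)) else
    tt >= window[1] & tt <= window[2]
  if (!any(sel)) return(0L)
  vm <- sqrt(rowSums(stream$data[sel, , drop = FALSE]^2))
  n <- length(vm)
  if (n < stream$rate) return(0L) # under a second of data
  bf <- signal::butter(2, c(0.5, 4) / (stream$rate / 2), type = "pass")
  s <- .iir_filtfilt(bf$b, bf$a, vm)

  amp <- stats::quantile(abs(s), 0.95)
  if (amp < 0.05) return(0L) # static signal: no gait
  thr <- rel_threshold * amp

  d <- diff(s)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  peaks <- peaks[s[peaks] > thr]
  if (length(peaks) == 0) return(0L)
  min_gap <- min_step_interval_s * stream$rate
  kept <- peaks[1]
  last <- peaks[1]
  for (p in peaks[-1]) {
    if (p - last >= min_gap) {
      kept <- c(kept, p)
      last <- p
    }
  }
  length(kept)
}
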