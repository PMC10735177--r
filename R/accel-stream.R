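#' Construct a raw accelerometer stream
#'
#' @param data Numeric matrix, one row per sample, columns x/y/z in g.
#' @param rate Sampling rate in Hz (e.g. 25, 30, 50).
#' @param start Start time, POSIXct or epoch seconds.
#' @param placement "wrist" or "thigh".
#' @param device Device identifier string.
#' @return A list of class \code{accel_stream}.
#' @export
accel_stream <- function(data, rate, start = 0,
                         placement = c("wrist", "thigh"), device = "accel") {
  placement <- match.arg(placement)
  data <- as.matrix(data)
  if (ncol(data) != 3) stop("data must have three axis columns")
  if (rate <= 0) stop("rate must be positive")
  colnames(data) <- c("x", "y", "z")
  out <- list(
    data = data, rate = rate, start = as.numeric(start),
    placement = placement, device = device
  )
  class(out) <- "accel_stream"
  out
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf(
    "<accel_stream> %d samples @ %g Hz (%.1f min), %s-worn '%s'\n",
    nrow(x$data), x$rate, nrow(x$data) / x$rate / 60, x$placement, x$device
  ))
  invisible(x)
}

# sample times of a stream
stream_times <- function(stream) {
  stream$start + (seq_len(nrow(stream$data)) - 1) / stream$rate
}

#' Resample a stream to a target rate
#'
#' Per-axis linear interpolation onto a uniform grid at \code{target_rate}
#' spanning the original duration (preserved to within one sample period);
#' used to bring 25/50 Hz watch data onto the 30 Hz reference grid before
#' counts are computed.
#'
#' @param stream An \code{accel_stream}.
#' @param target_rate Target rate, Hz.
#' @return An \code{accel_stream} at \code{target_rate}.
#' @export
resample_stream <- function(stream, target_rate) {
  if (target_rate <= 0) stop("target_rate must be positive")
  if (abs(target_rate - stream$rate) < 1e-12) return(stream)
  n <- nrow(stream$data)
  if (n < 2) stop("stream too short to resample")
  told <- (seq_len(n) - 1) / stream$rate
  tnew <- seq(0, told[n], by = 1 / target_rate)
  out <- vapply(
    1:3,
    function(a) stats::approx(told, stream$data[, a], xout = tnew)$y,
    numeric(length(tnew))
  )
  accel_stream(out, target_rate, stream$start, stream$placement, stream$device)
}
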