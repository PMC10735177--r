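#' Daily life-space metrics from a GPS track
#'
#' Projects the day's fixes onto a local azimuthal-equidistant plane centered
#' at the participant's home and summarises spatial extent with the metrics
#' used in older-adult life-space research:
#' \itemize{
#'   \item farthest straight-line (planar) distance from home, meters;
#'   \item minimum convex hull (MCH): area (m^2) and perimeter (m) of the
#'     smallest convex polygon containing every fix;
#'   \item standard deviational ellipse (SDE): 1-SD ellipse of the point
#'     cloud, from the eigendecomposition of the n-denominator coordinate
#'     covariance, centered at the mean point.
#' }
#' Fewer than three distinct non-collinear fixes cannot support a polygon:
#' such days are flagged \code{degenerate}, with zero hull area and, for
#' collinear clouds, the farthest-pair segment length reported as perimeter.
#'
#' @param track A cleaned \code{gps_track} (>= 1 fix).
#' @param home Numeric \code{c(lat, lon)} of the home location, degrees.
#' @return List of class \code{lifespace_summary}: \code{max_home_distance_m},
#'   \code{mch_area_m2}, \code{mch_perimeter_m}, \code{sde_center_xy_m},
#'   \code{sde_major_m}, \code{sde_minor_m}, \code{sde_theta_rad} (major-axis
#'   angle counterclockwise from east, in [0, pi)), \code{degenerate},
#'   \code{n_points}.
#' @export
lifespace_metrics <- function(track, home) {
  if (nrow(track) < 1) stop("at least one fix is required")
  xy <- project_aeqd(track$lat, track$lon, home)
  max_d <- sqrt(max(xy[, 1]^2 + xy[, 2]^2))
  uxy <- unique(xy)

  area <- 0
  perim <- 0
  degenerate <- TRUE
  if (nrow(uxy) >= 2) {
    h <- grDevices::chull(uxy[, 1], uxy[, 2])
    hx <- uxy[h, 1]
    hy <- uxy[h, 2]
    m <- length(h)
    if (m >= 3) {
      # shoelace; chull orders vertices clockwise so take |.|
      area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    }
    diam <- sqrt(max(
      outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
    ))
    # collinear clouds carry only floating-point sliver area
    if (area > 1e-9 * diam^2) {
      perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
      degenerate <- FALSE
    } else {
      # continuous limit of a flattened polygon: farthest-pair length
      perim <- diam
      area <- 0
    }
  }

  ctr <- colMeans(xy)
  major <- minor <- 0
  theta <- 0
  if (nrow(uxy) >= 2) {
    cc <- sweep(xy, 2, ctr)
    cv <- crossprod(cc) / nrow(xy) # n-denominator (GIS convention)
    ev <- eigen(cv, symmetric = TRUE)
    major <- sqrt(max(ev$values[1], 0))
    minor <- sqrt(max(ev$values[2], 0))
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  }

  out <- list(
    max_home_distance_m = max_d,
    mch_area_m2 = area,
    mch_perimeter_m = perim,
    sde_center_xy_m = unname(ctr),
    sde_major_m = major,
    sde_minor_m = minor,
    sde_theta_rad = theta,
    degenerate = degenerate,
    n_points = nrow(track)
  )
  class(out) <- "lifespace_summary"
  out
}

#' @export
print.lifespace_summary <- function(x, ...) {
  cat(sprintf(
    "<lifespace_summary> max dist %.1f m | MCH %.0f m^2, %.1f m%s | SDE %.1f x %.1f m @ %.2f rad\n",
    x$max_home_distance_m, x$mch_area_m2, x$mch_perimeter_m,
    if (x$degenerate) " (degenerate)" else "",
    x$sde_major_m, x$sde_minor_m, x$sde_theta_rad
  ))
  invisible(x)
}

#' Trim two device tracks to their common time window
#'
#' Restricts both tracks to the intersection of their covered time ranges so
#' device comparisons see identical periods, and flags the day invalid when
#' the joint coverage falls below the minimum GPS wear-time threshold
#' (8 h by default).
#'
#' @param track_a,track_b \code{gps_track}s for the same participant-day.
#' @param min_hours Minimum joint coverage for a valid day, hours.
#' @return List with trimmed \code{a}, \code{b}, \code{overlap_hours} and
#'   logical \code{valid}. An empty intersection gives zero-row tracks and
#'   \code{valid = FALSE}, not an error.
#' @export
align_devices <- function(track_a, track_b, min_hours = 8) {
  if (nrow(track_a) == 0 || nrow(track_b) == 0) {
    return(list(a = track_a[0, ], b = track_b[0, ], overlap_hours = 0, valid = FALSE))
  }
  t0 <- max(track_a$time[1], track_b$time[1])
  t1 <- min(track_a$time[nrow(track_a)], track_b$time[nrow(track_b)])
  trim <- function(tr) {
    out <- tr[tr$time >= t0 & tr$time <= t1, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(tr)
    attr(out, "device") <- attr(tr, "device")
    attr(out, "id") <- attr(tr, "id")
    out
  }
  overlap <- max(0, t1 - t0) / 3600
  list(
    a = trim(track_a), b = trim(track_b),
    overlap_hours = overlap,
    valid = overlap >= min_hours
  )
}
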