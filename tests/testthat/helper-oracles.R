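# Independent reference implementations used to cross-check the package.

# Build a gps_track from planar offsets (meters east/north of an origin),
# so test geometry is exact under the azimuthal-equidistant projection.
track_from_xy <- function(x, y, times, origin = c(43.26, -79.92), ...) {
  d <- sqrt(x^2 + y^2)
  b <- atan2(x, y) * 180 / pi
  ll <- t(mapply(function(bi, di) dest_point(origin[1], origin[2], bi, di), b, d))
  gps_track(times, ll[, 1], ll[, 2], ...)
}

# O(n^3) convex hull: an edge (i, j) is on the hull iff all other points lie
# on one side of it; vertices are chained into a polygon by angle about the
# centroid of the hull set.
brute_hull <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      cr[c(i, j)] <- 0
      if (all(cr <= 1e-9 * max(1, max(abs(cr)))) ||
        all(cr >= -1e-9 * max(1, max(abs(cr))))) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  hx <- x[on_hull]
  hy <- y[on_hull]
  u <- !duplicated(cbind(hx, hy))
  hx <- hx[u]
  hy <- hy[u]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]
  hy <- hy[o]
  m <- length(hx)
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  list(area = area, perimeter = perim, n_vertices = m)
}

# Regex-based reference for the 90/2/30 non-wear rule: a non-wear stretch is
# a maximal run matching "30+ zeros (interruption of <= 2 nonzero epochs
# flanked by 30+ zeros)*" or a plain zero run, kept when >= 90 epochs long.
regex_nonwear <- function(vm, window = 90, allowance = 2, flank = 30) {
  s <- paste(ifelse(vm == 0, "0", "1"), collapse = "")
  pat <- sprintf(
    "0{%d,}(?:1{1,%d}0{%d,})+|0+",
    flank, allowance, flank
  )
  wear <- rep(TRUE, length(vm))
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] != -1) {
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      if (len[k] >= window) wear[m[k]:(m[k] + len[k] - 1)] <- FALSE
    }
  }
  wear
}

# Random epoch day mixing run lengths around the rule's edge cases.
random_choi_day <- function(n_epochs = 1440) {
  vm <- integer(0)
  zero_pool <- c(1:5, 25:35, 80:100, 150:400)
  nz_pool <- c(1:4, 10:30)
  state_zero <- runif(1) < 0.5
  while (length(vm) < n_epochs) {
    len <- if (state_zero) sample(zero_pool, 1) else sample(nz_pool, 1)
    val <- if (state_zero) 0 else sample(1:500, 1)
    vm <- c(vm, rep(val, len))
    state_zero <- !state_zero
  }
  vm[1:n_epochs]
}

# Plain-R greedy stay-point reference (point-by-point, stats::median), the
# independent counterpart of the compiled scan.
r_staypoints <- function(px, py, tm, radius, min_dur, gap_break) {
  n <- length(px)
  stops <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n) {
      if (tm[j + 1] - tm[j] > gap_break) break
      xs <- px[i:(j + 1)]
      ys <- py[i:(j + 1)]
      mx <- stats::median(xs)
      my <- stats::median(ys)
      if (max((xs - mx)^2 + (ys - my)^2) > radius^2) break
      j <- j + 1L
    }
    if (tm[j] - tm[i] >= min_dur) {
      stops[[length(stops) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(stops)) do.call(rbind, stops) else matrix(integer(), ncol = 2)
}

# Match recovered move segments to planted trips by time overlap and return
# precision/recall counts.
match_trips <- function(moves, truth_det) {
  if (nrow(truth_det) == 0 || nrow(moves) == 0) {
    return(list(tp = 0, fp = nrow(moves), fn = nrow(truth_det)))
  }
  used <- rep(FALSE, nrow(truth_det))
  tp <- 0
  for (r in seq_len(nrow(moves))) {
    ov <- pmin(moves$end[r], truth_det$det_end) -
      pmax(moves$start[r], truth_det$det_start)
    cand <- which(!used & ov > 0)
    if (length(cand)) {
      used[cand[which.max(ov[cand])]] <- TRUE
      tp <- tp + 1
    }
  }
  list(tp = tp, fp = nrow(moves) - tp, fn = sum(!used))
}

# A small wrist/thigh schedule around a walking bout, for step/posture tests.
simple_schedule <- function(t0 = 0, pre_s = 60, walk_s = 40, post_s = 60,
                            cadence = 2, participant = 1L, day = 1L) {
  out <- data.frame(
    start = c(t0, t0 + pre_s, t0 + pre_s + walk_s),
    end = c(t0 + pre_s, t0 + pre_s + walk_s, t0 + pre_s + walk_s + post_s),
    activity = c("sit", "walk", "sit"),
    cadence = c(NA, cadence, NA),
    steps = c(NA, round(walk_s * cadence), NA),
    is_task = c(FALSE, TRUE, FALSE),
    task = c(NA, "walk", NA)
  )
  attr(out, "participant") <- participant
  attr(out, "day") <- day
  out
}
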