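#' Sedentary cut-point parameters
#'
#' @param sedentary_cutoff VM counts/min below which an epoch is sedentary;
#'   the wrist-worn cut-point is 2,860 counts/min.
#' @return List of class \code{intensity_params}.
#' @export
intensity_params <- function(sedentary_cutoff = 2860) {
  if (sedentary_cutoff <= 0) stop("cutoff must be positive")
  structure(list(sedentary_cutoff = sedentary_cutoff),
    class = "intensity_params"
  )
}

#' Non-wear detection parameters (Choi rule)
#'
#' Non-wear is at least \code{window_min} consecutive minutes of zero counts,
#' with an allowance of up to \code{allowance_min} minutes of nonzero counts
#' provided \code{flank_min} consecutive zero-count minutes precede and follow
#' the allowance. A day is valid when wear time reaches \code{min_valid_day_h}.
#'
#' @param window_min,allowance_min,flank_min Minutes.
#' @param min_valid_day_h Hours of wear for a valid day.
#' @return List of class \code{wear_params}.
#' @export
wear_params <- function(window_min = 90, allowance_min = 2, flank_min = 30,
                        min_valid_day_h = 8) {
  p <- list(
    window_min = window_min, allowance_min = allowance_min,
    flank_min = flank_min, min_valid_day_h = min_valid_day_h
  )
  if (any(unlist(p) <= 0)) stop("all wear parameters must be positive")
  if (allowance_min >= window_min) stop("allowance must be below the window")
  structure(p, class = "wear_params")
}

#' Classify epoch intensity against the sedentary cut-point
#'
#' Sedentary iff VM counts are strictly below the cut-point (2,859 is
#' sedentary, 2,860 is not); light and moderate/vigorous intensities are
#' collapsed into a single non-sedentary class. Intensity is defined only on
#' wear epochs: non-wear epochs get NA and are excluded from the minutes.
#'
#' @param vm Numeric vector of per-epoch VM counts.
#' @param params An \code{intensity_params} list.
#' @param wear Optional logical vector (TRUE = worn); default all worn.
#' @return List: \code{labels} (character, "sedentary"/"non_sedentary"/NA),
#'   \code{sedentary_min}, \code{non_sedentary_min}.
#' @export
classify_intensity <- function(vm, params = intensity_params(), wear = NULL) {
  if (is.null(wear)) wear <- rep(TRUE, length(vm))
  stopifnot(length(wear) == length(vm))
  labels <- ifelse(vm < params$sedentary_cutoff, "sedentary", "non_sedentary")
  labels[!wear] <- NA_character_
  list(
    labels = labels,
    sedentary_min = sum(labels == "sedentary", na.rm = TRUE),
    non_sedentary_min = sum(labels == "non_sedentary", na.rm = TRUE)
  )
}

#' Detect non-wear epochs with the Choi rule
#'
#' Scans the 60 s epoch series for non-wear blocks: maximal intervals of zero
#' counts at least 90 min long, in which a single interruption of up to 2 min
#' of nonzero counts is tolerated when flanked by at least 30 min of
#' consecutive zeros on each side. Applied to VM counts by default (axis
#' choice is the caller's, via the \code{vm} argument).
#'
#' @param vm Numeric vector of per-epoch counts (VM or a single axis).
#' @param params A \code{wear_params} list.
#' @return List: \code{wear} (logical, TRUE = worn), \code{wear_min},
#'   \code{nonwear_min}, \code{valid_day} (wear >= 8 h).
#' @export
detect_nonwear <- function(vm, params = wear_params()) {
  n <- length(vm)
  wear <- rep(TRUE, n)
  if (n > 0) {
    z <- vm == 0
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- length(r$lengths)
    i <- 1
    while (i <= k) {
      if (!r$values[i]) {
        i <- i + 1
        next
      }
      # grow a candidate block from this zero run
      b_start <- starts[i]
      j <- i
      repeat {
        # absorb [nonzero <= allowance] + [following zero run] when flanked
        # by >= flank_min zeros on both sides
        if (j + 2 <= k &&
          !r$values[j + 1] && r$lengths[j + 1] <= params$allowance_min &&
          r$values[j] && r$lengths[j] >= params$flank_min &&
          r$values[j + 2] && r$lengths[j + 2] >= params$flank_min) {
          j <- j + 2
        } else {
          break
        }
      }
      b_end <- ends[j]
      if (b_end - b_start + 1 >= params$window_min) {
        wear[b_start:b_end] <- FALSE
      }
      i <- j + 1
    }
  }
  list(
    wear = wear,
    wear_min = sum(wear),
    nonwear_min = sum(!wear),
    valid_day = sum(wear) >= params$min_valid_day_h * 60
  )
}
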