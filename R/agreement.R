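#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference A - B; the 95% limits of agreement are
#' bias +/- 1.96 times the sample SD of the differences. Per-pair
#' (mean, difference) coordinates are returned for plotting.
#'
#' @param a,b Equal-length numeric vectors of paired measurements (same units);
#'   \code{a} is conventionally the test method, \code{b} the reference.
#' @return List of class \code{bland_altman}: \code{bias}, \code{loa_low},
#'   \code{loa_high}, \code{sd_diff}, \code{n}, and \code{points} (data frame
#'   with \code{mean}, \code{diff}).
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 2) stop("at least two complete pairs are required")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  out <- list(
    bias = bias,
    loa_low = bias - 1.96 * s,
    loa_high = bias + 1.96 * s,
    sd_diff = s,
    n = length(d),
    points = data.frame(mean = (a + b) / 2, diff = d)
  )
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.3f, 95%% LoA [%.3f, %.3f]\n",
    x$n, x$bias, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean-difference scatter with the bias (solid) and 95% limits of agreement
#' (dashed) as horizontal lines.
#'
#' @param x A \code{bland_altman} object.
#' @param main,xlab,ylab Plot labels.
#' @param ... Passed to \code{plot}.
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman",
                              xlab = "Mean of methods",
                              ylab = "Difference (A - B)", ...) {
  graphics::plot(x$points$mean, x$points$diff,
    main = main, xlab = xlab, ylab = ylab, pch = 19, ...
  )
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Percent agreement between a test and a reference method
#'
#' The per-pair ratio (test/reference) x 100, summarised as its mean
#' (\code{raw}). Because over-reporting pushes the raw ratio above 100, a
#' symmetrized summary is also returned: per pair 100 - |ratio - 100|,
#' averaged, which penalises over- and under-estimation alike. Pairs with a
#' zero reference are excluded with a warning.
#'
#' @param test,reference Equal-length numeric vectors; \code{reference} is
#'   the denominator.
#' @return List: \code{raw} (mean ratio %), \code{symmetrized} (%),
#'   \code{n_used}, \code{n_excluded}.
#' @export
percent_agreement <- function(test, reference) {
  stopifnot(length(test) == length(reference))
  ok <- !(is.na(test) | is.na(reference)) & reference != 0
  nex <- sum(!ok)
  if (nex > 0) warning(sprintf("%d pair(s) with zero/missing reference excluded", nex))
  ratio <- test[ok] / reference[ok] * 100
  list(
    raw = mean(ratio),
    symmetrized = mean(100 - abs(ratio - 100)),
    n_used = sum(ok),
    n_excluded = nex
  )
}

#' Paired difference test with automatic normality gate
#'
#' Compares paired measurements with a paired t-test when a Shapiro-Wilk
#' check does not reject normality of the differences at alpha = 0.05, and
#' with the Wilcoxon signed-rank test otherwise. The choice can be forced.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @param method "auto", "t" or "wilcoxon".
#' @param alpha Significance level of the normality gate.
#' @return List: \code{method} used, \code{statistic}, \code{p_value},
#'   \code{shapiro_p} (NA when forced or undefined).
#' @export
paired_tests <- function(a, b, method = c("auto", "t", "wilcoxon"),
                         alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  d <- a[ok] - b[ok]
  if (length(d) < 2) stop("at least two complete pairs are required")

  if (all(d == 0)) {
    # degenerate: both tests are vacuous; report no difference
    return(list(method = "none", statistic = 0, p_value = 1, shapiro_p = NA_real_))
  }
  shp <- NA_real_
  if (method == "auto") {
    shp <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
    method <- if (shp < alpha) "wilcoxon" else "t"
  }
  if (method == "t") {
    ht <- stats::t.test(a[ok], b[ok], paired = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE, exact = FALSE))
  }
  list(
    method = method,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    shapiro_p = shp
  )
}

#' Spearman rank correlation for paired measurements
#'
#' Rank-based correlation with average ranks for ties. Constant input on
#' either side leaves the coefficient undefined; this is reported via
#' \code{defined = FALSE} rather than an error.
#'
#' @param a,b Equal-length numeric vectors (n >= 3).
#' @return List: \code{rho}, \code{p_value}, \code{n}, \code{defined}.
#' @export
spearman_rho <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 3) stop("at least three complete pairs are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(a), defined = FALSE))
  }
  ht <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(
    rho = unname(ht$estimate), p_value = ht$p.value,
    n = length(a), defined = TRUE
  )
}

#' Full device-agreement summary for one measure
#'
#' Convenience wrapper producing the agreement panel used in validation
#' reports: Bland-Altman bias and limits, Spearman rho, percent agreement and
#' the paired difference test.
#'
#' @param test,reference Paired measurements (test device, reference device).
#' @param measure Name of the measure, carried into the result.
#' @return List of class \code{agreement_result}.
#' @export
agreement_summary <- function(test, reference, measure = "") {
  ba <- bland_altman(test, reference)
  pa <- suppressWarnings(percent_agreement(test, reference))
  pt <- paired_tests(test, reference)
  rho <- if (sum(!(is.na(test) | is.na(reference))) >= 3) {
    spearman_rho(test, reference)
  } else {
    list(rho = NA_real_, p_value = NA_real_, n = ba$n, defined = FALSE)
  }
  out <- list(
    measure = measure, n = ba$n,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    rho = rho$rho, rho_p = rho$p_value,
    pct_agreement_raw = pa$raw, pct_agreement_sym = pa$symmetrized,
    test_method = pt$method, statistic = pt$statistic, p_value = pt$p_value,
    bland_altman = ba
  )
  class(out) <- "agreement_result"
  out
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> %s: n = %d, bias = %.3f, LoA [%.3f, %.3f], rho = %.3f, %%agree = %.1f (%s p = %.3g)\n",
    x$measure, x$n, x$bias, x$loa_low, x$loa_high,
    if (is.na(x$rho)) NA else x$rho, x$pct_agreement_sym,
    x$test_method, x$p_value
  ))
  invisible(x)
}
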