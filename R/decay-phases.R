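#' Detect decay phases in a normalised abundance profile
#'
#' Classifies a decay profile as single-phase or biphasic by fitting
#' 1-segment and continuous 2-segment piecewise-linear models to
#' log(value) against time (candidate breakpoints on the sample grid,
#' least squares) and comparing them by BIC. Two phases are declared only
#' when the BIC improvement of the segmented model exceeds a threshold
#' \emph{and} the second-phase decay rate exceeds the first by at least
#' \code{min_slope_ratio}: on densely sampled noiseless trajectories the
#' BIC term alone would flag the slight curvature that any
#' resource-coupled decay carries, so the ratio requirement reserves the
#' biphasic call for profiles with two genuinely distinct phases.
#'
#' In the queueing regime of the finite-RNase model the first phase is the
#' stalled one (shallow slope, degradation machinery sequestered by the
#' miRNA-sliced target) and the second phase the fast recovery.
#'
#' @param profile a \code{"decay_profile"} (see
#'   [transcription_halt_decay()]) or anything with \code{times} and
#'   \code{values} elements.
#' @param bic_threshold minimum BIC improvement (1-segment minus 2-segment)
#'   required to call two phases.
#' @param min_slope_ratio minimum ratio of second- to first-phase decay
#'   rate for a biphasic call (both phases must be decaying).
#' @param floor_eps values at or below zero are floored here (with a
#'   warning) before taking logs.
#' @return An object of class \code{"phase_report"}: list with
#'   \code{n_phases} (1 or 2), \code{breakpoint} (h, \code{NA} for one
#'   phase), \code{slopes} (log-linear slopes per phase, 1/h; decay rates
#'   are their negatives), and \code{delta_bic}.
#' @examples
#' tt <- seq(0, 6, by = 0.25)
#' detect_decay_phases(list(times = tt, values = exp(-tt)))$n_phases  # 1
#' @export
detect_decay_phases <- function(profile, bic_threshold = 10,
                                min_slope_ratio = 2, floor_eps = 1e-9) {
  tt <- profile$times
  vv <- profile$values
  if (length(tt) < 8)
    stop("phase detection needs at least 8 sample points", call. = FALSE)
  if (any(vv <= 0)) {
    warning("non-positive profile values floored at ", floor_eps,
            " before log transform", call. = FALSE)
    vv <- pmax(vv, floor_eps)
  }
  y <- log(vv)
  n <- length(y)

  rss1_fit <- stats::lm.fit(cbind(1, tt), y)
  rss1 <- sum(rss1_fit$residuals^2)
  slope1 <- rss1_fit$coefficients[2]

  # continuous 2-segment model: basis {1, t, (t - b)_+}, breakpoint on grid
  best <- list(rss = Inf, b = NA_real_, coef = NULL)
  for (k in 3:(n - 3)) {  # keep >= 3 points per segment
    b <- tt[k]
    hinge <- pmax(tt - b, 0)
    f <- stats::lm.fit(cbind(1, tt, hinge), y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, b = b, coef = f$coefficients)
  }
  # BIC with gaussian errors; 2-segment model spends 2 extra parameters
  # (hinge coefficient + breakpoint location)
  bic <- function(rss, k) n * log(max(rss, 1e-300) / n) + k * log(n)
  delta_bic <- bic(rss1, 2) - bic(best$rss, 4)

  s1 <- unname(best$coef[2])
  s2 <- unname(best$coef[2] + best$coef[3])
  distinct <- s1 < 0 && s2 < 0 && (s2 / s1) >= min_slope_ratio
  if (is.finite(delta_bic) && delta_bic > bic_threshold && distinct) {
    rep <- list(n_phases = 2L, breakpoint = best$b, slopes = c(s1, s2),
                delta_bic = delta_bic)
  } else {
    rep <- list(n_phases = 1L, breakpoint = NA_real_,
                slopes = unname(slope1), delta_bic = delta_bic)
  }
  structure(rep, class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  if (x$n_phases == 1L) {
    cat(sprintf("Single-phase decay: slope %.4g /h (delta BIC %.1f)\n",
                x$slopes[1], x$delta_bic))
  } else {
    cat(sprintf("Biphasic decay: slopes %.4g then %.4g /h, break at %.3g h (delta BIC %.1f)\n",
                x$slopes[1], x$slopes[2], x$breakpoint, x$delta_bic))
  }
  invisible(x)
}

#' Half-life of a decay profile
#'
#' First crossing of half the initial value, by piecewise-linear
#' interpolation of log(value) against time. The estimate is invariant to
#' an overall rescaling of the profile. If the profile never reaches half
#' its initial value, an error is raised unless \code{extrapolate = TRUE},
#' in which case the terminal log-linear slope is extended and the result
#' carries attribute \code{"extrapolated" = TRUE}.
#'
#' @param profile a \code{"decay_profile"} or list with \code{times} and
#'   \code{values}.
#' @param extrapolate allow extrapolation beyond the last sample.
#' @return Half-life in hours.
#' @examples
#' tt <- seq(0, 4, by = 0.1)
#' half_life(list(times = tt, values = exp(-tt * log(2))))  # 1 h
#' @export
half_life <- function(profile, extrapolate = FALSE) {
  tt <- profile$times
  vv <- profile$values / profile$values[1]
  y <- log(pmax(vv, 1e-300))
  target <- log(0.5)
  below <- which(y <= target)
  if (length(below)) {
    i <- below[1]
    if (i == 1L) return(structure(0, extrapolated = FALSE))
    t50 <- tt[i - 1] + (target - y[i - 1]) * (tt[i] - tt[i - 1]) /
      (y[i] - y[i - 1])
    return(structure(unname(t50), extrapolated = FALSE))
  }
  if (!extrapolate)
    stop("profile never crosses 0.5 of its initial value; ",
         "set extrapolate = TRUE to extend the terminal slope", call. = FALSE)
  n <- length(tt)
  slope <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])
  if (slope >= 0)
    stop("cannot extrapolate: terminal slope is non-negative", call. = FALSE)
  structure(unname(tt[n] + (target - y[n]) / slope), extrapolated = TRUE)
}

#' Locate the biphasic-onset threshold in the miRNA binding constant
#'
#' Bisects for the smallest binding constant at which the endogenous decay
#' profile of the transcription-halt experiment becomes biphasic under
#' [detect_decay_phases()]. Requires the bracket to straddle the
#' transition (single-phase at \code{lower}, biphasic at \code{upper}).
#'
#' @param params a [degradation_params()] object.
#' @param lower,upper bracketing binding constants (1/nM/h).
#' @param tol_rel relative bracket width at which bisection stops.
#' @param sample_times decay sampling grid.
#' @param ... passed to [detect_decay_phases()].
#' @return The threshold (1/nM/h), with attribute \code{"bracket"}.
#' @export
biphasic_threshold <- function(params, lower = 0.05, upper = 50,
                               tol_rel = 0.02,
                               sample_times = default_decay_times(), ...) {
  is_biphasic <- function(eta) {
    prof <- transcription_halt_decay(params, eta_plus_values = eta,
                                     sample_times = sample_times,
                                     species = "endogenous")[[1]]
    detect_decay_phases(prof, ...)$n_phases == 2L
  }
  lo_b <- is_biphasic(lower)
  hi_b <- is_biphasic(upper)
  if (lo_b || !hi_b)
    stop("bracket does not straddle the biphasic transition: n_phases at ",
         "lower = ", if (lo_b) 2 else 1, ", at upper = ", if (hi_b) 2 else 1,
         call. = FALSE)
  lo <- lower; hi <- upper
  while ((hi - lo) / hi > tol_rel) {
    mid <- sqrt(lo * hi)  # bisect in log space
    if (is_biphasic(mid)) hi <- mid else lo <- mid
  }
  structure(sqrt(lo * hi), bracket = c(lo, hi))
}
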