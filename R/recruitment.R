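#' Recruitment curve at a reference diameter
#'
#' Fraction of fibers of the reference diameter `d0` activated as a
#' function of stimulus current. Non-decreasing, 0 at zero current,
#' bounded by 1.
#'
#' @param current Current grid, amperes, starting at 0, increasing.
#' @param fraction Recruited fraction in `[0, 1]`, non-decreasing.
#' @param d0 Reference diameter, meters.
#' @return Object of class `recruitment_curve`.
#' @export
recruitment_curve <- function(current, fraction, d0) {
  stopifnot(length(current) == length(fraction), d0 > 0,
            current[1] >= 0, all(diff(current) > 0))
  if (any(fraction < -1e-12) || any(fraction > 1 + 1e-12))
    stop("fractions must lie in [0, 1]")
  if (any(diff(fraction) < -1e-12))
    stop("recruitment curve must be non-decreasing")
  structure(list(current = current, fraction = pmin(pmax(fraction, 0), 1),
                 d0 = d0),
            class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf(
    "<recruitment_curve> d0 = %.2g um, %d current samples up to %.3g A, max fraction %.3g\n",
    x$d0 * 1e6, length(x$current), max(x$current), max(x$fraction)))
  invisible(x)
}

#' Recruitment curve from per-fiber thresholds (synthetic titration)
#'
#' The recruitment curve at the reference diameter is the empirical CDF of
#' the per-fiber activation thresholds: `R*(I)` is the fraction of
#' thresholds at or below `I`.
#'
#' @param thresholds Positive activation thresholds, amperes.
#' @param d0 Reference diameter, meters.
#' @param I_grid Current grid; default 256 points from 0 to 1.2 times the
#'   largest threshold.
#' @return A [recruitment_curve()].
#' @export
titration_curve <- function(thresholds, d0, I_grid = NULL) {
  if (!length(thresholds)) stop("empty threshold list")
  stopifnot(all(thresholds > 0))
  if (is.null(I_grid))
    I_grid <- seq(0, 1.2 * max(thresholds), length.out = 256)
  frac <- vapply(I_grid, function(I) mean(thresholds <= I), numeric(1))
  recruitment_curve(I_grid, frac, d0)
}

#' Rescale a recruitment curve to fiber diameter
#'
#' Because the stimulus threshold scales as `1/d`, the recruitment curve
#' titrated at diameter `d0` applies to diameter `d` at stimulus `I` as
#' `R(d) = R*(d I / d0)` (piecewise-linear interpolation on the current
#' grid; 0 below the grid would require negative current, values past the
#' top of the grid take the final fraction).
#'
#' @param curve A [recruitment_curve()].
#' @param d Fiber diameter(s), meters.
#' @param I Stimulus current, amperes, `>= 0`.
#' @return Recruited fraction(s) at diameter(s) `d`.
#' @export
rescale_to_diameter <- function(curve, d, I) {
  stopifnot(inherits(curve, "recruitment_curve"), all(d > 0), I >= 0)
  stats::approx(curve$current, curve$fraction, xout = d * I / curve$d0,
                rule = 2)$y
}

#' Gaussian jitter of activation thresholds
#'
#' Adds independent zero-mean Gaussian noise to per-fiber thresholds,
#' emulating threshold variability; jittering smooths the recruitment curve
#' and hence the eCAP. Results are clipped below at a small positive floor.
#'
#' @param thresholds Thresholds, amperes.
#' @param sigma_jitter Noise standard deviation, amperes, `>= 0`.
#' @param seed Integer seed (reproducibility contract).
#' @param floor Lower clip, amperes.
#' @return Jittered thresholds.
#' @export
jitter_thresholds <- function(thresholds, sigma_jitter, seed = NULL,
                              floor = 1e-9) {
  stopifnot(sigma_jitter >= 0)
  if (sigma_jitter == 0) return(thresholds)
  if (!is.null(seed)) set.seed(seed)
  pmax(thresholds + stats::rnorm(length(thresholds), 0, sigma_jitter), floor)
}
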