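#' Fiber-level constants
#'
#' Default electrophysiological constants used throughout the package, all in
#' SI units. The conduction-law coefficients and Gaussian action-potential
#' widths are the values fitted to multicompartment fiber models of a rat
#' myelinated sensory-motor axon and an unmyelinated C-fiber:
#' `a = 4.3e6 1/s` (myelinated, `v = a d`), `b = 470 m^0.5/s` (unmyelinated,
#' `v = b sqrt(d)`), `w_V = 5e-5 s` (myelinated) and `w_V = 2e-4 s`
#' (unmyelinated). The axial conductivity `sigma_tau` and the AP peak
#' excursion `V_p` are pure amplitude scale factors that carry no shape
#' information; their defaults (1 S/m, 100 mV) are typical textbook values
#' and every amplitude-sensitive computation in the package is a ratio, so
#' these two constants never affect a comparison.
#'
#' @return Named list of constants: `a`, `b`, `w_V_myelinated`,
#'   `w_V_unmyelinated`, `w_phi`, `sigma_tau`, `V_p`, `d0_myelinated`,
#'   `d0_unmyelinated`.
#' @export
default_constants <- function() {
  list(
    a = 4.3e6,               # 1/s, myelinated v = a*d
    b = 470,                 # m^0.5/s, unmyelinated v = b*sqrt(d)
    w_V_myelinated = 5e-5,   # s, Gaussian sigma of the myelinated AP
    w_V_unmyelinated = 2e-4, # s, Gaussian sigma of the unmyelinated AP
    w_phi = 1e-3,            # m, typical sensitivity-profile width
    sigma_tau = 1,           # S/m, axial conductivity (amplitude scale only)
    V_p = 0.1,               # V, AP peak excursion (amplitude scale only)
    d0_myelinated = 4e-6,    # m, reference diameter for titration
    d0_unmyelinated = 0.8e-6 # m
  )
}

#' Conduction law of a fiber class
#'
#' Myelinated fibers conduct at a velocity proportional to their diameter,
#' unmyelinated fibers at a velocity proportional to the square root of the
#' diameter. The coefficient has units 1/s (myelinated) or m^0.5/s
#' (unmyelinated).
#'
#' @param kind `"myelinated"` or `"unmyelinated"`.
#' @param coefficient Positive proportionality constant. Defaults to the
#'   fitted constants of [default_constants()].
#' @return Object of class `conduction_law`.
#' @export
conduction_law <- function(kind = c("myelinated", "unmyelinated"),
                           coefficient = NULL) {
  kind <- match.arg(kind)
  if (is.null(coefficient)) {
    coefficient <- if (kind == "myelinated") default_constants()$a
                   else default_constants()$b
  }
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient), coefficient > 0)
  structure(list(kind = kind, coefficient = coefficient),
            class = "conduction_law")
}

#' @export
print.conduction_law <- function(x, ...) {
  form <- if (x$kind == "myelinated") "v = a*d" else "v = b*sqrt(d)"
  cat(sprintf("<conduction_law> %s, %s, coefficient = %g\n",
              x$kind, form, x$coefficient))
  invisible(x)
}

#' Conduction velocity for a fiber diameter
#'
#' @param law A [conduction_law()].
#' @param d Fiber diameter(s) in meters, `>= 0`.
#' @return Velocity in m/s (vectorized over `d`).
#' @examples
#' conduction_velocity(conduction_law("unmyelinated"), 0.1e-6) # ~0.15 m/s
#' @export
conduction_velocity <- function(law, d) {
  stopifnot(inherits(law, "conduction_law"))
  if (any(d < 0)) stop("fiber diameter must be non-negative")
  if (law$kind == "myelinated") law$coefficient * d
  else law$coefficient * sqrt(d)
}

#' Axial current prefactor eta
#'
#' The transmembrane current per unit length of a fiber is
#' `i = eta * d^2 V_x / d l^2` with `eta = pi d^2 sigma_tau / 4`, where
#' `sigma_tau` is the axial (intracellular) conductivity.
#'
#' @param d Fiber diameter(s), meters.
#' @param sigma_tau Axial conductivity, S/m.
#' @return eta in S*m (vectorized over `d`).
#' @export
axial_prefactor <- function(d, sigma_tau = default_constants()$sigma_tau) {
  stopifnot(sigma_tau > 0)
  if (any(d < 0)) stop("fiber diameter must be non-negative")
  pi * d^2 * sigma_tau / 4
}

#' Action-potential waveform
#'
#' A transmembrane-potential waveform on a uniform time grid, with its peak
#' at `t = 0`. When constructed from a parametric Gaussian the parameters
#' are retained so that derivatives can be evaluated analytically.
#'
#' @param time Uniformly spaced time grid, seconds.
#' @param values Transmembrane potential, volts.
#' @param V_p,w_V Optional Gaussian parameters (peak volts, width seconds)
#'   if the waveform is parametric.
#' @param recenter Shift the grid so the peak sits at `t = 0` (default TRUE).
#' @return Object of class `ap_waveform` with elements `time`, `values`,
#'   `dt`, and optionally `V_p`, `w_V`.
#' @export
ap_waveform <- function(time, values, V_p = NULL, w_V = NULL,
                        recenter = TRUE) {
  stopifnot(length(time) == length(values), length(time) >= 5L)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniform and increasing")
  if (recenter) {
    ipk <- which.max(abs(values))
    time <- time - time[ipk]
  }
  structure(list(time = time, values = values, dt = dt[1],
                 V_p = V_p, w_V = w_V),
            class = "ap_waveform")
}

#' @export
print.ap_waveform <- function(x, ...) {
  cat(sprintf(
    "<ap_waveform> %d samples, dt = %.3g s, span [%.3g, %.3g] s, peak %.3g V%s\n",
    length(x$time), x$dt, min(x$time), max(x$time), max(abs(x$values)),
    if (!is.null(x$w_V)) sprintf(" (Gaussian, w_V = %.3g s)", x$w_V) else ""))
  invisible(x)
}

#' Parametric Gaussian action potential
#'
#' `V_t(t) = V_p exp(-t^2 / (2 w_V^2))`, peak at `t = 0`.
#'
#' @param V_p Peak amplitude, volts.
#' @param w_V Gaussian width (sigma), seconds.
#' @param time Uniform time grid spanning at least `+/- 5 w_V`; if omitted a
#'   grid of `+/- 6 w_V` at step `w_V / 50` is built.
#' @return An [ap_waveform()] carrying the Gaussian parameters.
#' @export
gaussian_ap <- function(V_p = default_constants()$V_p,
                        w_V = default_constants()$w_V_myelinated,
                        time = NULL) {
  stopifnot(w_V > 0)
  if (is.null(time)) time <- seq(-6 * w_V, 6 * w_V, by = w_V / 50)
  if (min(time) > -5 * w_V || max(time) < 5 * w_V)
    stop("time grid must span at least +/- 5 w_V to contain the pulse")
  ap_waveform(time, V_p * exp(-time^2 / (2 * w_V^2)),
              V_p = V_p, w_V = w_V, recenter = FALSE)
}

#' Second time derivative of an AP waveform
#'
#' For parametric Gaussian waveforms the analytic derivative
#' `(V_p / w_V^2) (t^2 / w_V^2 - 1) exp(-t^2 / (2 w_V^2))` is returned;
#' otherwise a central second finite difference (one-sided at the ends) on
#' the uniform grid. For a waveform returning to baseline at both ends the
#' time integral of the result is ~0.
#'
#' @param ap An [ap_waveform()].
#' @param analytic Use the closed-form derivative when Gaussian parameters
#'   are present (default TRUE).
#' @return Numeric vector of `d^2 V / d t^2`, V/s^2, on `ap$time`.
#' @export
second_time_derivative <- function(ap, analytic = TRUE) {
  stopifnot(inherits(ap, "ap_waveform"))
  t <- ap$time
  if (analytic && !is.null(ap$w_V) && !is.null(ap$V_p)) {
    w <- ap$w_V
    return((ap$V_p / w^2) * (t^2 / w^2 - 1) * exp(-t^2 / (2 * w^2)))
  }
  v <- ap$values
  n <- length(v)
  d2 <- c(v[3] - 2 * v[2] + v[1],
          v[-c(1, 2)] - 2 * v[-c(1, n)] + v[-c(n - 1, n)],
          v[n] - 2 * v[n - 1] + v[n - 2]) / ap$dt^2
  d2
}

#' Critical diameter where AP extent matches electrode extent
#'
#' Solves `v(d*) = w_phi / w_V`, the diameter at which the spatial extent of
#' the action potential equals the extent of the electrode sensitivity
#' profile. Below `d*` a fiber is in the short-AP regime, above it in the
#' long-AP regime; the SFAP amplitude scaling changes character across it.
#'
#' @param law A [conduction_law()].
#' @param w_phi Sensitivity-profile width, meters.
#' @param w_V AP Gaussian width, seconds.
#' @return Diameter `d*` in meters.
#' @examples
#' # myelinated defaults: ~4.7 um
#' critical_diameter(conduction_law("myelinated"), 1e-3, 5e-5)
#' @export
critical_diameter <- function(law, w_phi, w_V) {
  stopifnot(inherits(law, "conduction_law"), w_phi > 0, w_V > 0)
  v_star <- w_phi / w_V
  if (law$kind == "myelinated") v_star / law$coefficient
  else (v_star / law$coefficient)^2
}

#' Diameter-dependent stimulus threshold law
#'
#' Stimulus threshold is inversely proportional to fiber diameter:
#' `T(d) = T0 * d0 / d`, anchored at a reference diameter `d0`.
#'
#' @param d0 Reference diameter, meters.
#' @param T0 Threshold current at `d0`, amperes.
#' @return Object of class `threshold_law`.
#' @export
threshold_law <- function(d0, T0) {
  stopifnot(d0 > 0, T0 > 0)
  structure(list(d0 = d0, T0 = T0), class = "threshold_law")
}

#' Stimulus threshold for a fiber diameter
#'
#' @param thr A [threshold_law()].
#' @param d Diameter(s), meters, `> 0`.
#' @return Threshold current(s), amperes.
#' @export
stimulus_threshold <- function(thr, d) {
  stopifnot(inherits(thr, "threshold_law"))
  if (any(d <= 0)) stop("fiber diameter must be positive")
  thr$T0 * thr$d0 / d
}
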