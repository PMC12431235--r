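#' Sensitivity profile (lead field) along a fiber path
#'
#' The sensitivity function Phi(l) is the electric potential along the fiber
#' path produced by a virtual unit current applied to the recording
#' electrodes. By reciprocity it is the weight with which transmembrane
#' currents at arclength l contribute to the recorded signal.
#'
#' @param arclength Uniform arclength grid, meters.
#' @param values Phi, V/A.
#' @param label Optional electrode-configuration label.
#' @param tapered Logical: have the ends been forced to zero?
#' @return Object of class `sensitivity_profile` with elements `arclength`,
#'   `values`, `dl`, `label`, `tapered`.
#' @export
sensitivity_profile <- function(arclength, values, label = "",
                                tapered = FALSE) {
  stopifnot(length(arclength) == length(values), length(arclength) >= 3L)
  dl <- diff(arclength)
  if (any(dl <= 0) || max(abs(dl - dl[1])) > 1e-9 * dl[1])
    stop("arclength grid must be uniform and increasing")
  structure(list(arclength = arclength, values = values, dl = dl[1],
                 label = label, tapered = tapered),
            class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_profile> %s%d samples over [%.3g, %.3g] m, peak |Phi| = %.3g V/A%s\n",
    if (nzchar(x$label)) paste0(x$label, ": ") else "",
    length(x$arclength), min(x$arclength), max(x$arclength),
    max(abs(x$values)), if (x$tapered) " (tapered)" else ""))
  invisible(x)
}

#' Gaussian electrode contact
#'
#' Parametric monopolar contact whose sensitivity along the fiber is
#' `Phi(x) = polarity * Phi_p exp(-(x - x_c)^2 / (2 w_phi^2))`. A bipolar
#' electrode is the list of two contacts with opposite polarity.
#'
#' @param Phi_p Peak sensitivity, V/A.
#' @param w_phi Gaussian width, meters.
#' @param x_c Contact center arclength, meters.
#' @param polarity +1 or -1.
#' @return Object of class `gaussian_contact`.
#' @export
gaussian_contact <- function(Phi_p, w_phi = default_constants()$w_phi,
                             x_c = 0, polarity = 1) {
  stopifnot(w_phi > 0, polarity %in% c(-1, 1))
  structure(list(Phi_p = Phi_p, w_phi = w_phi, x_c = x_c,
                 polarity = polarity),
            class = "gaussian_contact")
}

#' Sensitivity profile of Gaussian contacts
#'
#' Sums the signed Gaussians of one or more [gaussian_contact()]s on an
#' arclength grid.
#'
#' @param contacts A `gaussian_contact` or list of them.
#' @param arclength Uniform arclength grid, meters.
#' @return A [sensitivity_profile()].
#' @export
gaussian_profile <- function(contacts, arclength) {
  if (inherits(contacts, "gaussian_contact")) contacts <- list(contacts)
  stopifnot(length(contacts) >= 1L)
  phi <- numeric(length(arclength))
  for (cc in contacts) {
    stopifnot(inherits(cc, "gaussian_contact"))
    phi <- phi + cc$polarity * cc$Phi_p *
      exp(-(arclength - cc$x_c)^2 / (2 * cc$w_phi^2))
  }
  lab <- if (length(contacts) == 1L) "gaussian monopolar"
         else sprintf("gaussian %d-contact", length(contacts))
  sensitivity_profile(arclength, phi, label = lab)
}

#' Point-electrode configuration in a homogeneous medium
#'
#' One or two point recording terminals in an infinite homogeneous medium of
#' conductivity `sigma_e`. A unit current injected at a terminal produces
#' the potential `1 / (4 pi sigma_e r)` at distance `r`; with two terminals
#' the lead field is the signed difference (first minus second).
#'
#' @param positions Matrix with one or two rows of 3-D coordinates, meters.
#' @param sigma_e Medium conductivity, S/m.
#' @return Object of class `point_electrode_config`.
#' @export
point_electrode_config <- function(positions, sigma_e = 1) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(nrow(positions) %in% c(1L, 2L), sigma_e > 0)
  structure(list(positions = positions, sigma_e = sigma_e),
            class = "point_electrode_config")
}

#' Point-electrode sensitivity profile along a fiber path
#'
#' Evaluates `Phi(l) = (1 / 4 pi sigma_e) sum_k (+/-1) / |r(l) - r_k|` for
#' the terminals of a [point_electrode_config()] along a straight or
#' polyline fiber path.
#'
#' @param cfg A [point_electrode_config()].
#' @param fiber_path Either a function `l -> c(x, y, z)` (vectorized:
#'   n x 3 matrix for a vector `l`), or a 2-row matrix `rbind(p0, p1)`
#'   defining a straight path where arclength l runs from `p0` towards `p1`.
#' @param arclength Uniform arclength grid, meters.
#' @return A [sensitivity_profile()].
#' @export
point_electrode_profile <- function(cfg, fiber_path, arclength) {
  stopifnot(inherits(cfg, "point_electrode_config"))
  pts <- .eval_fiber_path(fiber_path, arclength)
  phi <- numeric(length(arclength))
  pol <- if (nrow(cfg$positions) == 2L) c(1, -1) else 1
  for (k in seq_len(nrow(cfg$positions))) {
    dd <- sqrt((pts[, 1] - cfg$positions[k, 1])^2 +
               (pts[, 2] - cfg$positions[k, 2])^2 +
               (pts[, 3] - cfg$positions[k, 3])^2)
    if (any(dd == 0)) stop("electrode terminal lies on the fiber path")
    phi <- phi + pol[k] / (4 * pi * cfg$sigma_e * dd)
  }
  lab <- if (nrow(cfg$positions) == 2L) "point bipolar" else "point monopolar"
  sensitivity_profile(arclength, phi, label = lab)
}

.eval_fiber_path <- function(fiber_path, l) {
  if (is.function(fiber_path)) {
    pts <- fiber_path(l)
    pts <- matrix(as.numeric(pts), ncol = 3)
    stopifnot(nrow(pts) == length(l))
    return(pts)
  }
  fp <- matrix(as.numeric(fiber_path), ncol = 3)
  stopifnot(nrow(fp) == 2L)
  dir <- fp[2, ] - fp[1, ]
  dir <- dir / sqrt(sum(dir^2))
  cbind(fp[1, 1] + l * dir[1], fp[1, 2] + l * dir[2], fp[1, 3] + l * dir[3])
}

#' Taper a sensitivity profile to zero at both ends
#'
#' Lead-field tables computed on a finite window generally do not vanish at
#' the window ends, which makes the recorded signal gauge-dependent. From
#' each end moving inward, the first sample whose local |slope| reaches
#' `min_slope` is found; the profile outward of that point is replaced by
#' the tangent line until it crosses zero, and set to zero beyond the
#' crossing. If no sample reaches `min_slope` the end value is ramped
#' linearly to zero over `margin_frac` of the window (with a message).
#'
#' @param profile A [sensitivity_profile()].
#' @param min_slope Minimal |slope| (V/A/m) that marks the start of the
#'   tapered section. Default: 1% of `max|Phi|` divided by half the window
#'   length.
#' @param margin_frac Fallback ramp length as a fraction of the window.
#' @return A tapered [sensitivity_profile()] (exact zeros at both ends).
#' @export
taper_ends <- function(profile, min_slope = NULL, margin_frac = 0.1) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  phi <- profile$values
  l <- profile$arclength
  n <- length(phi)
  if (is.null(min_slope))
    min_slope <- 0.01 * max(abs(phi)) / ((l[n] - l[1]) / 2)
  slope <- c(diff(phi), NA) / profile$dl        # forward slope at i
  slope_b <- c(NA, diff(phi)) / profile$dl      # backward slope at i

  taper_one <- function(phi, from_start) {
    idx <- if (from_start) seq_len(n) else rev(seq_len(n))
    sl <- if (from_start) slope else -slope_b   # slope looking inward
    hit <- NA_integer_
    for (i in idx) {
      if (!is.na(sl[i]) && abs(sl[i]) >= min_slope) { hit <- i; break }
    }
    if (is.na(hit)) {
      m <- max(2L, ceiling(margin_frac * n))
      message("taper_ends: no point reaches min_slope at ",
              if (from_start) "start" else "end",
              "; ramping linearly over ", m, " samples")
      if (from_start) {
        ramp <- seq(0, 1, length.out = m)
        phi[seq_len(m)] <- phi[m] * ramp
      } else {
        ramp <- seq(1, 0, length.out = m)
        phi[(n - m + 1L):n] <- phi[n - m + 1L] * ramp
      }
      return(phi)
    }
    s <- if (from_start) slope[hit] else slope_b[hit]
    # tangent line through (l[hit], phi[hit]) with slope s, outward until it
    # crosses zero; zero past the crossing
    if (from_start) {
      out <- seq_len(hit)
    } else {
      out <- hit:n
    }
    lin <- phi[hit] + s * (l[out] - l[hit])
    crossed <- sign(lin) != sign(phi[hit])
    lin[crossed | lin == 0] <- 0
    # beyond the zero crossing (moving outward), force zero
    if (from_start) {
      cz <- which(lin == 0)
      if (length(cz)) lin[seq_len(max(cz))] <- 0
    } else {
      cz <- which(lin == 0)
      if (length(cz)) lin[min(cz):length(lin)] <- 0
    }
    phi[out] <- lin
    phi
  }

  if (abs(phi[1]) > 0) phi <- taper_one(phi, TRUE)
  if (abs(phi[n]) > 0) phi <- taper_one(phi, FALSE)
  phi[1] <- 0; phi[n] <- 0
  sensitivity_profile(l, phi, label = profile$label, tapered = TRUE)
}

#' Time-reparameterize a sensitivity profile
#'
#' Converts Phi(l) into the time-domain kernel Phi(l_init + v t) seen by an
#' action potential initiated at arclength `l_init` and propagating at
#' velocity `v`. Interpolation is cubic (monotone grid spline) inside the
#' tabulated support and exactly zero outside, matching the tapered
#' boundary.
#'
#' @param profile A [sensitivity_profile()].
#' @param v Conduction velocity, m/s, `> 0`.
#' @param time Uniform time grid, seconds.
#' @param l_init AP initiation arclength, meters (default 0).
#' @param method `"cubic"` (default) or `"linear"`.
#' @return Numeric vector `Phi(l_init + v * time)` on `time`.
#' @export
time_reparameterize <- function(profile, v, time, l_init = 0,
                                method = c("cubic", "linear")) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  if (v <= 0) stop("velocity must be positive")
  method <- match.arg(method)
  lq <- l_init + v * time
  inside <- lq >= profile$arclength[1] &
            lq <= profile$arclength[length(profile$arclength)]
  out <- numeric(length(time))
  if (any(inside)) {
    if (method == "cubic") {
      out[inside] <- stats::spline(profile$arclength, profile$values,
                                   xout = lq[inside], method = "natural")$y
    } else {
      out[inside] <- stats::approx(profile$arclength, profile$values,
                                   xout = lq[inside])$y
    }
  }
  out
}
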