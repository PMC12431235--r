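#' Voltage signal on a uniform time grid
#'
#' @param time Uniform time grid, seconds.
#' @param values Recorded voltage, volts.
#' @return Object of class `signal_trace`.
#' @export
signal_trace <- function(time, values) {
  stopifnot(length(time) == length(values), all(is.finite(values)))
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("time grid must be uniform and increasing")
  structure(list(time = time, values = values, dt = dt[1]),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "<signal_trace> %d samples, dt = %.3g s, span [%.3g, %.3g] s, peak-to-peak %.3g V\n",
    length(x$time), x$dt, min(x$time), max(x$time),
    diff(range(x$values))))
  invisible(x)
}

#' Peak-to-peak amplitude of a signal
#' @param s A [signal_trace()].
#' @return `max - min` of the trace, volts.
#' @export
peak_to_peak <- function(s) {
  stopifnot(inherits(s, "signal_trace"))
  diff(range(s$values))
}

# linear (continuous) convolution of two sampled functions sharing step dt;
# returns values on a grid starting at t0x + t0y
.conv_time <- function(x, y, dt) {
  stats::convolve(x, rev(y), type = "open") * dt
}

#' SFAP by the reciprocity-theorem convolution
#'
#' Computes the single-fiber action potential as
#' `S(t) = (eta / v) * (d^2 V_t / dt^2  *  Phi(v t))`,
#' the convolution in time of the second temporal derivative of the
#' transmembrane potential with the sensitivity function traversed at the
#' conduction velocity. The sensitivity profile should be tapered to zero at
#' its ends; an untapered profile makes the result gauge-dependent (a
#' warning is issued).
#'
#' @param ap An [ap_waveform()].
#' @param profile A [sensitivity_profile()] (ideally tapered).
#' @param v Conduction velocity, m/s.
#' @param eta Axial prefactor `eta`, S*m (see [axial_prefactor()]).
#' @param l_init AP initiation arclength, meters.
#' @return A [signal_trace()] covering the AP transit past the profile
#'   support.
#' @export
sfap_reciprocity <- function(ap, profile, v, eta, l_init = 0) {
  stopifnot(inherits(ap, "ap_waveform"), inherits(profile, "sensitivity_profile"))
  if (v <= 0) stop("velocity must be positive")
  if (!isTRUE(profile$tapered))
    warning("sensitivity profile is not tapered; SFAP is gauge-ambiguous")
  dt <- ap$dt
  l0 <- profile$arclength[1]
  l1 <- profile$arclength[length(profile$arclength)]
  tphi <- seq((l0 - l_init) / v, (l1 - l_init) / v, by = dt)
  phi_t <- time_reparameterize(profile, v, tphi, l_init = l_init)
  d2v <- second_time_derivative(ap)
  s <- (eta / v) * .conv_time(d2v, phi_t, dt)
  t_out <- ap$time[1] + tphi[1] + dt * (seq_along(s) - 1L)
  signal_trace(t_out, s)
}

#' SFAP by point-source summation (reference method)
#'
#' Independent reference computation of the SFAP in an infinite homogeneous
#' medium: the fiber is discretized into segments, the transmembrane current
#' of each segment during the propagating AP is computed from the second
#' spatial derivative of the transmembrane potential, and the recorded
#' voltage is the (differential) sum of the point-source potentials
#' `i_j(t) / (4 pi sigma_e |r_j - r_e|)` over all segments.
#'
#' @param ap An [ap_waveform()] (Gaussian-parametric waveforms use the
#'   analytic second derivative; tabulated ones are interpolated).
#' @param v Conduction velocity, m/s.
#' @param eta Axial prefactor, S*m.
#' @param cfg A [point_electrode_config()] with one or two terminals.
#' @param fiber_path Straight path as `rbind(p0, p1)` or a function of
#'   arclength (see [point_electrode_profile()]).
#' @param fiber_length Fiber length, meters.
#' @param n_segments Number of segments (default 2000).
#' @param time Output time grid, seconds.
#' @param l_init AP initiation arclength, meters.
#' @return A [signal_trace()]; attribute `charge_residual` holds
#'   `max_t |sum_j i_j(t)| / max_{j,t} |i_j(t)|`, the charge-conservation
#'   residual of the discretized membrane currents.
#' @export
sfap_point_source <- function(ap, v, eta, cfg, fiber_path, fiber_length,
                              n_segments = 2000, time, l_init = 0) {
  stopifnot(inherits(ap, "ap_waveform"),
            inherits(cfg, "point_electrode_config"),
            v > 0, fiber_length > 0, n_segments >= 10)
  dl <- fiber_length / n_segments
  lmid <- (seq_len(n_segments) - 0.5) * dl
  pts <- .eval_fiber_path(fiber_path, lmid)
  pol <- if (nrow(cfg$positions) == 2L) c(1, -1) else 1
  kern <- numeric(n_segments)
  for (k in seq_len(nrow(cfg$positions))) {
    dd <- sqrt((pts[, 1] - cfg$positions[k, 1])^2 +
               (pts[, 2] - cfg$positions[k, 2])^2 +
               (pts[, 3] - cfg$positions[k, 3])^2)
    if (any(dd < dl)) stop("an electrode terminal lies within a fiber segment")
    kern <- kern + pol[k] / (4 * pi * cfg$sigma_e * dd)
  }
  # V_x(l, t) = V_t(t - (l - l_init)/v); i = eta * d2V/dl2 * dl
  #           = (eta / v^2) * V_t''(t - (l - l_init)/v) * dl
  d2fun <- .d2v_fun(ap)
  s <- numeric(length(time))
  cur_sum <- numeric(length(time))
  cur_peak <- 0
  chunk <- 256L
  for (j0 in seq(1L, n_segments, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, n_segments)
    targ <- outer(time, (lmid[jj] - l_init) / v, "-")
    imat <- (eta / v^2) * d2fun(targ) * dl      # n_t x n_chunk currents
    s <- s + drop(imat %*% kern[jj])
    cur_sum <- cur_sum + rowSums(imat)
    cur_peak <- max(cur_peak, max(abs(imat)))
  }
  out <- signal_trace(time, s)
  attr(out, "charge_residual") <- max(abs(cur_sum)) / cur_peak
  out
}

# second-derivative evaluator usable at arbitrary times (zero off support)
.d2v_fun <- function(ap) {
  if (!is.null(ap$w_V) && !is.null(ap$V_p)) {
    w <- ap$w_V; Vp <- ap$V_p
    function(t) (Vp / w^2) * (t^2 / w^2 - 1) * exp(-t^2 / (2 * w^2))
  } else {
    d2 <- second_time_derivative(ap)
    tt <- ap$time
    function(t) {
      out <- array(0, dim = if (is.null(dim(t))) length(t) else dim(t))
      inside <- t >= tt[1] & t <= tt[length(tt)]
      out[inside] <- stats::approx(tt, d2, xout = t[inside])$y
      out
    }
  }
}

#' Closed-form SFAP for Gaussian AP and Gaussian monopolar contact
#'
#' For a Gaussian AP `V_p exp(-t^2/2w_V^2)` and a monopolar Gaussian
#' sensitivity profile `Phi_p exp(-(x - x_c)^2 / 2 w_phi^2)` the
#' reciprocity convolution has the closed form
#' \deqn{S(t) = \sqrt{2\pi}\, V_p \Phi_p \eta \frac{w_\phi w_V}{w_C^5 v^2}
#'   e^{-(t - x_c/v)^2 / 2 w_C^2}\,(t - x_c/v - w_C)(t - x_c/v + w_C)}
#' with `w_C = sqrt((w_phi/v)^2 + w_V^2)`, the temporal width of the
#' recorded waveform. The signal peaks (negatively) at `t = x_c/v`, the
#' transit time to the contact, with magnitude
#' `sqrt(2 pi) V_p Phi_p eta w_phi w_V / (v^2 w_C^3)`, and crosses zero at
#' `x_c/v +/- w_C` — the typical central peak between two side-lobes of
#' opposite polarity.
#'
#' @param time Output time grid, seconds.
#' @param V_p,w_V AP peak (V) and width (s).
#' @param Phi_p,w_phi,x_c Contact peak (V/A), width (m) and center (m).
#' @param v Conduction velocity, m/s.
#' @param eta Axial prefactor, S*m.
#' @return A [signal_trace()] with attributes `w_C`, `peak_time`,
#'   `zero_crossings` (length 2), `peak_magnitude`.
#' @export
gaussian_sfap <- function(time, V_p, w_V, Phi_p, w_phi, x_c, v, eta) {
  stopifnot(w_V > 0, w_phi > 0, v > 0)
  w_C <- sqrt((w_phi / v)^2 + w_V^2)
  u <- time - x_c / v
  s <- sqrt(2 * pi) * V_p * Phi_p * eta * w_phi * w_V / (w_C^5 * v^2) *
    exp(-u^2 / (2 * w_C^2)) * (u - w_C) * (u + w_C)
  out <- signal_trace(time, s)
  attr(out, "w_C") <- w_C
  attr(out, "peak_time") <- x_c / v
  attr(out, "zero_crossings") <- c(x_c / v - w_C, x_c / v + w_C)
  attr(out, "peak_magnitude") <-
    sqrt(2 * pi) * abs(V_p * Phi_p) * eta * w_phi * w_V / (v^2 * w_C^3)
  out
}

#' SFAP peak amplitude as a function of fiber diameter
#'
#' Evaluates the closed-form peak magnitude
#' `sqrt(2 pi) V_p Phi_p eta(d) w_phi w_V / (v(d)^2 w_C(d)^3)` over a
#' diameter sweep. For myelinated fibers (`v = a d`) the amplitude grows as
#' `d^3` well below the critical diameter and plateaus well above it; for
#' unmyelinated fibers (`v = b sqrt(d)`) it increases monotonically over
#' the physiological range.
#'
#' @param law A [conduction_law()].
#' @param d Diameter grid, meters.
#' @param w_V AP width, s.
#' @param w_phi Contact width, m.
#' @param V_p,Phi_p,sigma_tau Amplitude scales.
#' @return `data.frame(d, v, eta, w_C, amplitude)`.
#' @export
peak_amplitude_vs_diameter <- function(law, d,
                                       w_V = default_constants()$w_V_myelinated,
                                       w_phi = default_constants()$w_phi,
                                       V_p = default_constants()$V_p,
                                       Phi_p = 1,
                                       sigma_tau = default_constants()$sigma_tau) {
  v <- conduction_velocity(law, d)
  eta <- axial_prefactor(d, sigma_tau)
  w_C <- sqrt((w_phi / v)^2 + w_V^2)
  amp <- sqrt(2 * pi) * abs(V_p * Phi_p) * eta * w_phi * w_V / (v^2 * w_C^3)
  data.frame(d = d, v = v, eta = eta, w_C = w_C, amplitude = amp)
}

#' Limit-case SFAP approximations
#'
#' Two asymptotic regimes of the reciprocity SFAP:
#' * `"long_ap"` — the AP's spatial extent (`v w_V`) is much larger than the
#'   electrode's sensitive region: the signal is proportional to the local
#'   transmembrane current at the contact,
#'   `S(t) ~ (eta/v^2) V_t''(t - (x_0 - l_init)/v) * integral(Phi)`.
#' * `"short_ap"` — the AP is much shorter than the sensitive region: the
#'   signal samples the second spatial derivative of the lead field at the
#'   propagating AP location,
#'   `S(t) ~ eta v integral(V_t) * Phi''(l_init + v t)`.
#'
#' Both hold only away from the crossover `v = w_phi / w_V`.
#'
#' @param mode `"long_ap"` or `"short_ap"`.
#' @param ap An [ap_waveform()].
#' @param profile A tapered [sensitivity_profile()].
#' @param v Conduction velocity, m/s.
#' @param eta Axial prefactor, S*m.
#' @param time Output time grid, seconds.
#' @param l_init AP initiation arclength, meters.
#' @param x0 Contact center, meters; default the arclength of `max |Phi|`.
#' @return A [signal_trace()].
#' @export
limit_sfap <- function(mode = c("long_ap", "short_ap"), ap, profile, v, eta,
                       time, l_init = 0, x0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ap, "ap_waveform"), inherits(profile, "sensitivity_profile"),
            v > 0)
  l <- profile$arclength
  phi <- profile$values
  if (mode == "long_ap") {
    if (is.null(x0)) x0 <- l[which.max(abs(phi))]
    int_phi <- .trapz(l, phi)
    d2fun <- .d2v_fun(ap)
    s <- (eta / v^2) * d2fun(time - (x0 - l_init) / v) * int_phi
  } else {
    int_v <- .trapz(ap$time, ap$values)
    n <- length(phi)
    d2phi <- c(phi[3] - 2 * phi[2] + phi[1],
               phi[-c(1, 2)] - 2 * phi[-c(1, n)] + phi[-c(n - 1, n)],
               phi[n] - 2 * phi[n - 1] + phi[n - 2]) / profile$dl^2
    pd2 <- sensitivity_profile(l, d2phi, tapered = TRUE)
    s <- eta * v * int_v * time_reparameterize(pd2, v, time, l_init = l_init,
                                               method = "linear")
  }
  signal_trace(time, s)
}

#' Count the lobes of a signal
#'
#' A lobe is a local extremum whose magnitude reaches `rel_threshold` of the
#' signal's peak magnitude; consecutive extrema of the same sign are merged
#' (the larger kept) so that counted lobes alternate in polarity. Monopolar
#' SFAPs are triphasic (3 lobes); well-separated bipolar recordings give two
#' triphasic waveforms (6), merged bipolar recordings a single tetraphasic
#' one (4).
#'
#' @param s A [signal_trace()].
#' @param rel_threshold Fraction of `max |s|` an extremum must reach
#'   (default 0.05, suppressing numerical ripple).
#' @return Integer lobe count (0 for an all-zero signal).
#' @export
count_lobes <- function(s, rel_threshold = 0.05) {
  stopifnot(inherits(s, "signal_trace"))
  v <- s$values
  vmax <- max(abs(v))
  if (vmax == 0) return(0L)
  dv <- diff(v)
  sg <- sign(dv)
  sg <- sg[sg != 0]
  if (length(sg) < 2L) return(0L)
  # indices of strict local extrema
  d1 <- diff(v)
  cand <- which(d1[-1] * d1[-length(d1)] < 0) + 1L
  cand <- cand[abs(v[cand]) >= rel_threshold * vmax]
  if (!length(cand)) return(0L)
  signs <- sign(v[cand])
  keep <- logical(length(cand))
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && signs[j + 1L] == signs[i]) j <- j + 1L
    grp <- i:j
    keep[grp[which.max(abs(v[cand[grp]]))]] <- TRUE
    i <- j + 1L
  }
  sum(keep)
}
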