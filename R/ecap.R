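#' Discretized fiber-diameter grid
#'
#' Uniform diameter grid over which fiber populations are discretized;
#' default 2000 points on 0.1 to 15 micrometers.
#'
#' @param lower,upper Bounds, meters.
#' @param n Number of grid points.
#' @return Object of class `diameter_grid` with elements `d` (grid) and
#'   `delta` (spacing).
#' @export
diameter_grid <- function(lower = 0.1e-6, upper = 15e-6, n = 2000) {
  stopifnot(upper > lower, lower > 0, n >= 2)
  d <- seq(lower, upper, length.out = n)
  structure(list(d = d, delta = d[2] - d[1], lower = lower, upper = upper,
                 n = as.integer(n)),
            class = "diameter_grid")
}

.FIBER_TYPES <- c("myelinated_afferent", "myelinated_efferent",
                  "unmyelinated_afferent", "unmyelinated_efferent")

.myelination <- function(type) {
  if (grepl("^myelinated", type)) "myelinated" else "unmyelinated"
}

#' Fiber population of one type within a fascicle
#'
#' A population is a fiber count `N` and a gamma diameter density
#' (shape/scale) discretized on a [diameter_grid()] and renormalized on the
#' truncated support so that `sum(p * delta) = 1`.
#'
#' @param type One of `"myelinated_afferent"`, `"myelinated_efferent"`,
#'   `"unmyelinated_afferent"`, `"unmyelinated_efferent"`.
#' @param N Number of fibers (non-negative).
#' @param shape,scale Gamma parameters of the diameter density; `scale` in
#'   meters.
#' @param grid A [diameter_grid()].
#' @return Object of class `fiber_population`.
#' @export
fiber_population <- function(type, N, shape, scale,
                             grid = diameter_grid()) {
  type <- match.arg(type, .FIBER_TYPES)
  stopifnot(N >= 0, shape > 0, scale > 0, inherits(grid, "diameter_grid"))
  p <- stats::dgamma(grid$d, shape = shape, scale = scale)
  Z <- sum(p) * grid$delta
  if (Z <= 0) stop("diameter density has no mass on the grid")
  structure(list(type = type, N = N, shape = shape, scale = scale,
                 grid = grid, p = p / Z),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf(
    "<fiber_population> %s, N = %g, gamma(shape = %.3g, scale = %.3g um)\n",
    x$type, x$N, x$shape, x$scale * 1e6))
  invisible(x)
}

#' Fascicle: geometry, populations, lead field, recruitment
#'
#' Fibers within one fascicle share a sensitivity profile (the lead field
#' interpolated along the fascicle center-line) and a recruitment curve per
#' myelination class.
#'
#' @param id Fascicle identifier.
#' @param centroid 2-D cross-section position, meters.
#' @param area Cross-section area, m^2.
#' @param populations Named list of [fiber_population()]s.
#' @param sensitivity A tapered [sensitivity_profile()].
#' @param recruitment Named list with elements `myelinated` and/or
#'   `unmyelinated`, each a [recruitment_curve()].
#' @return Object of class `fascicle`.
#' @export
fascicle <- function(id, centroid, area, populations, sensitivity,
                     recruitment) {
  stopifnot(area > 0, length(centroid) == 2,
            inherits(sensitivity, "sensitivity_profile"))
  for (p in populations) stopifnot(inherits(p, "fiber_population"))
  for (r in recruitment) stopifnot(inherits(r, "recruitment_curve"))
  names(populations) <- vapply(populations, `[[`, "", "type")
  structure(list(id = id, centroid = centroid, area = area,
                 populations = populations, sensitivity = sensitivity,
                 recruitment = recruitment),
            class = "fascicle")
}

#' @export
print.fascicle <- function(x, ...) {
  Ns <- vapply(x$populations, `[[`, numeric(1), "N")
  cat(sprintf("<fascicle> %s at (%.2f, %.2f) mm, area %.3g mm^2, fibers: %s\n",
              as.character(x$id), x$centroid[1] * 1e3, x$centroid[2] * 1e3,
              x$area * 1e6,
              paste(sprintf("%s=%g", names(Ns), Ns), collapse = ", ")))
  invisible(x)
}

#' Diameter-dependent scaling function of eCAP contributions
#'
#' Per-diameter weight `w(d) = R(d) N p(d) delta_d eta(d) / v(d)`
#' combining recruitment, fiber count and density, and the axial-current
#' scaling of the SFAP.
#'
#' @param pop A [fiber_population()].
#' @param curve A [recruitment_curve()] for the population's myelination
#'   class.
#' @param I Stimulus current, amperes.
#' @param law A [conduction_law()] (default: the fitted law for the
#'   population's myelination class).
#' @param sigma_tau Axial conductivity, S/m.
#' @return Numeric vector of weights on `pop$grid$d`.
#' @export
scaling_function <- function(pop, curve, I, law = NULL,
                             sigma_tau = default_constants()$sigma_tau) {
  stopifnot(inherits(pop, "fiber_population"),
            inherits(curve, "recruitment_curve"))
  if (is.null(law)) law <- conduction_law(.myelination(pop$type))
  d <- pop$grid$d
  R <- rescale_to_diameter(curve, d, I)
  v <- conduction_velocity(law, d)
  eta <- axial_prefactor(d, sigma_tau)
  R * pop$N * pop$p * pop$grid$delta * eta / v
}

#' Recruited fraction of a population
#'
#' `integral R(d) p(d) dd` over the diameter grid.
#'
#' @inheritParams scaling_function
#' @return Scalar in `[0, 1]`.
#' @export
recruited_fraction <- function(pop, curve, I) {
  stopifnot(inherits(pop, "fiber_population"))
  R <- rescale_to_diameter(curve, pop$grid$d, I)
  sum(R * pop$p) * pop$grid$delta
}

#' Exposure function of a fascicle and fiber type
#'
#' The per-fascicle convolution kernel
#' `X(t) = sum_d w(d) Phi(l_init + v(d) t)`, the diameter-weighted sum of
#' velocity-reparameterized sensitivity functions. Convolving `X` with the
#' second temporal derivative of the AP yields the fascicle's eCAP
#' contribution.
#'
#' @param fasc A [fascicle()].
#' @param type Fiber type (one of the population names).
#' @param I Stimulus current, amperes.
#' @param time Uniform time grid, seconds.
#' @param l_init AP initiation arclength, meters.
#' @param sigma_tau Axial conductivity, S/m.
#' @param skip_tol Diameter bins whose weight is below `skip_tol` times the
#'   maximum weight are skipped (relative truncation of negligible mass).
#' @return A [signal_trace()] of `X(t)` (units V*S/A per second of AP
#'   curvature; the kernel of the eCAP convolution).
#' @export
exposure_function <- function(fasc, type, I, time, l_init = 0,
                              sigma_tau = default_constants()$sigma_tau,
                              skip_tol = 1e-9) {
  stopifnot(inherits(fasc, "fascicle"))
  pop <- fasc$populations[[type]]
  if (is.null(pop)) stop("fascicle has no population of type ", type)
  myel <- .myelination(type)
  curve <- fasc$recruitment[[myel]]
  law <- conduction_law(myel)
  w <- scaling_function(pop, curve, I, law, sigma_tau)
  v <- conduction_velocity(law, pop$grid$d)
  X <- numeric(length(time))
  if (any(w > 0)) {
    wmax <- max(w)
    for (j in which(w > skip_tol * wmax)) {
      X <- X + w[j] * time_reparameterize(fasc$sensitivity, v[j], time,
                                          l_init = l_init)
    }
  }
  signal_trace(time, X)
}

#' Assemble the eCAP of a multifascicular nerve
#'
#' The eCAP is the sum over fascicles and fiber types of the convolution of
#' the second temporal derivative of the (type-specific) AP waveform with
#' the fascicle exposure function:
#' `S(t) = sum_tau sum_i  d^2 V_tau / dt^2  *  X_{i,tau}(t)`.
#' All recruited fibers fire at `t = 0` from the common initiation
#' arclength.
#'
#' @param nerve List of [fascicle()]s.
#' @param ap_list Named list with elements `myelinated` and `unmyelinated`,
#'   each an [ap_waveform()] sharing the time step of `time`.
#' @param I Stimulus current, amperes.
#' @param time Uniform kernel time grid, seconds (default 0 to 25 ms at
#'   10 us).
#' @param l_init AP initiation arclength, meters.
#' @param types Fiber types to include (default all present).
#' @param sigma_tau Axial conductivity, S/m.
#' @return Object of class `ecap_result`: `time` (output grid), `total`,
#'   and `contributions` (matrix, one row per fascicle x type).
#' @export
compute_ecap <- function(nerve, ap_list, I,
                         time = seq(0, 25e-3, by = 1e-5),
                         l_init = 0, types = NULL,
                         sigma_tau = default_constants()$sigma_tau) {
  stopifnot(length(nerve) >= 1L)
  dt <- time[2] - time[1]
  for (ap in ap_list) {
    stopifnot(inherits(ap, "ap_waveform"))
    if (abs(ap$dt - dt) > 1e-9 * dt)
      stop("AP waveform time step must match the kernel time grid")
  }
  # common output grid spanning all convolution supports
  t_ap_min <- min(vapply(ap_list, function(a) a$time[1], numeric(1)))
  t_ap_max <- max(vapply(ap_list, function(a) max(a$time), numeric(1)))
  t_out <- seq(time[1] + t_ap_min, time[length(time)] + t_ap_max + dt / 2,
               by = dt)
  rows <- list()
  labels <- character()
  fasc_ids <- character()
  type_ids <- character()
  for (f in nerve) {
    present <- names(f$populations)
    use <- if (is.null(types)) present else intersect(types, present)
    for (ty in use) {
      if (f$populations[[ty]]$N <= 0) next
      myel <- .myelination(ty)
      ap <- ap_list[[myel]]
      if (is.null(ap)) stop("ap_list lacks a waveform for ", myel, " fibers")
      X <- exposure_function(f, ty, I, time, l_init = l_init,
                             sigma_tau = sigma_tau)
      contrib <- .conv_time(second_time_derivative(ap), X$values, dt)
      full <- numeric(length(t_out))
      off <- round((time[1] + ap$time[1] - t_out[1]) / dt)
      idx <- seq_along(contrib) + off
      keep <- idx >= 1L & idx <= length(full)
      full[idx[keep]] <- contrib[keep]
      rows[[length(rows) + 1L]] <- full
      labels <- c(labels, paste0(f$id, ".", ty))
      fasc_ids <- c(fasc_ids, as.character(f$id))
      type_ids <- c(type_ids, ty)
    }
  }
  if (!length(rows)) {
    contributions <- matrix(0, nrow = 0, ncol = length(t_out))
  } else {
    contributions <- do.call(rbind, rows)
    rownames(contributions) <- labels
  }
  total <- if (nrow(contributions)) colSums(contributions)
           else numeric(length(t_out))
  structure(list(time = t_out, total = total,
                 contributions = contributions,
                 fascicle = fasc_ids, type = type_ids, I = I),
            class = "ecap_result")
}

#' @export
print.ecap_result <- function(x, ...) {
  cat(sprintf(
    "<ecap_result> I = %.3g A, %d contributions, %d samples, peak-to-peak %.3g V\n",
    x$I, nrow(x$contributions), length(x$time), diff(range(x$total))))
  invisible(x)
}

#' Per-fascicle summed contributions of an eCAP result
#'
#' @param res An `ecap_result`.
#' @return Matrix with one row per fascicle (types summed).
#' @export
fascicle_contributions <- function(res) {
  stopifnot(inherits(res, "ecap_result"))
  ids <- unique(res$fascicle)
  out <- t(vapply(ids, function(id) {
    colSums(res$contributions[res$fascicle == id, , drop = FALSE])
  }, numeric(length(res$time))))
  rownames(out) <- ids
  out
}

#' Stimulus-amplitude sweep of the eCAP
#'
#' Computes the eCAP for each stimulus current and extracts the total
#' peak-to-peak amplitude, per-fascicle peak amplitudes and per-fascicle
#' myelinated recruited fractions.
#'
#' @param nerve List of [fascicle()]s.
#' @param currents Ascending stimulus currents, amperes.
#' @inheritParams compute_ecap
#' @return List: `summary` (`data.frame(I, peak_to_peak)`),
#'   `fascicle_peak` and `recruited` (current x fascicle matrices), and
#'   `results` (list of `ecap_result`s).
#' @export
amplitude_sweep <- function(nerve, ap_list, currents,
                            time = seq(0, 25e-3, by = 1e-5),
                            l_init = 0, types = NULL,
                            sigma_tau = default_constants()$sigma_tau) {
  stopifnot(!is.unsorted(currents))
  ids <- vapply(nerve, function(f) as.character(f$id), "")
  pk <- matrix(NA_real_, length(currents), length(ids),
               dimnames = list(NULL, ids))
  rec <- pk
  pp <- numeric(length(currents))
  results <- vector("list", length(currents))
  for (k in seq_along(currents)) {
    I <- currents[k]
    res <- compute_ecap(nerve, ap_list, I, time, l_init, types, sigma_tau)
    results[[k]] <- res
    pp[k] <- diff(range(res$total))
    fc <- fascicle_contributions(res)
    pk[k, rownames(fc)] <- apply(abs(fc), 1, max)
    for (f in nerve) {
      pops <- f$populations[grepl("^myelinated", names(f$populations))]
      Ns <- vapply(pops, `[[`, numeric(1), "N")
      if (!length(pops) || sum(Ns) == 0) next
      fr <- vapply(pops, function(p)
        recruited_fraction(p, f$recruitment$myelinated, I), numeric(1))
      rec[k, as.character(f$id)] <- sum(fr * Ns) / sum(Ns)
    }
  }
  list(summary = data.frame(I = currents, peak_to_peak = pp),
       fascicle_peak = pk, recruited = rec, results = results)
}

#' Correlation and clustering of fascicular eCAP contributions
#'
#' Pearson correlation matrix of the per-fascicle contributions, followed
#' by k-means clustering of the correlation rows (fascicles with similar
#' activation produce strongly correlated contributions and cluster
#' together).
#'
#' @param res An `ecap_result` with at least 2 fascicles.
#' @param k Number of clusters (default 3).
#' @param seed Seed for k-means initialization.
#' @return List: `correlation` (matrix), `cluster` (named integer vector),
#'   `excluded` (fascicles with all-zero contribution, if any).
#' @export
contribution_correlation <- function(res, k = 3, seed = 1) {
  fc <- fascicle_contributions(res)
  if (nrow(fc) < 2L) stop("need at least 2 fascicles")
  zero <- apply(fc, 1, function(x) all(abs(x) < .Machine$double.eps * 100))
  if (any(zero))
    warning("excluding fascicles with all-zero contribution: ",
            paste(rownames(fc)[zero], collapse = ", "))
  fc <- fc[!zero, , drop = FALSE]
  cm <- stats::cor(t(fc))
  k_eff <- min(k, nrow(cm))
  set.seed(seed)
  cl <- stats::kmeans(cm, centers = k_eff, nstart = 10)$cluster
  list(correlation = cm, cluster = cl,
       excluded = rownames(fc)[zero])
}
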