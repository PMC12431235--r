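#' Synthetic nerve / electrode specification
#'
#' Parametric description of a multifascicular nerve cross-section with an
#' intrafascicular stimulating array (two columns of 8 contacts, the total
#' stimulus current divided equally over the 16 contacts) and a recording
#' cuff of 4 ring contacts (125 um thick, 3 mm apart) centered 6 cm
#' downstream of the stimulation plane. The lead fields of the built-in
#' generator are homogeneous-medium point-terminal surrogates; lead-field
#' tables from an external field solver can be substituted through the file
#' interface.
#'
#' @param seed Integer seed controlling every random draw.
#' @param semi_axes Nerve cross-section ellipse semi-axes, meters.
#' @param n_fascicles Number of fascicles to pack.
#' @param fascicle_radius_range Min/max fascicle radius, meters.
#' @param stim_columns_x x-offsets of the two stimulating contact columns.
#' @param stim_n_per_column Contacts per column (8).
#' @param cuff_offset Axial distance of the first cuff ring from the
#'   stimulation plane, meters (6 cm).
#' @param cuff_spacing Inter-ring spacing, meters (3 mm).
#' @param cuff_n_rings Number of ring contacts (4).
#' @param cuff_radius Cuff ring radius, meters.
#' @param cuff_points Point terminals discretizing each ring.
#' @param recording_pair Indices of the two rings used differentially.
#' @param sigma_e Medium conductivity, S/m.
#' @param currents Stimulus current sweep, amperes (totals over all
#'   contacts).
#' @param partial_current The partial-activation stimulus, amperes.
#' @param threshold_range Median myelinated activation threshold of the
#'   nearest / farthest fascicle, amperes (thresholds grow linearly with
#'   centroid distance to the closest stimulating contact).
#' @param threshold_gsd Geometric SD of the within-fascicle log-normal
#'   threshold spread.
#' @param threshold_cap Upper clip on thresholds, amperes (guarantees
#'   complete myelinated activation at the top of the current sweep).
#' @param unmyelinated_threshold_factor Multiplier on myelinated medians
#'   for the unmyelinated titration.
#' @param n_titration Fibers titrated per fascicle.
#' @param myelinated_density,unmyelinated_density Fibers per m^2 of
#'   fascicle cross-section.
#' @param gamma_myelinated,gamma_unmyelinated `c(shape, scale_m)` of the
#'   diameter densities.
#' @param afferent_fraction_range Afferent fraction of myelinated fibers at
#'   the two extremes of the cross-section x-axis (afferents and efferents
#'   segregate to opposite sides; unmyelinated efferents co-localize with
#'   myelinated afferents).
#' @param profile_window Arclength window `c(l0, l1)` of the tabulated lead
#'   field, meters.
#' @param profile_n Samples of the lead-field table.
#' @param diameter_n Diameter bins of the populations' [diameter_grid()].
#' @return Object of class `nerve_spec` (a validated parameter list).
#' @export
nerve_spec <- function(seed = 42L,
                       semi_axes = c(1.5e-3, 1.0e-3),
                       n_fascicles = 10L,
                       fascicle_radius_range = c(1.0e-4, 2.5e-4),
                       stim_columns_x = c(-1e-4, 1e-4),
                       stim_n_per_column = 8L,
                       cuff_offset = 6e-2,
                       cuff_spacing = 3e-3,
                       cuff_n_rings = 4L,
                       cuff_radius = 1.7e-3,
                       cuff_points = 16L,
                       recording_pair = c(1L, 4L),
                       sigma_e = 1,
                       currents = c(100, 200, 300, 400, 500) * 1e-6,
                       partial_current = 31.25e-6,
                       threshold_range = c(10e-6, 100e-6),
                       threshold_gsd = 1.2,
                       threshold_cap = 200e-6,
                       unmyelinated_threshold_factor = 10,
                       n_titration = 200L,
                       myelinated_density = 4e9,
                       unmyelinated_density = 3e10,
                       gamma_myelinated = c(6, 1e-6),
                       gamma_unmyelinated = c(4, 0.2e-6),
                       afferent_fraction_range = c(0.2, 0.8),
                       profile_window = c(0, 0.12),
                       profile_n = 601L,
                       diameter_n = 2000L) {
  spec <- list(seed = as.integer(seed), semi_axes = semi_axes,
               n_fascicles = as.integer(n_fascicles),
               fascicle_radius_range = fascicle_radius_range,
               stim_columns_x = stim_columns_x,
               stim_n_per_column = as.integer(stim_n_per_column),
               cuff_offset = cuff_offset, cuff_spacing = cuff_spacing,
               cuff_n_rings = as.integer(cuff_n_rings),
               cuff_radius = cuff_radius,
               cuff_points = as.integer(cuff_points),
               recording_pair = as.integer(recording_pair),
               sigma_e = sigma_e, currents = currents,
               partial_current = partial_current,
               threshold_range = threshold_range,
               threshold_gsd = threshold_gsd,
               threshold_cap = threshold_cap,
               unmyelinated_threshold_factor = unmyelinated_threshold_factor,
               n_titration = as.integer(n_titration),
               myelinated_density = myelinated_density,
               unmyelinated_density = unmyelinated_density,
               gamma_myelinated = gamma_myelinated,
               gamma_unmyelinated = gamma_unmyelinated,
               afferent_fraction_range = afferent_fraction_range,
               profile_window = profile_window,
               profile_n = as.integer(profile_n),
               diameter_n = as.integer(diameter_n))
  .validate_nerve_spec(spec)
  class(spec) <- "nerve_spec"
  spec
}

.validate_nerve_spec <- function(spec) {
  stopifnot(all(spec$semi_axes > 0), spec$n_fascicles >= 1,
            spec$fascicle_radius_range[1] > 0,
            spec$fascicle_radius_range[2] >= spec$fascicle_radius_range[1],
            spec$cuff_radius > max(spec$semi_axes),
            spec$sigma_e > 0, all(spec$currents > 0),
            !is.unsorted(spec$currents),
            spec$threshold_range[1] > 0,
            spec$threshold_range[2] >= spec$threshold_range[1],
            spec$threshold_gsd >= 1, spec$n_titration >= 10,
            length(spec$recording_pair) == 2L,
            all(spec$recording_pair >= 1L),
            all(spec$recording_pair <= spec$cuff_n_rings),
            spec$profile_window[2] > spec$profile_window[1],
            spec$diameter_n >= 10)
  invisible(TRUE)
}

#' @export
print.nerve_spec <- function(x, ...) {
  cat(sprintf(
    "<nerve_spec> seed %d: %d fascicles in %.1f x %.1f mm ellipse, %d stim contacts, %d-ring cuff at %.0f mm\n",
    x$seed, x$n_fascicles, x$semi_axes[1] * 1e3, x$semi_axes[2] * 1e3,
    2L * x$stim_n_per_column, x$cuff_n_rings, x$cuff_offset * 1e3))
  invisible(x)
}

#' Per-contact stimulus current
#'
#' The total stimulus current is divided equally over the stimulating
#' contacts (e.g., 500 uA over 16 contacts is 31.25 uA per contact).
#'
#' @param spec A [nerve_spec()].
#' @param I Total current, amperes.
#' @return Current per contact, amperes.
#' @export
per_contact_current <- function(spec, I) {
  I / (2 * spec$stim_n_per_column)
}

#' Default committed synthetic fixture
#'
#' The versioned nerve/electrode specification used throughout the test
#' suite: 10 fascicles, the 100-500 uA stimulus sweep and the
#' partial-activation case of 31.25 uA.
#'
#' @param seed Seed (default 42).
#' @return A [nerve_spec()].
#' @export
default_fixture <- function(seed = 42L) {
  nerve_spec(seed = seed)
}

# stimulating contact positions (3 columns: x, y, z = 0 plane)
.stim_contacts <- function(spec) {
  ys <- seq(-0.75, 0.75, length.out = spec$stim_n_per_column) *
    spec$semi_axes[2]
  xy <- expand.grid(x = spec$stim_columns_x, y = ys)
  cbind(xy$x, xy$y, 0)
}

# cuff ring terminals: list of (cuff_points x 3) matrices, one per ring
.cuff_rings <- function(spec) {
  th <- seq(0, 2 * pi, length.out = spec$cuff_points + 1L)[-1L]
  lapply(seq_len(spec$cuff_n_rings), function(r) {
    z <- spec$cuff_offset + (r - 1L) * spec$cuff_spacing
    cbind(spec$cuff_radius * cos(th), spec$cuff_radius * sin(th), z)
  })
}

# lead field of the differential ring pair along a straight fiber at (x, y)
.cuff_profile <- function(spec, centroid, arclength) {
  rings <- .cuff_rings(spec)
  pair <- spec$recording_pair
  phi <- numeric(length(arclength))
  w <- 1 / spec$cuff_points
  for (s in c(1, -1)) {
    ring <- rings[[pair[if (s == 1) 1L else 2L]]]
    for (k in seq_len(nrow(ring))) {
      dd <- sqrt((centroid[1] - ring[k, 1])^2 +
                 (centroid[2] - ring[k, 2])^2 +
                 (arclength - ring[k, 3])^2)
      phi <- phi + s * w / (4 * pi * spec$sigma_e * dd)
    }
  }
  sensitivity_profile(arclength, phi,
                      label = sprintf("cuff rings %d-%d", pair[1], pair[2]))
}

#' Generate a synthetic multifascicular nerve
#'
#' Deterministically (under the spec's seed) packs non-overlapping circular
#' fascicles into the elliptical cross-section by rejection sampling,
#' assigns each fascicle area-scaled fiber populations with a
#' location-dependent afferent/efferent composition, computes its lead
#' field from the cuff ring terminals in a homogeneous medium (tapered to
#' zero at the window ends), and builds per-fascicle recruitment curves by
#' synthetic titration: median thresholds grow linearly with the centroid
#' distance to the nearest stimulating contact, with a log-normal
#' within-fascicle spread.
#'
#' @param spec A [nerve_spec()].
#' @param max_attempts Rejection-sampling budget for the packing.
#' @return List of class `synthetic_nerve`: `fascicles` (list of
#'   [fascicle()]s), `spec`, `stim_contacts`, `cuff_rings`.
#' @export
synth_nerve <- function(spec = default_fixture(), max_attempts = 5000L) {
  .validate_nerve_spec(spec)
  set.seed(spec$seed)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  rmin <- spec$fascicle_radius_range[1]
  rmax <- spec$fascicle_radius_range[2]
  centers <- matrix(NA_real_, spec$n_fascicles, 2)
  radii <- numeric(spec$n_fascicles)
  placed <- 0L
  attempts <- 0L
  while (placed < spec$n_fascicles) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "fascicle packing failed: placed %d of %d after %d attempts; reduce count or radii",
        placed, spec$n_fascicles, max_attempts))
    r <- stats::runif(1, rmin, rmax)
    x <- stats::runif(1, -a, a)
    y <- stats::runif(1, -b, b)
    # inside ellipse with margin r
    if ((x / (a - r))^2 + (y / (b - r))^2 >= 1) next
    if (placed > 0L) {
      dd <- sqrt((centers[seq_len(placed), 1] - x)^2 +
                 (centers[seq_len(placed), 2] - y)^2)
      if (any(dd < radii[seq_len(placed)] + r + 0.1 * rmin)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(x, y)
    radii[placed] <- r
  }
  stim <- .stim_contacts(spec)
  grid <- diameter_grid(n = spec$diameter_n)
  arcl <- seq(spec$profile_window[1], spec$profile_window[2],
              length.out = spec$profile_n)
  consts <- default_constants()
  fr <- spec$afferent_fraction_range
  fascicles <- vector("list", spec$n_fascicles)
  for (i in seq_len(spec$n_fascicles)) {
    ctr <- centers[i, ]
    area <- pi * radii[i]^2
    # location-dependent composition: afferent fraction linear in x
    f_aff <- fr[1] + (fr[2] - fr[1]) * (ctr[1] + a) / (2 * a)
    N_my <- round(spec$myelinated_density * area)
    N_un <- round(spec$unmyelinated_density * area)
    pops <- list(
      fiber_population("myelinated_afferent", round(N_my * f_aff),
                       spec$gamma_myelinated[1], spec$gamma_myelinated[2],
                       grid),
      fiber_population("myelinated_efferent", N_my - round(N_my * f_aff),
                       spec$gamma_myelinated[1], spec$gamma_myelinated[2],
                       grid),
      fiber_population("unmyelinated_afferent", N_un - round(N_un * f_aff),
                       spec$gamma_unmyelinated[1], spec$gamma_unmyelinated[2],
                       grid),
      fiber_population("unmyelinated_efferent", round(N_un * f_aff),
                       spec$gamma_unmyelinated[1], spec$gamma_unmyelinated[2],
                       grid))
    # distance-dominated synthetic titration thresholds
    dist <- min(sqrt((stim[, 1] - ctr[1])^2 + (stim[, 2] - ctr[2])^2))
    dist_norm <- dist / a
    T_med <- spec$threshold_range[1] +
      (spec$threshold_range[2] - spec$threshold_range[1]) *
      min(dist_norm, 1)
    thr_my <- pmin(T_med * exp(stats::rnorm(spec$n_titration, 0,
                                            log(spec$threshold_gsd))),
                   spec$threshold_cap)
    thr_un <- pmin(spec$unmyelinated_threshold_factor * thr_my,
                   spec$unmyelinated_threshold_factor * spec$threshold_cap)
    recr <- list(
      myelinated = titration_curve(thr_my, consts$d0_myelinated),
      unmyelinated = titration_curve(thr_un, consts$d0_unmyelinated))
    prof <- taper_ends(.cuff_profile(spec, ctr, arcl))
    fascicles[[i]] <- fascicle(
      id = sprintf("f%02d", i), centroid = ctr, area = area,
      populations = pops, sensitivity = prof, recruitment = recr)
  }
  structure(list(fascicles = fascicles, spec = spec,
                 stim_contacts = stim, cuff_rings = .cuff_rings(spec),
                 radii = radii),
            class = "synthetic_nerve")
}

#' @export
print.synthetic_nerve <- function(x, ...) {
  cat(sprintf("<synthetic_nerve> %d fascicles (seed %d)\n",
              length(x$fascicles), x$spec$seed))
  for (f in x$fascicles) print(f)
  invisible(x)
}

#' Default AP waveforms for the two myelination classes
#'
#' Parametric Gaussian APs with the fitted widths (5e-5 s myelinated,
#' 2e-4 s unmyelinated) on grids sharing the step `dt`.
#'
#' @param dt Time step, seconds (default 10 us).
#' @param V_p Peak amplitude, volts.
#' @return Named list of [ap_waveform()]s (`myelinated`, `unmyelinated`).
#' @export
default_ap_waveforms <- function(dt = 1e-5,
                                 V_p = default_constants()$V_p) {
  consts <- default_constants()
  make <- function(w_V) {
    half <- ceiling(6 * w_V / dt) * dt
    gaussian_ap(V_p, w_V, time = seq(-half, half, by = dt))
  }
  list(myelinated = make(consts$w_V_myelinated),
       unmyelinated = make(consts$w_V_unmyelinated))
}
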