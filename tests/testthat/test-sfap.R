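test_that("constant (trivially tapered) sensitivity yields a null SFAP", {
  wV <- 5e-5
  ap <- gaussian_ap(0.1, wV, time = seq(-8 * wV, 8 * wV, by = wV / 50))
  l <- seq(0, 0.12, length.out = 2001)
  const <- suppressMessages(taper_ends(sensitivity_profile(l, rep(3, 2001))))
  s <- sfap_reciprocity(ap, const, v = 20, eta = 1e-12)
  # second derivative of a baseline-returning AP integrates to ~0 against a
  # constant interior; only the taper ramps contribute
  expect_lt(max(abs(s$values)) /
              (1e-12 / 20 * max(abs(second_time_derivative(ap))) * 3),
            1e-3)
})

test_that("reciprocity convolution matches the Gaussian closed form", {
  cst <- default_constants()
  wV <- cst$w_V_myelinated
  d <- 6e-6
  v <- conduction_velocity(conduction_law("myelinated"), d)
  eta <- axial_prefactor(d)
  ap <- gaussian_ap(0.1, wV, time = seq(-6 * wV, 6 * wV, by = wV / 50))
  prof <- gaussian_test_profile(Phi_p = 1, w_phi = 1e-3, x_c = 0.06)
  s_conv <- sfap_reciprocity(ap, prof, v, eta)
  s_cf <- gaussian_sfap(s_conv$time, 0.1, wV, 1, 1e-3, 0.06, v, eta)
  expect_lt(max(abs(s_conv$values - s_cf$values)) / max(abs(s_cf$values)),
            1e-3)
})

test_that("Gaussian closed form has the predicted structure", {
  # unit parameters: w_C = sqrt(2); |S(0)| frozen from the numeric
  # convolution oracle
  tt <- seq(-10, 10, by = 1e-3)
  s <- gaussian_sfap(tt, V_p = 1, w_V = 1, Phi_p = 1, w_phi = 1, x_c = 0,
                     v = 1, eta = 1)
  expect_equal(attr(s, "w_C"), sqrt(2))
  expect_equal(abs(s$values[which(tt == 0)]), 0.8862269, tolerance = 1e-6)
  expect_equal(attr(s, "peak_magnitude"), 0.8862269, tolerance = 1e-6)
  # zero crossings of the polynomial factor at x_c/v +/- w_C
  expect_equal(attr(s, "zero_crossings"), c(-sqrt(2), sqrt(2)))
  iz <- which.min(abs(tt - sqrt(2)))
  expect_lt(abs(s$values[iz]), 1e-2 * max(abs(s$values)))
  # physical parameters: w_C and peak time
  s2 <- gaussian_sfap(seq(0, 6e-3, 1e-6), 0.1, 5e-5, 1, 1e-3, 0.06, 20,
                      1e-12)
  expect_equal(attr(s2, "w_C"), 7.071e-5, tolerance = 1e-3)
  expect_equal(attr(s2, "peak_time"), 0.06 / 20)
  expect_equal(s2$time[which.max(abs(s2$values))], 3e-3, tolerance = 1e-3)
})

test_that("reciprocity SFAP agrees with point-source summation", {
  cst <- default_constants()
  law <- conduction_law("myelinated")
  d <- 4e-6
  v <- conduction_velocity(law, d)
  eta <- axial_prefactor(d)
  ap <- gaussian_ap(0.1, cst$w_V_myelinated,
                    time = seq(-3e-4, 3e-4, by = 2e-6))
  L <- 0.3
  path <- rbind(c(0, 0, 0), c(L, 0, 0))
  cfg <- point_electrode_config(rbind(c(0.15, 1e-3, 0), c(0.16, 1e-3, 0)),
                                sigma_e = 1)
  prof <- taper_ends(point_electrode_profile(cfg, path,
                                             seq(0, L, length.out = 3001)))
  s_rec <- sfap_reciprocity(ap, prof, v, eta)
  tm <- seq(5e-3, 12e-3, by = 2e-6)
  s_ps <- sfap_point_source(ap, v, eta, cfg, path, L, n_segments = 2000,
                            time = tm)
  pred <- stats::approx(s_rec$time, s_rec$values, xout = tm)$y
  expect_gt(.r_squared <- summary(stats::lm(s_ps$values ~ pred))$r.squared,
            0.99)
  slope <- unname(stats::coef(stats::lm(s_ps$values ~ pred))[2])
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  # charge conservation of the discretized membrane currents
  expect_lt(attr(s_ps, "charge_residual"), 1e-6)
  # discretization refinement: doubling segments changes the trace < 1%
  s_ps2 <- sfap_point_source(ap, v, eta, cfg, path, L, n_segments = 4000,
                             time = tm)
  expect_lt(max(abs(s_ps2$values - s_ps$values)) / max(abs(s_ps$values)),
            0.01)
  # symmetric pair about the fiber midpoint: signal antisymmetric about the
  # midpoint-crossing time
  cfg_sym <- point_electrode_config(rbind(c(0.14, 1e-3, 0),
                                          c(0.16, 1e-3, 0)))
  tmid <- 0.15 / v
  tsym <- seq(tmid - 2e-3, tmid + 2e-3, by = 2e-6)
  s_sym <- sfap_point_source(ap, v, eta, cfg_sym, path, L,
                             n_segments = 2000, time = tsym)
  expect_lt(max(abs(s_sym$values + rev(s_sym$values))) /
              max(abs(s_sym$values)), 0.02)
})

test_that("SFAP is gauge-invariant for charge-conserving currents", {
  wV <- 5e-5
  v <- 20
  # AP grid wide enough that the waveform returns to baseline to machine
  # precision (a truncated pulse carries residual charge)
  ap <- gaussian_ap(0.1, wV, time = seq(-10 * wV, 10 * wV, by = wV / 50))
  l <- seq(0, 0.12, length.out = 4001)
  prof <- gaussian_profile(gaussian_contact(1, 1e-3, 0.06), l)
  shifted <- sensitivity_profile(l, prof$values + 5)
  expect_warning(s1 <- sfap_reciprocity(ap, prof, v, 1e-12), "gauge")
  expect_warning(s2 <- sfap_reciprocity(ap, shifted, v, 1e-12), "gauge")
  # compare where the AP kernel fully overlaps the profile window
  Tw <- 0.12 / v
  m <- 11 * wV
  keep <- s1$time > m & s1$time < Tw - m
  expect_lt(max(abs(s1$values[keep] - s2$values[keep])) /
              max(abs(s1$values)), 1e-6)
})

test_that("SFAP amplitude scaling with diameter follows the limit laws", {
  law <- conduction_law("myelinated")
  d_star <- critical_diameter(law, 1e-3, 5e-5)
  # log-log slope -> 3 well below d*, -> 0 well above
  d_small <- d_star * c(0.008, 0.01, 0.0125)
  d_large <- d_star * c(80, 100, 125)
  tab_s <- peak_amplitude_vs_diameter(law, d_small)
  tab_l <- peak_amplitude_vs_diameter(law, d_large)
  expect_equal(loglog_slope(d_small, tab_s$amplitude), 3, tolerance = 0.01)
  expect_equal(loglog_slope(d_large, tab_l$amplitude), 0, tolerance = 0.01)
  # unmyelinated amplitude strictly increasing over the physiological range
  un <- conduction_law("unmyelinated")
  tab_u <- peak_amplitude_vs_diameter(un, seq(0.1e-6, 4e-6, length.out = 100),
                                      w_V = 2e-4)
  expect_true(all(diff(tab_u$amplitude) > 0))
  # myelinated plateau: ratio at 15 vs 10 um far below the d^3 scaling,
  # and essentially 1 deep in the plateau
  tab_m <- peak_amplitude_vs_diameter(law, c(10e-6, 15e-6, 100e-6, 150e-6))
  expect_lt(tab_m$amplitude[2] / tab_m$amplitude[1], 1.2)
  expect_lt(tab_m$amplitude[4] / tab_m$amplitude[3], 1.02)
})

test_that("limit-case approximations hold in their regimes only", {
  wV <- 5e-5
  eta <- 1e-12
  ap <- gaussian_ap(0.1, wV, time = seq(-8 * wV, 8 * wV, by = wV / 100))
  prof <- gaussian_test_profile(n = 8001)
  v_star <- 1e-3 / wV
  errs <- sapply(c(10, 1, 0.1), function(fac) {
    v <- fac * v_star
    s_full <- sfap_reciprocity(ap, prof, v, eta)
    c(long = rel_l2(limit_sfap("long_ap", ap, prof, v, eta,
                               time = s_full$time)$values, s_full$values),
      short = rel_l2(limit_sfap("short_ap", ap, prof, v, eta,
                                time = s_full$time)$values, s_full$values))
  })
  expect_lt(errs["long", 1], 0.05)   # v = 10 w_phi/w_V
  expect_lt(errs["short", 3], 0.05)  # v = 0.1 w_phi/w_V
  expect_gt(errs["long", 2], 0.05)   # crossover: neither limit valid
  expect_gt(errs["short", 2], 0.05)
})

test_that("time-integral of an SFAP from a baseline-returning AP is ~0", {
  cst <- default_constants()
  wV <- cst$w_V_myelinated
  ap <- gaussian_ap(0.1, wV, time = seq(-8 * wV, 8 * wV, by = wV / 50))
  prof <- gaussian_test_profile()
  s <- sfap_reciprocity(ap, prof, 20, 1e-12)
  expect_lt(abs(sum(s$values) * s$dt) / (max(abs(s$values)) *
                                           attr(gaussian_sfap(
                                             s$time, 0.1, wV, 1, 1e-3, 0.06,
                                             20, 1e-12), "w_C")),
            1e-4)
})

test_that("lobe counts follow the mono/bipolar transitions", {
  cst <- default_constants()
  wV <- cst$w_V_myelinated
  d <- 6e-6
  v <- conduction_velocity(conduction_law("myelinated"), d)
  eta <- axial_prefactor(d)
  ap <- gaussian_ap(0.1, wV, time = seq(-6 * wV, 6 * wV, by = wV / 50))
  mono <- sfap_reciprocity(ap, gaussian_test_profile(), v, eta)
  expect_identical(count_lobes(mono), 3L)
  w_C <- sqrt((1e-3 / v)^2 + wV^2)
  far <- gaussian_profile(list(
    gaussian_contact(1, 1e-3, 0.06),
    gaussian_contact(1, 1e-3, 0.06 + 10 * v * w_C, polarity = -1)),
    seq(0, 0.2, length.out = 6001))
  far$tapered <- TRUE
  expect_identical(count_lobes(sfap_reciprocity(ap, far, v, eta)), 6L)
  near <- gaussian_profile(list(
    gaussian_contact(1, 1e-3, 0.06),
    gaussian_contact(1, 1e-3, 0.06 + 0.3 * v * w_C, polarity = -1)),
    seq(0, 0.12, length.out = 4001))
  near$tapered <- TRUE
  s_near <- sfap_reciprocity(ap, near, v, eta)
  expect_identical(count_lobes(s_near), 4L)
  # all-zero signal has no lobes
  expect_identical(count_lobes(signal_trace(1:10 * 1e-3, rep(0, 10))), 0L)
  # small separation: bipolar SFAP ~ (separation / v) * d/dt monopolar,
  # centered between the two arrival times
  sep <- 0.3 * v * w_C
  dmono <- diff(mono$values) / mono$dt          # derivative at midpoints
  tmid <- mono$time[-length(mono$time)] + mono$dt / 2
  pred <- (sep / v) * dmono
  s_n <- stats::approx(s_near$time, s_near$values,
                       xout = tmid + sep / (2 * v))$y
  keep <- !is.na(s_n)
  fit <- stats::lm(s_n[keep] ~ pred[keep])
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)
})
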