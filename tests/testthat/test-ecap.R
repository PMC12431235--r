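# helper: fascicle with a given myelinated recruitment curve
with_recruitment <- function(f, curve) {
  f$recruitment$myelinated <- curve
  f
}

full_recruitment <- function(d0 = 4e-6) {
  recruitment_curve(c(0, 1e-9, 1), c(0, 1, 1), d0)
}

sharp_cutoff <- function(d_cut, d0 = 4e-6, I = 1) {
  x <- d_cut * I / d0
  recruitment_curve(c(0, x * (1 - 1e-9), x, 10 * x), c(0, 0, 1, 1), d0)
}

test_that("scaling function combines recruitment, density and eta/v", {
  nerve <- fixture_nerve()
  f <- nerve$fascicles[[1]]
  pop <- f$populations$myelinated_afferent
  curve <- f$recruitment$myelinated
  expect_true(all(scaling_function(pop, curve, 0) == 0))
  w <- scaling_function(pop, curve, 31.25e-6)
  expect_true(all(w >= 0))
  # full recruitment: weights proportional to p(d) * d for myelinated
  w_full <- scaling_function(pop, full_recruitment(), 1)
  law <- conduction_law("myelinated")
  ref <- pop$N * pop$p * pop$grid$delta *
    axial_prefactor(pop$grid$d) / conduction_velocity(law, pop$grid$d)
  expect_equal(w_full, ref)
  expect_equal(w_full / (pop$p * pop$grid$d),
               rep((w_full / (pop$p * pop$grid$d))[1], pop$grid$n))
})

test_that("exposure function reduces to the reparameterized lead field", {
  nerve <- fixture_nerve()
  f <- nerve$fascicles[[2]]
  grid <- f$populations$myelinated_afferent$grid
  # single nonzero diameter bin with unit weight
  j <- 1000
  pop <- f$populations$myelinated_afferent
  pop$p <- replace(numeric(grid$n), j, 1 / grid$delta)
  pop$N <- 1
  f$populations$myelinated_afferent <- pop
  f <- with_recruitment(f, full_recruitment())
  tgrid <- seq(0, 25e-3, by = 1e-5)
  X <- exposure_function(f, "myelinated_afferent", 1, tgrid)
  law <- conduction_law("myelinated")
  v <- conduction_velocity(law, grid$d[j])
  scale <- axial_prefactor(grid$d[j]) / v
  ref <- scale * time_reparameterize(f$sensitivity, v, tgrid)
  expect_equal(X$values, ref, tolerance = 1e-12)
})

test_that("diameter-grid doubling leaves the eCAP essentially unchanged", {
  nerve <- fixture_nerve()
  aps <- fixture_aps()
  f <- nerve$fascicles[[4]]
  f2 <- f
  g2 <- diameter_grid(n = 4000)
  f2$populations <- lapply(f$populations, function(p)
    fiber_population(p$type, p$N, p$shape, p$scale, g2))
  names(f2$populations) <- names(f$populations)
  I <- nerve$spec$partial_current
  r1 <- compute_ecap(list(f), aps, I)
  r2 <- compute_ecap(list(f2), aps, I)
  expect_lt(max(abs(r1$total - r2$total)) / max(abs(r1$total)), 0.01)
})

test_that("eCAP assembly is additive, linear, and reduces to the SFAP", {
  nerve <- fixture_nerve()
  aps <- fixture_aps()
  res <- fixture_ecap_partial()
  # exact additivity of contributions
  expect_equal(res$total, colSums(res$contributions),
               tolerance = 1e-12)
  # zero stimulus -> zero signal
  r0 <- compute_ecap(nerve$fascicles[1:2], aps, 0)
  expect_true(all(r0$total == 0))
  # linearity in the fiber counts
  f <- nerve$fascicles[[1]]
  f3 <- f
  f3$populations <- lapply(f$populations, function(p) { p$N <- 3 * p$N; p })
  names(f3$populations) <- names(f$populations)
  I <- nerve$spec$partial_current
  ra <- compute_ecap(list(f), aps, I)
  rb <- compute_ecap(list(f3), aps, I)
  expect_equal(rb$total, 3 * ra$total, tolerance = 1e-9)
  # degenerate population: eCAP equals the single-fiber SFAP
  fd <- nerve$fascicles[[2]]
  grid <- fd$populations$myelinated_afferent$grid
  j <- 1200
  pop <- fd$populations$myelinated_afferent
  pop$p <- replace(numeric(grid$n), j, 1 / grid$delta)
  pop$N <- 1
  fd$populations$myelinated_afferent <- pop
  fd <- with_recruitment(fd, full_recruitment())
  rd <- compute_ecap(list(fd), aps, 1, types = "myelinated_afferent")
  law <- conduction_law("myelinated")
  v <- conduction_velocity(law, grid$d[j])
  sf <- sfap_reciprocity(aps$myelinated, fd$sensitivity, v,
                         axial_prefactor(grid$d[j]))
  ref <- stats::approx(sf$time, sf$values, xout = rd$time, rule = 2)$y
  expect_lt(max(abs(rd$total - ref)) / max(abs(ref)), 1e-6)
  # mismatched AP grid is rejected
  bad_aps <- list(myelinated = gaussian_ap(0.1, 5e-5),
                  unmyelinated = fixture_aps()$unmyelinated)
  expect_error(compute_ecap(nerve$fascicles[1], bad_aps, I), "time step")
})

test_that("smooth full recruitment cancels; a sharp cutoff de-cancels", {
  nerve <- fixture_nerve()
  aps <- fixture_aps()
  f <- with_recruitment(nerve$fascicles[[3]], full_recruitment())
  res_full <- compute_ecap(list(f), aps, 1, types = "myelinated_afferent")
  # population-level cancellation: the peak of the summed eCAP is far below
  # the sum of the individual |SFAP| peaks (subsampled diameter bins,
  # weight-rescaled)
  pop <- f$populations$myelinated_afferent
  law <- conduction_law("myelinated")
  w <- scaling_function(pop, full_recruitment(), 1, law)
  idx <- which(w > 1e-6 * max(w))
  idx <- idx[seq(1, length(idx), by = 20)]
  tgrid <- seq(0, 25e-3, by = 1e-5)
  d2v <- second_time_derivative(aps$myelinated)
  peak_sum <- 0
  for (j in idx) {
    v <- conduction_velocity(law, pop$grid$d[j])
    X <- time_reparameterize(f$sensitivity, v, tgrid)
    s <- ecapsim:::.conv_time(d2v, X, 1e-5)
    peak_sum <- peak_sum + 20 * w[j] * max(abs(s))
  }
  expect_gt(peak_sum / max(abs(res_full$total)), 10)
  # partial recruitment: cutoff at the density mode raises peak-to-peak
  d_mode <- (pop$shape - 1) * pop$scale
  f_cut <- with_recruitment(nerve$fascicles[[3]], sharp_cutoff(d_mode))
  res_cut <- compute_ecap(list(f_cut), aps, 1, types = "myelinated_afferent")
  expect_gt(diff(range(res_cut$total)) / diff(range(res_full$total)), 1.5)
})

test_that("amplitude sweep shows monotone recruitment, rise-fall, plateau", {
  nerve <- fixture_nerve()
  aps <- fixture_aps()
  # designed two-population fascicle with a single sharp threshold
  f <- nerve$fascicles[[3]]
  T0 <- 20e-6
  fd <- with_recruitment(f, recruitment_curve(
    c(0, T0 * (1 - 1e-12), T0, 1), c(0, 0, 1, 1), 4e-6))
  currents <- c(5, 8, 10, 14, 20, 32, 64, 200, 400, 800) * 1e-6
  sw <- amplitude_sweep(list(fd), aps, currents,
                        types = c("myelinated_afferent",
                                  "myelinated_efferent"))
  rec <- sw$recruited[, 1]
  pk <- sw$fascicle_peak[, 1]
  expect_true(all(diff(rec) >= -1e-12))
  # rises to a maximum at partial recruitment, decays, then plateaus
  imax <- which.max(pk)
  expect_gt(imax, 1)
  expect_lt(imax, length(pk))
  expect_lt(rec[imax], 0.5)
  expect_gt(pk[imax] / pk[length(pk)], 2)
  # plateau once recruitment is complete: relative change < 1%
  plateau <- pk[rec > 0.999]
  expect_gt(length(plateau), 1)
  expect_lt(max(abs(diff(plateau))) / plateau[1], 0.01)
  # total peak-to-peak is reported per current
  expect_identical(nrow(sw$summary), length(currents))
})

test_that("fascicular contributions correlate and cluster by activation", {
  res <- fixture_ecap_partial()
  cc <- contribution_correlation(res, k = 3, seed = 7)
  expect_equal(diag(cc$correlation), rep(1, nrow(cc$correlation)),
               ignore_attr = TRUE)
  expect_true(all(abs(cc$correlation) <= 1 + 1e-12))
  expect_identical(length(unique(cc$cluster)), 3L)
  # identical contributions correlate at 1; a negated copy at -1
  fc <- fascicle_contributions(res)
  expect_equal(stats::cor(fc[1, ], fc[1, ]), 1)
  expect_equal(stats::cor(fc[1, ], -fc[1, ]), -1)
  # fascicles with near-identical recruitment and geometry cluster together:
  # pairs in the same cluster have higher mean correlation than cross-pairs
  same <- outer(cc$cluster, cc$cluster, "==")
  off <- upper.tri(cc$correlation)
  expect_gt(mean(cc$correlation[off & same]),
            mean(cc$correlation[off & !same]))
})
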