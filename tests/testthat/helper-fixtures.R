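# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fixture_nerve <- function() {
  memo("nerve", synth_nerve(default_fixture()))
}

fixture_aps <- function() {
  memo("aps", default_ap_waveforms())
}

# eCAP of the default nerve at the partial-activation stimulus
fixture_ecap_partial <- function() {
  memo("ecap_partial", {
    nerve <- fixture_nerve()
    compute_ecap(nerve$fascicles, fixture_aps(), nerve$spec$partial_current)
  })
}

# a Gaussian monopolar profile marked as tapered (negligible at the window
# ends by construction: the contact sits many widths from both ends)
gaussian_test_profile <- function(Phi_p = 1, w_phi = 1e-3, x_c = 0.06,
                                  window = c(0, 0.12), n = 4001) {
  p <- gaussian_profile(gaussian_contact(Phi_p, w_phi, x_c),
                        seq(window[1], window[2], length.out = n))
  p$tapered <- TRUE
  p
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# log-log slope of y(x) by linear regression
loglog_slope <- function(x, y) {
  unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
}
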