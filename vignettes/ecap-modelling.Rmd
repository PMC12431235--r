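---
title: "Semi-analytic eCAP modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-analytic eCAP modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecapsim)
```

## The physical model

`ecapsim` computes extracellular recordings from spatially extended neural
sources using a lead-field (reciprocity) formulation. The single
assumption behind the formulation is charge conservation: the
transmembrane currents of a fiber integrate to zero at every instant. Under
that assumption the voltage recorded between two electrodes is

$$S = \int \Phi(l)\, i(l)\, dl,$$

where $\Phi(l)$ is the potential along the fiber path per unit current
applied to the recording electrodes, and $i(l)$ the membrane current per
unit length. Charge conservation is also what makes the result
well-defined: adding a constant to $\Phi$ (a gauge shift) changes nothing
because $\int i\,dl = 0$. The package asserts this numerically
(`sfap_reciprocity()` warns when a profile has not been tapered to zero at
its ends, because a finite tabulation window breaks the assumption at the
boundaries).

For a propagating action potential, $i = \eta\, \partial^2 V_x / \partial
l^2$ with $\eta = \pi d^2 \sigma_\tau / 4$, and the SFAP becomes a
temporal convolution

$$S(t) = \frac{\eta}{v}\left(\partial_t^2 V_t(t) * \Phi(v t)\right),$$

implemented in `sfap_reciprocity()` as a discrete linear convolution with
zero padding (`stats::convolve`, FFT-based) scaled by the time step. An
independent reference route, `sfap_point_source()`, discretizes the fiber
into segments, evaluates each segment's membrane current from the second
spatial derivative of the propagating waveform, and sums point-source
potentials $1/(4\pi\sigma_e r)$ in a homogeneous medium. The two routes
agree with $R^2 > 0.99$ on a straight fiber, which is the package's main
verification benchmark; the point-source route also reports a
charge-conservation residual (`attr(, "charge_residual")`, ~1e-13 for a
baseline-complete Gaussian waveform).

### The closed form and a normalization subtlety

With Gaussian approximations $V_t = V_p e^{-t^2/2w_V^2}$ and
$\Phi = \Phi_p e^{-(x-x_c)^2/2w_\phi^2}$, the convolution evaluates in
closed form (`gaussian_sfap()`):

$$S(t) = \sqrt{2\pi}\,V_p \Phi_p \eta \frac{w_\phi w_V}{w_C^5 v^2}
  e^{-(t - x_c/v)^2/2w_C^2}\,(t - t_c - w_C)(t - t_c + w_C),
  \qquad t_c = x_c/v,$$

with $w_C = \sqrt{(w_\phi/v)^2 + w_V^2}$. The $\sqrt{2\pi}$ prefactor is
required for consistency with the defining convolution: the package's test
suite verifies the closed form against direct numeric convolution to
better than $10^{-3}$ relative error, and the prefactor was fixed against
that oracle before being frozen. Renderings of this expression that drop
the $\sqrt{2\pi}$ change only the absolute scale, never the shape, zeros
($t_c \pm w_C$) or any amplitude *ratio*.

Two limit cases (`limit_sfap()`) bracket the behavior. When the AP's
spatial extent $v w_V$ is much larger than $w_\phi$, the signal is
proportional to the local membrane current at the contact (long-AP limit);
when much smaller, it samples the second spatial derivative of the lead
field at the AP's position (short-AP limit). Both were derived by Taylor
expansion of the convolution and validated numerically: at $v = 10\,
w_\phi/w_V$ and $v = 0.1\, w_\phi/w_V$ the limits are within 1.5% relative
L2 error of the full convolution, while at the crossover $v = w_\phi/w_V$
both fail badly (>100%) — the crossover diameter
$d^* = w_\phi/(a w_V) \approx 4.7\ \mu m$ for the myelinated constants is
where SFAP behavior changes character.

## Parameters that matter

| parameter | meaning | default | unit |
|---|---|---|---|
| `a` | myelinated velocity slope, $v = a d$ | 4.3e6 | 1/s |
| `b` | unmyelinated slope, $v = b\sqrt{d}$ | 470 | m^0.5/s |
| `w_V` | Gaussian AP width (sigma) | 5e-5 (myel.), 2e-4 (unmyel.) | s |
| `w_phi` | lead-field width near one contact | 1e-3 | m |
| `sigma_tau` | axial conductivity | 1 | S/m |
| `V_p` | AP peak excursion | 0.1 | V |
| `d0` | titration reference diameter | 4e-6 (myel.), 0.8e-6 (unmyel.) | m |

All internal units are SI; micrometers and milliseconds appear only at I/O
boundaries. `sigma_tau` and `V_p` deserve emphasis: **they are pure
amplitude scale factors and their true values are not constrained by
anything this package computes**. Every quantitative claim in the test
suite is a ratio, a timing, a count or a correlation, never an absolute
voltage. `w_V` is interpreted as the Gaussian sigma of the waveform fit
(the interpretation under which the closed-form algebra is
self-consistent).

## From fiber to nerve

Each fascicle contributes the convolution of $\partial_t^2 V_t$ with an
exposure function — the diameter-weighted sum of velocity-reparameterized
lead fields:

$$X_{i,\tau}(t) = \sum_d R_{i,\tau}(d)\, N_{i,\tau}\, p_\tau(d)\, \Delta d\,
  \frac{\eta_\tau(d)}{v(d)}\, \Phi_i(l_0 + v(d) t).$$

Design choices here:

* **Diameter grid.** 2000 uniform bins on 0.1–15 μm for every fiber type,
  with the gamma density renormalized on the truncated support. Doubling
  to 4000 bins changes the eCAP by <1% (asserted), so the grid is
  converged. Bins whose weight is below 1e-9 of the maximum are skipped —
  a pure speed optimization with effect far below the convergence error.
* **Reparameterization.** $\Phi_i(v t)$ uses a natural cubic spline inside
  the tabulated support and exact zero outside, matching the tapered
  boundary.
* **Tapering.** Lead-field tables are forced to zero at the window ends:
  from each end the first point whose slope reaches `min_slope` (default:
  1% of max|Φ| per half-window — the threshold is a free choice since no
  canonical value exists) starts a tangent-line descent to zero. A profile
  with no such point falls back to a linear ramp with a message.
* **Timing.** All recruited fibers fire at $t = 0$ from a common
  initiation arclength (default 0), with the recording cuff 6 cm
  downstream. The default signal grid is 0–25 ms at 10 μs; unmyelinated
  fibers slower than ~2.4 m/s arrive after the window and are truncated —
  their diameter-density mass is negligible at the default parameters, and
  the span is configurable.
* **One AP per myelination class.** Afferents and efferents share a
  waveform; their separation in the model is purely compositional.

### Recruitment

Titration is summarized as the empirical CDF of per-fiber activation
thresholds at a reference diameter $d_0$ (`titration_curve()`), and
rescaled to any diameter through the $1/d$ threshold law:
$R(d) = R^*(d I / d_0)$. A Gaussian threshold jitter
(`jitter_thresholds()`) is available and provably lowers the maximum slope
of the recruitment curve, smoothing the eCAP.

The cancellation physics that motivates all of this: for a *smoothly*
recruited population the lobed SFAPs of neighboring diameters arrive
slightly shifted and cancel — the assembled peak is more than an order of
magnitude below the sum of individual SFAP peak magnitudes (asserted at
~150x on the default fixture). A sharp recruitment cutoff interrupts the
cancellation at the cutoff diameter and produces a dominant deflection at
that diameter's arrival time. The size of the effect scales with the
diameter-density weight at the cutoff: the test places the cutoff at the
mode of the gamma density, where it roughly doubles the peak-to-peak
amplitude; a cutoff in the sparse lower tail is invisible. The same
mechanism makes per-fascicle amplitude-vs-current curves rise to a maximum
at partial recruitment, decay, and plateau once recruitment is complete.

## The synthetic nerve generator

`synth_nerve()` emulates the study conditions end to end with no external
data: an elliptical cross-section (3 x 2 mm) packed with 10
non-overlapping circular fascicles (radii 100–250 μm) by seeded rejection
sampling; an intrafascicular stimulating array of two columns of 8
contacts with the total current divided equally over the 16 contacts (the
stimulus sweep is 100–500 μA, plus the partial-activation case 31.25 μA);
and a recording cuff of 4 rings, 3 mm apart, 6 cm downstream, each ring
discretized into 16 point terminals in a homogeneous medium of 1 S/m, read
out differentially between rings 1 and 4 (9 mm separation).

What it deliberately does *not* emulate — and hence what passing tests do
not show about real data:

* **Heterogeneous dielectric structure.** Real lead fields are shaped by
  anisotropic endoneurium, resistive perineurium and the cuff insulation;
  the built-in point-terminal fields are homogeneous-medium surrogates.
  This is the main fidelity gap; external solver tables can be loaded via
  `read_profile()`.
* **Histology-derived geometry and fiber counts.** Fascicle layout is
  random packing; per-fascicle counts are area-scaled densities
  (4e9 myelinated, 3e10 unmyelinated per m²) with an afferent fraction
  varying linearly across the cross-section (0.2 to 0.8, afferents and
  efferents on opposite sides, unmyelinated efferents co-localized with
  myelinated afferents). Real counts come from histology statistics.
* **Titration physics.** Thresholds are distance-dominated surrogates:
  fascicle median thresholds grow linearly (10 to 100 μA) with centroid
  distance to the nearest stimulating contact, log-normal within-fascicle
  spread of geometric SD 1.2, clipped at 200 μA so that the myelinated
  populations are essentially fully recruited (>99%) at 500 μA while
  activation is heterogeneous (range >0.3) at 31.25 μA. A real titration
  would couple the stimulating field to fiber electrophysiology.
* **Diameter statistics.** Gamma(6, 1 μm) myelinated and gamma(4, 0.2 μm)
  unmyelinated defaults give means of 6 μm and 0.8 μm — plausible for a
  large mammalian autonomic nerve, chosen once and not tuned.

Determinism is a contract: the same seed reproduces the nerve
bit-identically, and scenario runs write manifests with per-file checksums.

## The inverse problem

`fit_diameter_distribution()` minimizes the L1 mismatch
$\sum_i |V_i - \hat V_i|$ over the gamma (shape, scale) of the
myelinated-afferent population, all other populations fixed. The
optimizer is a compass-plus-diagonal pattern search with mesh halving on
box-normalized parameters: poll the 8 neighbors at the current step,
accept strict improvement, halve on failure, stop when the step falls
below 1e-6 of the box or the evaluation budget (500) is spent. The
diagonal directions matter because shape and scale are strongly
correlated through the distribution mean; a compass-only search stalls in
the valley. A Nelder-Mead fallback (`stats::optim`) is provided.

`make_ecap_forward()` makes the fit cheap: the velocity-reparameterized
lead-field kernels and the fixed populations' contribution are
precomputed once, so one forward evaluation is a gamma-density evaluation,
a matrix product and one FFT convolution (~0.1 s on the committed
3-fascicle fixture). From a ±30% perturbed start the search recovers the
generating parameters to ~4e-6 relative error in ~300 evaluations; the
objective at the truth is exactly zero because the reference is generated
by the same deterministic forward model. Fitting *in vivo* data would face
degeneracy across subpopulations and geometry uncertainty, which is out of
scope here.

## Numerical choices and degenerate inputs

* Convolution grids: the AP time step should resolve $w_V$ (defaults use
  $w_V/50$ for SFAP work and 10 μs for nerve-level work, i.e. 5 samples
  per $w_V$ — adequate because the eCAP kernel $X$ is much wider than
  $w_V$).
* Waveform truncation: gauge invariance and charge conservation hold to
  machine precision only for waveforms that return to baseline within the
  grid; `gaussian_ap()` therefore refuses grids shorter than $\pm 5 w_V$,
  and exact invariance checks use $\pm 10 w_V$.
* Lobe counting uses a 5%-of-peak threshold to suppress numerical ripple
  and merges consecutive same-sign extrema, keeping the larger.
* Degenerate inputs: zero-diameter fibers have zero velocity and
  prefactor; an all-zero signal has zero lobes; a constant lead field
  tapers to a ramp (with a message) and yields a null SFAP; empty
  threshold lists, non-uniform grids, descending time columns and unknown
  config keys are errors.
* Sign conventions: $S$ is positive as written in the defining integral;
  bipolar polarity is first-listed contact minus second.

## Problem sizes used in the shipped checks

The verification benchmark uses a 300 mm fiber with 2000–4000 segments and
a 2 μs output step; the nerve-level checks use the 10-fascicle fixture at
2000 diameter bins and 10 μs; the inverse-problem check uses a 3-fascicle
subset with a 500-evaluation budget. These sizes were chosen as the
smallest at which the convergence assertions (segment doubling <1%,
diameter-grid doubling <1%) already hold comfortably.

## Known limitations

Beyond the generator's fidelity gaps listed above: myelinated fibers are
treated as continuous line sources (no Ranvier-node discreteness, which
would matter when $\Phi$ varies over internode distances); no stimulus
artifact, background activity, pulse trains, conduction block, or
sensory/motor electrophysiological differences; absolute voltages are
uncalibrated ($\sigma_\tau$, $V_p$); and recruitment is single-pulse.
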