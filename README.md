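# ecapsim

Semi-analytic modelling of evoked compound action potentials (eCAPs) in
multifascicular peripheral nerves, for neural-interface designers and
computational neuroscientists who want to understand — or invert — the
signals a cuff electrode records during electrical nerve stimulation.

## The model

The voltage a pair of recording electrodes picks up from a nerve fiber is
governed by a reciprocity relation: if Φ(l) is the *sensitivity function*
(the potential along the fiber path per unit current virtually injected
into the recording electrodes), the recorded signal is

    S = ∫ Φ(l) i(l) dl,

where i(l) is the transmembrane current per unit length. During a
propagating action potential, i = η ∂²V_x/∂l² with η = π d² σ_τ / 4, and
the signal becomes a convolution in time,

    S(t) = (η / v) · ( ∂²V_t/∂t² * Φ(v·t) ),

so a single-fiber action potential (SFAP) is fully determined by the AP
waveform V_t, the conduction velocity v(d) (proportional to d for
myelinated fibers, to √d for unmyelinated ones), and the lead field Φ.
When both V_t and Φ are Gaussian (widths w_V and w_φ), the convolution has
a closed form whose temporal width is w_C = √((w_φ/v)² + w_V²) — a
triphasic wave peaking at the transit time x_c/v. The diameter
d\* at which v = w_φ/w_V separates two regimes: below it the SFAP
amplitude grows as d³ (myelinated), above it the amplitude saturates.

The nerve-level eCAP sums SFAPs over fascicles and fiber types. Each
fascicle contributes the convolution of ∂²V_t/∂t² with an *exposure
function*

    X_i,τ(t) = Σ_d R_i,τ(d) · N_i,τ p_τ(d) Δd · (η_τ(d)/v(d)) · Φ_i(v(d)·t),

where p_τ is a gamma diameter density on a 2000-point grid (0.1–15 μm) and
R_i,τ(d) is the recruitment at the stimulus current, obtained from a
titration curve at a reference diameter d₀ and rescaled through the
1/d threshold law as R(d) = R\*(d·I/d₀). Because SFAP lobes from smoothly
varying diameters cancel, fully recruited fascicles contribute weakly;
a sharp recruitment cutoff de-cancels the contributions above it and
dominates the signal — which is why eCAP amplitude is not monotone in
stimulus current. The package also solves the inverse problem: recovering
the gamma (shape, scale) of a fiber population from a reference eCAP by
derivative-free pattern search on the L1 mismatch.

A built-in generator replaces the field-solver stage with
homogeneous-medium point-terminal lead fields and synthesizes complete
multifascicular nerve/electrode fixtures, so everything runs with no
external data; lead fields from an external solver can be supplied through
plain-text tables.

## Worked example

```r
library(ecapsim)

law <- conduction_law("myelinated")     # v = a d, a = 4.3e6 1/s
d   <- 6e-6
v   <- conduction_velocity(law, d)      # 25.8 m/s
eta <- axial_prefactor(d)               # 2.83e-11 S*m

ap  <- gaussian_ap(V_p = 0.1, w_V = 5e-5)
phi <- taper_ends(gaussian_profile(gaussian_contact(1, 1e-3, x_c = 0.06),
                                   seq(0, 0.12, length.out = 4001)))
s <- sfap_reciprocity(ap, phi, v, eta)
s
#> <signal_trace> 5252 samples, dt = 1e-06 s, span [-0.0003, 0.00495] s, peak-to-peak 3.04e-09 V
count_lobes(s)
#> [1] 3
```

The SFAP is the classic triphasic wave. Its closed form confirms the
timing: the peak sits at the transit time to the contact and the width is
set by w_C:

```r
cf <- gaussian_sfap(s$time, 0.1, 5e-5, 1, 1e-3, 0.06, v, eta)
attr(cf, "w_C")        #> 6.33e-05  (seconds)
attr(cf, "peak_time")  #> 0.00233   (= 0.06 m / 25.8 m/s)
```

A full synthetic nerve, its eCAP at the partial-activation stimulus
(31.25 μA, i.e. 500 μA divided over the 16 stimulating contacts), and
recovery of the myelinated-afferent diameter distribution from a
self-generated reference:

```r
nerve <- synth_nerve(default_fixture())
aps   <- default_ap_waveforms()
res   <- compute_ecap(nerve$fascicles, aps, I = 31.25e-6)
res
#> <ecap_result> I = 3.13e-05 A, 40 contributions, 2741 samples, peak-to-peak 3.19e-06 V

fwd <- make_ecap_forward(nerve$fascicles[c(2, 3, 7)], aps, 31.25e-6)
ref <- fwd(6, 1e-6)                       # ground truth: gamma(6, 1 um)
fit <- fit_diameter_distribution(
  fit_problem(fwd, ref, init = c(6 * 1.3, 1e-6 * 0.7),
              lower = c(3, 0.5e-6), upper = c(9, 1.5e-6)))
fit$par
#>        shape        scale
#> 6.000023e+00 9.999973e-07
```

Starting 30% off, the pattern search returns the generating parameters to
a relative error of ~4e-6 in 333 forward evaluations.

A command-line wrapper with `synth`, `sfap`, `ecap`, `sweep`, `invert` and
`run` subcommands is installed at `inst/cli/ecapsim.R`; scenario files are
YAML and every run writes a manifest with checksums for reproducibility.

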