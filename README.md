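# targetkin

Global and target analysis of time-resolved difference-absorption
spectroscopy, built around the photochemistry of microbial rhodopsins.

## What problem this solves

Ultrafast pump-probe experiments on photoreceptor proteins produce
difference-absorption matrices ΔA(t, λ) spanning femtoseconds to seconds,
in which excited-state absorption, stimulated emission, ground-state bleach
and photoproduct bands overlap in both time and wavelength. Disentangling
them requires fitting the whole matrix at once with a kinetic model.
`targetkin` implements the standard hierarchy of such analyses for users of
transient-absorption, pump-dump-probe and flash-photolysis data:

* **Global (sequential/parallel) analysis** — the matrix is described by n
  components interconverting with successive lifetimes (evolution-associated
  difference spectra, EADS) or, equivalently, by a sum of exponentials
  (decay-associated difference spectra, DADS). The two are related by an
  exact triangular basis change.
* **Target analysis** — the matrix is described by an explicit compartmental
  scheme with branching, equilibria and absorbing states, yielding
  species-associated difference spectra (SADS), rate constants, branching
  fractions and photoproduct quantum yields.
* **Multi-pulse modelling** — a delayed dump pulse transfers excited-state
  population to a ground-state intermediate; pump-probe and pump-dump-probe
  matrices are fitted jointly with shared kinetics and spectra.

The forward model is exact: the rate matrix K of the compartment network is
eigendecomposed and each mode is convolved analytically with a Gaussian
instrument response,
f(t) = ½ exp(k(μ−t) + k²σ²/2) erfc((μ + kσ² − t)/(σ√2)),
evaluated in an overflow-safe scaled-erfc form. Fitting uses variable
projection (separable least squares): spectra are eliminated analytically
per wavelength and only the nonlinear parameters — log lifetimes or rates,
IRF center/width, logit dump fractions — are optimized by
Levenberg–Marquardt with jittered multi-starts. Quantum yields are
absorbing-state probabilities of the fitted scheme, cross-checked by a
Gillespie jump simulation; the amplitude degeneracy between a photoproduct
branch and its spectrum is resolved by an equal-bleach spectral constraint,
as in published target analyses of channelrhodopsin.

A synthetic-data module (`c1c2_presets()`) generates C1C2-like datasets —
six (pH 8) or seven (pH 10) femtosecond components, a 300 fs dump
experiment, and a three-stage microsecond-to-second photocycle — with known
ground truth, so every fitting stage is testable without measured data.

## Worked example

Build the primary-photochemistry target scheme (three excited states with
branching, photoproduct K1, ground-state intermediate), read off its
quantum yield, then recover the sequential constants from a simulated pH 8
matrix:

```r
library(targetkin)

pre <- c1c2_presets(ph = 8)
terminal_yields(pre$scheme)
#>  K1  GS
#> 0.3 0.7

ds <- simulate_sequential_dataset(
  pre$sequential_lifetimes, preset_component_spectra(pre), pre$irf,
  linlog_time_axis(n_points = 150, t_max = 1.25e8), pre$wavelengths,
  noise_sigma = 0.01, seed = 42)

fit <- fit_sequential(ds, init_lifetimes = c(0.2, 3, 30, 1500, 1e5, Inf),
                      irf = irf_model(0.02, fwhm = 0.2))
fit
#> <ta_fit> sequential fit, 6 components, ssq = 1.41384
#>   lifetimes (ps): 4.426e-01, 1.915e+00, 1.029e+01, 6.872e+02, 4.797e+05,       Inf
#>   parameters:
#>   parameter     value        se
#>        tau1 4.426e-01 1.080e-02
#>        tau2 1.915e+00 6.764e-02
#>        tau3 1.029e+01 5.288e-01
#>        tau4 6.872e+02 3.784e+01
#>        tau5 4.797e+05 7.940e+03
#>  irf_center 8.174e-06 2.513e-04
#>   irf_width 6.415e-02 3.016e-04
```

The six generating components (0.45 ps, 2.0 ps, 11 ps, 630 ps, 490 ns,
non-decaying) are recovered within a few percent at 1% noise; `fit$eads`
and `fit$dads` hold the associated spectra on the 380–680 nm grid, and
`svd_residual_diagnostics(fit)` confirms the residual is structureless.

Dump-pulse accounting: calibrate a 300 fs dump to remove 11% of the excited
population and ask what fraction of photoproduct is lost:

```r
d <- calibrate_dump_fraction(
  pre$scheme, pre$pdp_irf,
  dump_event(0.3, data.frame(from = c("ES1", "ES2"), to = "GSI",
                             fraction = 0.1)), 0.11)
dump_readout(pre$scheme, pre$pdp_irf, d)
#> <dump_readout> dumped excited fraction 0.110; K1 loss 0.058 at 100 ps (0.058 terminal)
```

Only ~6% of product is lost: most photoproduct is formed by the fastest
(450 fs) channel before the dump fires.

A thin command-line front end for shell use lives at
`inst/scripts/targetkin-cli.R` (subcommands `simulate`, `fit-global`,
`fit-target`, `fit-flash`), reading and writing time-explicit matrix files
and kinetic-scheme config files.

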