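# dcsflow

Blood-flow quantification for diffuse correlation spectroscopy (DCS).

DCS probes tissue perfusion by shining a long-coherence laser on the
scalp and measuring, a few centimetres away, how fast the speckle pattern
of multiply scattered light decorrelates. The measurement is the
intensity autocorrelation g2(τ); the physiological quantity is the blood
flow index BFi = αDb (mm²/s) of the tissue the photons traversed. The
hard part is the head: photons cross scalp and skull before sampling the
brain, so a measured curve mixes layers, and the classical inversion —
nonlinear least-squares fitting of an analytical model — is slow,
noise-sensitive, and biased by whatever optical properties and layer
thicknesses one assumes.

`dcsflow` implements the full quantification chain for studying exactly
these trade-offs, entirely from synthetic data:

* **Forward models.** The semi-infinite correlation-diffusion solution
  g1(τ) = [e^(−K r1)/r1 − e^(−K r2)/r2] / [e^(−K₀ r1)/r1 − e^(−K₀ r2)/r2]
  with K² = 3 μa μs′ + 6 μs′² k0² BFi τ (`semi_infinite_g1()`), the
  Siegert relation g2 = 1 + β g1² (`siegert_g2()`), and a three-layer
  scalp/skull/brain solver via the Fourier-domain interface elimination
  and an inverse Hankel transform over q ∈ [0, 30] mm⁻¹
  (`three_layer_g1()`).
* **Correlator noise.** The shot-noise-limited σ(τ) model with bin width,
  integration time and count rate, and seeded Gaussian injection
  (`noise_sigma()`, `add_noise()`).
* **Photon Monte Carlo.** A layered-slab, Henyey–Greenstein (g = 0.89),
  white (scattering-only) Monte Carlo recording per-layer path lengths
  and momentum transfer, with curve reconstruction
  G1(τ) = ⟨exp(−(k0²/3) Σᵢ Yᵢ 6Dbᵢ τ) exp(−Σᵢ μaᵢ Lᵢ)⟩
  re-weightable to arbitrary dynamics (`simulate_photons()`,
  `g1_from_histories()`).
* **Estimators.** Levenberg–Marquardt fitters for the semi-infinite and
  three-layer models (`fit_semi_infinite()`, `fit_three_layer()`), and a
  compact 1D-CNN regressor (25,506 parameters, 18 layers) that maps a
  normalized g2 curve directly to (β, BFi) (`build_model()`,
  `train_model()`, `predict_flow()`).
* **Experiments.** Relative-flow sweeps, intrinsic brain-flow
  sensitivity, repeated noise trials, and robustness sweeps over
  mis-assumed μa, μs′ and scalp/skull thicknesses (`rbfi_sweep()`,
  `sensitivity_curve()`, `noise_trials()`, `robustness_sweep()`), plus a
  command-line interface (`run_cli()`, `inst/cli/dcsflow`).

## Worked example

Generate the baseline three-layer head curve at ρ = 30 mm (scalp 5 mm,
skull 7 mm; brain BFi = 6×10⁻⁶ mm²/s, β = 0.5) and invert it both ways:

```r
library(dcsflow)

grid <- make_tau_grid()                 # 127 lags, 1 us .. <10,000 us
acq  <- acquisition(rho = 30)           # 785 nm, n = 1.37, beta = 0.5
g2   <- siegert_g2(three_layer_g1(baseline_head(), acq, grid), beta = 0.5)
g2
#> <dcs_curve:intensity> 127 lags, value[1]=1.475288, generator=three_layer

fit_semi_infinite(g2, acq)
#> <dcs_fit> beta=0.4797 BFi=3.873e-07 mm^2/s resnorm=0.00528 (converged, 7 it.)

fit_three_layer(g2, acq, head_assumed = assumed_head())
#> <dcs_fit> beta=0.5040 BFi=7.543e-06 mm^2/s resnorm=0.0003059 (converged, 11 it.)
```

The homogeneous semi-infinite fit reports 3.9×10⁻⁷ mm²/s — an order of
magnitude below the true brain value of 6×10⁻⁶, because even at 30 mm the
curve is dominated by the slow scalp (10⁻⁶) and static skull layers: this
is the superficial-contamination problem in one line. The three-layer
fit, which models those layers (with the protocol's slightly mis-assumed
optical properties), recovers 7.5×10⁻⁶ mm²/s, within ~26% of the truth,
and its residual norm is an order of magnitude smaller. The trained
network estimator and the noise/robustness comparisons between all three
methods are produced by the evaluation functions and the acceptance
script below.

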