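---
title: "Modelling Ca2+-dependent vesicle priming and fusion with primekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Ca2+-dependent vesicle priming and fusion with primekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primekin)
```

## The model

`primekin` implements a sequential-pool kinetic model of large dense-core
vesicle (LDCV) exocytosis in chromaffin cells. Vesicles mature through a
single obligatory pathway,

Depot ⇌ NRP ⇌ RRP ⇌ RRPCa ⇌ RRPCa₂ ⇌ RRPCa₃ → F,

with occupancies carried in membrane-capacitance units (fF), so the fused
pool F is directly the predicted capacitance change ΔCm. The model makes
three structural assumptions:

1. **Priming step 1 is gated by a cooperative Ca²⁺ sensor.** A priming
   sensor (PS) binds n Ca²⁺ ions in a single cooperative step,
   n·Ca²⁺ + PS ⇌ CaₙPS, and only the fully bound form promotes priming:
   k₁(Ca²⁺, t) = f(t) · k1_max, where f is the bound fraction. The sensor
   is not assumed to be at equilibrium; f obeys
   df/dt = k_on (1 − f) Ca²⁺ⁿ − k_off f with k_off = k_on K_Dⁿ, so K_D is
   the half-activation concentration and the equilibrium fraction is the
   Hill form Ca²⁺ⁿ/(K_Dⁿ + Ca²⁺ⁿ). Treating the printed K_D (0.407 µM) as
   the half-activation concentration is the only dimensionally consistent
   reading when k_on carries units of s⁻¹µM⁻ⁿ; the Hill denominators are
   implemented as K_Dⁿ + Ca²⁺ⁿ throughout. Total sensor is not limiting
   (each vesicle carries one), so a single global fraction f couples into
   k₁.
2. **Priming step 2 is accelerated by a one-site Ca²⁺ catalyst.**
   k₂ = k₂₀ + g·k_2cat and k₋₂ = k₋₂₀ + g·k₋_2cat with
   g = Ca²⁺/(K_D,cat + Ca²⁺), and k₋_2cat = k₋₂₀·k_2cat/k₂₀ so that the
   catalyst accelerates forward and reverse transitions consistently.
3. **Fusion requires three sequential Ca²⁺-binding steps** on the fusion
   sensor (forward 3k₃[Ca], 2k₃[Ca], k₃[Ca]; reverse k₋₃, 2k₋₃, 3k₋₃)
   followed by irreversible fusion at k₄. Mass over all seven states is
   conserved exactly by construction.

The alternative parallel-pool topology (a separately releasable SRP) is
deliberately not implemented; the package commits to the sequential
scheme.

## Parameters

`default_parameters()` ships calibrated sets for four conditions —
`control`, `unc13b_ko`, `munc13_1_oe`, `ubmunc13_2_oe` — that share the
sensor affinity (K_D = 0.407 µM, n = 7.38), pool size (V_tot = 2350 fF),
reverse rates (k₋₁ = 0.470 s⁻¹, k₋₂₀ = 0.021 s⁻¹), catalyst affinity
(K_D,cat = 138 µM) and fusion-sensor kinetics (k₃ = 4.4 s⁻¹µM⁻¹,
k₋₃ = 56 s⁻¹, k₄ = 1450 s⁻¹), and differ in the condition-specific rates
k_on, k1_max, k₂₀ and k_2cat. Two rates are always derived, never free:
k_off (from K_D and k_on) and k₋_2cat (detailed balance). All parameters
are strictly positive; `update_parameters()` recomputes the derived pair
whenever a primary value changes.

```{r}
generics::tidy(default_parameters("control"))
```

## Numerical choices

* **Integration.** The rates span more than four orders of magnitude
  (k₄ = 1450 s⁻¹ against k₁ ~ 10⁻² s⁻¹), so `simulate_flash()` uses a
  stiff-capable variable-step solver (`deSolve`'s `lsoda`) at relative
  tolerance 10⁻⁸ and absolute tolerance 10⁻⁶ fF. Ca²⁺ is interpolated
  piecewise-linearly between trace samples. Solver round-off below zero
  is clipped within −10⁻⁹·V_tot; anything more negative raises a
  numerical error rather than being silently repaired. Conservation is
  checked at every output point (tolerance 10⁻⁶·V_tot) and the returned
  ΔCm is the fused pool passed through a cumulative maximum, which
  removes solver-level (≤ tolerance) non-monotonicity only.
* **Initialisation.** Simulations start at the quasi-steady state of the
  mean pre-flash Ca²⁺: the balance equations of the first five pools
  (Depot…RRPCa₂) are set to zero together with mass conservation over the
  six unfused states — the RRPCa₃ balance is deliberately excluded, so a
  small fusion leak exists in principle, but at sub-micromolar pre-flash
  Ca²⁺ it moves the pools by far less than 1% of V_tot over a second
  (this is asserted in the test suite). The system is linear in the six
  occupancies at fixed rates and is solved directly; the priming sensor
  is initialised at its analytic equilibrium fraction. A kinetically
  equilibrated sensor (after the ~80 s whole-cell period) would differ,
  because at 0.5 µM the sensor's relaxation time is far longer than any
  recording; the analytic steady state is the documented convention.
* **Cost function.** `trace_cost()` compares traces on the data's native
  grid (model interpolated onto it) as
  Σ wᵢ (yᵢᵈᵃᵗᵃ − yᵢᵐᵒᵈᵉˡ)² / M with M the smaller of the two trace
  maxima — the choice that produces the larger, i.e. more conservative,
  cost. Weights are 100 up to 80 ms post-flash, 10 to 1.2 s, 1 after
  (closed-left boundaries), compensating the fixed sampling rate's bias
  toward slow components.
* **Optimisation.** `fit_model()` runs a Nelder–Mead simplex on
  log-transformed free parameters (positivity by construction), relative
  cost tolerance 10⁻⁶, up to 2000 iterations, restarted once from the
  best vertex, and never returns a cost above the starting cost. Shared
  free parameters take one value across conditions; per-condition ones
  one value each. Following the calibration design, K_D and n are fixed
  from the Hill analysis rather than fitted. `fit_hill()` and
  `fit_burst_exponentials()` use Levenberg–Marquardt (`minpack.lm`) with
  bounded parameters; the burst fit uses the raw `nls.lm` interface
  because degenerate traces legitimately push amplitudes to the zero
  bound, where the Jacobian is rank-deficient.
* **Burst decomposition.** The fitted form is two saturating exponentials
  plus a line. A third, slowest exponential with a time constant of
  several seconds is not identifiable on a 4 s window — it is locally
  linear there — so the sustained component is the line's slope, and the
  exocytotic delay is the fitted time at which the curve meets the
  pre-flash level. Components are labelled so τ_fast < τ_slow. Seeds
  (τ = 0.02 s and 0.2 s, amplitudes from early-trace quantiles) are fixed,
  making fits deterministic.
* **Amperometry conventions.** Currents are filtered with a zero-phase
  Gaussian kernel (−3 dB at 1 kHz), baselined by a 200 ms running median,
  and thresholded at 5 pA; segment boundaries sit at baseline
  re-crossings, and overlapping events split at local minima below 50% of
  the smaller adjacent peak. Rise time is measured 25–75% of peak, decay
  75–25%, duration between 5% crossings; a pre-spike foot is scored when
  the current dwells above 2 pA for at least 1 ms before the 25% rise
  point. The original analysis macro does not print its fractional
  levels; these are configurable arguments with the stated defaults. Note
  that a 1 kHz Gaussian filter slightly rounds very sharp peaks (~2% on a
  10 ms triangle) while preserving area — amplitude conventions are
  therefore filter-dependent, charge is not.
* **Morphometry conventions.** Distance bins are closed-left `[lo, hi)`;
  docked vesicles are recorded at distance 0 and always land in the first
  bin (0–4 nm in 3D mode, matching tomogram voxel size). The 2D scheme
  uses 40 nm bins to 2 µm. Unit conversions go through a single constant,
  1 µF/cm² = 10 fF/µm². Cell surface area is taken from capacitance
  (a_c = Cm / 10 fF µm⁻²); the circumference-based alternative is not
  implemented, as cultured chromaffin cells in slices are not round.

## The synthetic-data generators

Every input the pipeline consumes can be generated with a seed
(`flash_protocol()`/`make_ca_trace()`, `make_capacitance_dataset()`,
`make_amperometric_trace()`, `make_distance_sample()`); all generators are
pure functions of their arguments, and datasets carry ground truth as an
attribute. The defaults emulate the study conditions: pre-flash plateaus
of 0.25–1.7 µM covering the six binning intervals (250–350 through
1200–1700 nM), a post-flash step to ~20 µM relaxing with τ = 5 s
(post-flash decay kinetics are only shown graphically in uncaging work;
this is a documented placeholder, configurable), capacitance traces at a
500 Hz analysis grid with additive Gaussian noise (5 fF default), and
25 kHz current traces with 0.3 pA baseline noise, log-normal spike
amplitudes around 40 pA and biexponential events (τ_rise 0.5 ms, τ_decay
3 ms).

What the generators do *not* emulate — and hence what passing recovery
tests do not establish about real recordings: correlated (non-white)
capacitance noise and lock-in artefacts, Ca²⁺ indicator calibration error
and spatial Ca²⁺ gradients, cell-to-cell parameter heterogeneity beyond
additive noise, electrode drift and overlapping multi-vesicular
amperometric events beyond the simple valley-splitting rule, and
non-uniform vesicle size distributions in the distance sampler. Recovery
results on synthetic data are statements about the estimators under the
stated noise model, not about instrument physics.

## Problem sizes

The shipped tests and the acceptance analyses run at desk scale by
choice: 200 Hz capacitance grids and 4 s windows for model fits (one
two-condition fit converges in tens of cost evaluations), a fixed-step
RK4 cross-check at h = 10⁻⁴ s over 4 s, 40–90 s amperometric records at
25 kHz (2 kHz for rate-statistics replicates), and distance samples of a
few thousand vesicles. These sizes keep every analysis deterministic,
seconds-scale and fully reproducible from seeds.

## Known limitations

* The model is deterministic and whole-cell; no vesicle-level
  stochasticity, no Ca²⁺ microdomains, no channel gating.
* `fit_model()` returns point estimates only — no bootstrap or profile
  likelihood; the calibration this package mirrors reported point fits.
* The steady-state initialisation is quasi-steady by construction (see
  above); at pre-flash Ca²⁺ well above ~2 µM the neglected RRPCa₃ balance
  would no longer be negligible.
* Identifiability: with n ≈ 7, K_D and n trade off strongly in Hill fits
  on noisy data (the test suite demonstrates ~10%/~25% spread on K_D/n at
  5% multiplicative noise); fixing K_D and n during capacitance fits is
  both the historical and the practical choice.
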