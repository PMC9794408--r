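---
title: "Models and methods behind phycoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoflux)
```

This vignette is the package's own account of the science it implements:
the kinetic model and its assumptions, the surrounding photophysiology
formulas, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where more than one defensible
option existed.

## The sequential energy-transfer model

Red algal phycobilisomes funnel absorbed photon energy from phycoerythrin
(PE) in the peripheral rods through phycocyanin (PC) and the
allophycocyanin (APC) core into chlorophyll-a of photosystems I and II.
`phycoflux` models time-resolved fluorescence after a short excitation
pulse as a chain of three kinetic compartments,

$$\dot n_A = -\Big(\tfrac{1}{\tau_{AB}} + \tfrac{1}{\tau_{dA}}\Big) n_A,\qquad
\dot n_B = \tfrac{n_A}{\tau_{AB}} - \Big(\tfrac{1}{\tau_{BC}} + \tfrac{1}{\tau_{dB}}\Big) n_B,\qquad
\dot n_C = \tfrac{n_B}{\tau_{BC}} - \tfrac{n_C}{\tau_C},$$

with $n_A(0) = 1$ and the measured surface
$I(t, \lambda) = \sum_i S_i(\lambda)\, (n_i \circledast \mathrm{IRF})(t)$.
Compartment A is dominated by PE emission (560–610 nm), B mixes reduced PE
with PC and chlorophyll emission, and C collects the terminal emitters and
photosystems; $\tau_C$ represents charge separation. The assumptions are
those of linear target analysis: first-order transfer, excitation densities
low enough that annihilation is negligible, time-invariant spectra within a
compartment, and additive detector noise.

Populations are evaluated in closed form (Bateman cascade). Because the
fitted constants make the total rates of A and B *exactly* equal
($1/50 + 1/1000$ twice), the generic partial-fraction solution is
singular at the truth itself; the implementation groups rates whose
relative gap is below $10^{-6}$ and switches to the analytic
$t e^{-kt}$ (pair) and $\tfrac12 t^2 e^{-kt}$ (triple) limit forms. The
Gaussian instrument response is applied analytically: each
$t^p e^{-kt}$ term convolves to the exponentially modified Gaussian
($p = 0$) or its first and second derivatives with respect to $-k$
($p = 1, 2$), evaluated through `log(erfcx)` so that extreme arguments
explored by the optimiser cannot overflow.

### Fitting: variable projection

`fit_global()` separates the linear from the nonlinear parameters: for a
trial set of rate constants the spectra $S_i(\lambda)$ are the exact linear
least-squares solution per wavelength (optionally nonnegative via bounded
least squares), and only the free time constants are iterated, in log
space, by Levenberg–Marquardt. Convergence uses relative tolerances of
$10^{-10}$ with a 500-iteration cap; non-convergence is flagged on the
result, never raised. A deterministic multi-start (up to five fixed
perturbation patterns of the starting constants, best SSR wins) guards
against local minima without consuming the random-number stream. Standard
errors come from the Gauss–Newton Hessian with a delta-method
transformation back from log scale, and a rank check on the intensity
matrix warns when fewer than three kinetic components are identifiable.

Defaults: $\tau_{dA} = \tau_{dB} = 1000$ ps fixed (the measured exciton
lifetime of PE dissolved in water), free starts
$\tau_{AB} = \tau_{BC} = 60$ ps and $\tau_C = 250$ ps. Whether the two
50 ps transfer constants are one shared parameter or two coincidentally
equal ones cannot be decided from the data; the default fits them
independently, and `tie_transfer = TRUE` fits a single shared constant.

### Transfer efficiency: 92.6%, not 94%

Light-harvesting efficiency is the rate competition
$(1/\tau_\mathrm{transfer}) / (1/\tau_\mathrm{transfer} + 1/\tau_\mathrm{decay})$,
by default with the observed 120 ps PE-band transfer time against the
1500 ps decay of dissolved PE:

```{r}
transfer_efficiency(120, 1500)
```

Evaluating this expression gives 92.59%. Reports of ~94% for the same pair
of constants circulate; 94% is not reproducible from this formula (it
would require, e.g., a decay constant near 2 ns), so the package reports
the formula value and documents the discrepancy rather than resolving it.

### Band decay times

`band_decay_time()` integrates the surface over a wavelength band and fits
a single exponential to the post-peak tail (from the maximum until the
trace falls below 2% of peak, configurable). Note that a band decay time
is an *effective* quantity, not a rate constant of the model: in the
synthetic truth the 560–610 nm PE band receives contributions from
compartments A, B (at 70% amplitude) and weakly C, so its tail time
(~89 ps for the default truth) is substantially longer than the bare
A-compartment lifetime $1/(1/50 + 1/1000) \approx 47.6$ ps. The same
relationship — a band decay time roughly twice the elementary transfer
constant — is typical of real phycobilisome measurements.

## Optics, pigments, PAM, excitation spectra

* **Reflectance → absorbance.** $D(\lambda) = \log_{10}(1/R)$ (base-10 by
  the standard absorbance convention), non-pigment absorption removed by
  subtracting the mean over 750–800 nm. Band maxima are read at 495 (PUB),
  565 (PE), 630 (PC) and 680 nm (chlorophyll-a) as point values with
  linear interpolation; a ±5 nm window-maximum is available
  (`window = 5`) since the read-out bandwidth convention is not unique.
  In the 590–640 nm overlap region chlorophyll-a contributes ~30% and PC
  ~70%, so the 630 nm value is multiplied by 0.7 — applied only at that
  readout, matching the single published correction factor.
* **Chromophores.** Beer–Lambert, $c = A/(\varepsilon l)$, with native
  extinction coefficients 105000 (PUB), 136000 (PEB), 102000 (PCB)
  M⁻¹cm⁻¹ and $M_r = 587$ g mol⁻¹ for all three bilins; mass
  concentrations in mg/L with optional per-gram-tissue normalisation.
  Protocol-specific multi-wavelength biliprotein equations are supported
  as a runtime coefficient table (`biliprotein_concentrations()`), since
  the exact published coefficient sets vary by protocol and instrument.
* **PAM contamination model.** The detector sees flash-invariant
  phycobilisome fluorescence $C$ on top of chlorophyll fluorescence, so
  the measured signals are $f_0 = F_0 + bC$ and $f_m = F_m + bC$ and the
  apparent dark yield is $(F_m - F_0)/(F_m + bC)$ — always at or below the
  true $F_v/F_m$. In the regime $bC \approx F_m$, a fractional change $d$
  in $b$ changes the apparent yield by exactly $d/(2+d)$: 4.76% for a 10%
  change, which is why modest treatment-induced pigment shifts cannot
  move the apparent yield by more than ~5%.
* **Electron transport and light curves.**
  $\mathrm{ETR} = F_q'/F_m' \cdot \mathrm{PAR} \cdot 0.15 \cdot A$, with
  0.15 the fraction of chlorophyll-a associated with PSII in red algae and
  $A = 1 - 10^{-D}$ from the mean 400–700 nm absorbance. Light curves are
  fitted with the two-parameter Jassby–Platt tanh (no photoinhibition
  term, as only $\alpha$, $\mathrm{ETR}_{max}$ and $E_k$ are reported);
  start values take $\alpha$ from the first two nonzero steps and the
  asymptote from the largest observed ETR. Because "maximum ETR" is
  ambiguous between the fitted asymptote and the largest observation,
  both are reported (`etr_max_fit`, `etr_max_obs`).
* **Excitation spectra.** PSI-band fluorescence excitation spectra are
  normalised at 570 nm; readouts at 495/565/620 nm give the chromophore
  contributions, with PCB credited 70% of the 620 nm intensity (the rest
  is direct chlorophyll-a excitation). The PUB contribution estimator
  `pub_contribution_495()` defaults to the odds transform
  $r/(1+r)$ of the PUB:PEB energy-transfer ratio; no unique combination
  rule for the concentration/absorbance/EET ratios follows from first
  principles, so the estimator choice is always reported with its inputs.

## The synthetic-data generator

`ground_truth()` fixes the study conditions; the generators derive
deterministic per-operation substreams from one master seed, and
zero-noise simulations are bitwise-identical to the forward model.

* **Surfaces.** Compartment spectra are Gaussian band sums: A is a pure PE
  band (585 nm, 45 nm FWHM); B repeats it at 70% amplitude plus PC
  (640 nm) and chlorophyll (710 nm) bands; C has weak PE, PC red-shifted
  to 655 nm, an APC shoulder (675 nm) and strong chlorophyll emission
  (715 nm). The IRF is Gaussian with 15 ps FWHM centred at 0 — a typical
  synchroscan streak resolution, as no instrument width is otherwise
  implied. Noise is zero-mean Gaussian with
  $\sigma = 0.02\sqrt{\max(I, \mathrm{floor})}$ — shot-like scaling, the
  appropriate default for a photon-counting streak detector; real
  signal-to-noise figures are not recoverable, so this is a convention,
  not a reconstruction. The default grids are 1 ps × 2 nm over
  −50..500 ps × 550..760 nm, emulating the pixel density of a streak
  image over the stated measurement window; at substantially coarser
  sampling the two transfer constants become only weakly separable at 2%
  noise (their sum stays well determined — an intrinsic identifiability
  limit of the near-degenerate cascade, not an optimiser failure).
* **Reflectance.** Absorbance bands at 440, 495, 535, 565, 630 and
  680 nm (peaks 0.45–0.9) plus a flat non-pigment offset of 0.15,
  returned as $R = 10^{-D}$; peak heights were chosen so the implied
  absorbed fraction $A \approx 0.7$ matches strongly pigmented coralline
  tissue.
* **Rapid light curves.** Yields are the tanh response inverted through
  the ETR formula, using the absorbed fraction implied by the pigment
  truth so the synthetic study is internally coherent. The default truth
  is $\alpha = 0.08$, $\mathrm{ETR}_{max} = 10$ (so $E_k = 125$, inside
  the 0–420 step range) with yield noise 0.02. Note an arithmetic
  constraint: $F_q'/F_m'$ at the dark step equals
  $\alpha/(0.15\,A)$, so any $\alpha > 0.15 A$ forces yields above 1;
  such configurations (used in some stress tests) are accepted with a
  warning rather than rejected.
* **Excitation spectra.** Gaussian contributions at 495/565/620 nm
  (weights 0.8/1.0/0.75, 30 nm FWHM) plus a direct-chlorophyll term at
  620 nm equal to 3/7 of the PCB weight — so that exactly 70% of the
  620 nm intensity is PCB, making the generator self-consistent with the
  0.7 readout correction.
* **Treatment structure.** The 4-intensity (350/80/20/2.5 µmol photons
  m⁻²s⁻¹) × 3-spectrum (mesophotic, shallow, shallow+red at the highest
  intensity only) grid, with mild deterministic acclimation effects (PE
  up and PC down at low intensity, PUB up under the mesophotic spectrum)
  so that treatment summaries have recoverable structure.

What the generator does **not** emulate: photobleaching,
exciton–exciton annihilation at high excitation density, state
transitions, spectral separation of PSI vs PSII, instrument drift over a
months-long experiment, or biological replicate variability beyond noise.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions — not robustness to the full messiness of
measured algae.

## Validation strategy and problem sizes

The test suite checks every closed form against an independent oracle:
Bateman populations against a fourth-order Runge–Kutta integration
(max error < 10⁻⁸), IRF convolution against direct quadrature and a
Gaussian⊛Gaussian identity, variable projection against a joint
nonlinear fit of rates and amplitudes (same SSR to 10⁻⁶ relative),
excitation-loss bookkeeping against cumulative trapezoid integration,
and all arithmetic formulas against hand-computed values. Parameter
recovery is exercised on 50 simulated surfaces at the default conditions
(recovering both 50 ps constants and 220 ps within 10% in ≥90% of seeds,
and the 30% PE amplitude step between compartments A and B within
5 percentage points in the median), 200 noisy rapid light curves for
$E_k$ recovery, and a 9-sample end-to-end synthetic study for the
workflow. Residual whiteness of correctly specified fits is checked by a
runs test at $\alpha = 0.01$. These sizes keep the whole suite within a
few minutes on a single CPU while leaving the recovery statistics stable
across seeds.

## Known limitations

* The chain topology is strictly A → B → C with per-compartment loss; the
  parallel PE → core route discussed for real phycobilisomes is not
  separately parameterised (it is absorbed into the effective constants).
* Amplitudes are unconstrained by default; enforcing nonnegativity
  (`nonneg = TRUE`) is slower and rarely changes well-posed fits.
* The runs test on stacked residuals assumes exchangeable noise; strongly
  heteroscedastic detectors would need a weighted fit (the variable
  projection step is unweighted, as is conventional).
* `convolve_irf()` on sampled signals is a discrete convolution; signals
  with discontinuities are only O(Δt) accurate at the jump. The fitting
  path never uses it — model terms are convolved analytically.
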