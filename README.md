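# phycoflux

Photophysics of phycobilisome light harvesting in red algae (and
cyanobacteria): global kinetic analysis of excitation energy transfer from
time-resolved fluorescence, reflectance-based pigment absorbance,
chromophore quantification, PAM photophysiology, and excitation-spectrum
energy-transfer readouts — plus a synthetic-data generator with known ground
truth that exercises the whole pipeline.

The package is aimed at photosynthesis biophysicists and algal
physiologists who need a tested, scriptable route from raw spectroscopy
tables (delimited text) to the quantities usually reported in
light-harvesting studies: transfer time constants, compartment-associated
emission spectra, transfer efficiencies, pigment band absorbances and
ratios, chromophore concentrations, and rapid-light-curve descriptors.

## The model at the core

Excitation energy absorbed by phycoerythrin (PE) in the phycobilisome rods
migrates through phycocyanin (PC) and the allophycocyanin core into the
photosystems. Time-resolved fluorescence surfaces `I(t, λ)` are decomposed
by global target analysis into a sequential three-compartment cascade
A → B → C with per-compartment losses:

```
dn_A/dt = −(1/τ_AB + 1/τ_dA) n_A
dn_B/dt = n_A/τ_AB − (1/τ_BC + 1/τ_dB) n_B
dn_C/dt = n_B/τ_BC − n_C/τ_C
I(t, λ) = Σ_i S_i(λ) · (n_i ⊛ IRF)(t)
```

with `n_A(0) = 1`. The natural decays `τ_dA = τ_dB = 1 ns` (the exciton
lifetime of PE in water) are fixed; `τ_AB`, `τ_BC`, `τ_C` are free. The
populations are closed-form Bateman cascades; the Gaussian instrument
response is applied analytically (exponentially modified Gaussian terms,
including the degenerate `t·e^{−kt}` limits that arise because the two
total rates coincide at the fitted constants). Fitting uses variable
projection — the compartment spectra `S_i(λ)` solve a linear least-squares
problem per wavelength at each trial of the nonlinear rates, which are
minimised by Levenberg–Marquardt with a deterministic multi-start.

Around the kinetics sit the standard photophysiology computations:
`D(λ) = log10(1/R)` reflectance absorbance with 750–800 nm baseline
correction and band readouts (0.7 overlap factor at 630 nm for PC);
Beer–Lambert chromophore quantification (`c = A/(ε·l)`, native ε for PUB,
PEB, PCB); the PAM contamination model `f0 = F0 + bC`, `fm = Fm + bC`;
`ETR = Fq′/Fm′ · PAR · 0.15 · A` with `A = 1 − 10^−D`; the Jassby–Platt
light response `ETR(E) = ETRmax·tanh(αE/ETRmax)`; and the transfer
efficiency `(1/τ_transfer)/((1/τ_transfer) + (1/τ_decay))`.

## Worked example

Simulate a noisy time-resolved surface from the default ground truth
(50 ps transfers, 1 ns natural decays, 220 ps terminal decay, 15 ps IRF,
2% shot-like noise) and refit it:

```r
library(phycoflux)
truth <- ground_truth(seed = 42)
sim <- simulate_surface(truth)
fit <- fit_global(sim$surface,
                  start = compartment_model(tau_ab = 60, tau_bc = 60, tau_c = 250))
fit
#> Global target analysis fit (variable projection)
#> Sequential A -> B -> C compartment model
#>   tau_ab     49.941 ps  (free)
#>   tau_bc     49.939 ps  (free)
#>   tau_da   1000.000 ps
#>   tau_db   1000.000 ps
#>   tau_c     220.001 ps  (free)
#>   IRF: fwhm 15.00 ps, t0 0.00 ps
#>   SSR 3.58712, converged: TRUE (LM info 1, 11 iterations)
#>   approx. SE:  tau_ab 4.21, tau_bc 4.15, tau_c 0.225
```

The free constants come back at the generating values: ~50 ps for both
transfer steps and ~220 ps for charge separation in the photosystems. The
light-harvesting efficiency implied by a 120 ps band transfer time against
the 1.5 ns decay of dissolved phycoerythrin:

```r
transfer_efficiency(120, 1500)
#> [1] 0.9259259
```

i.e. 92.6% of excitations reach the reaction centres. A rapid light curve
and an excitation-spectrum readout from the same ground truth:

```r
fit_rlc(simulate_rlc(truth))
#> Jassby-Platt rapid light curve fit: ETR = ETRmax tanh(alpha E / ETRmax)
#>   alpha 0.0872, ETRmax (fit) 9.549, ETRmax (obs) 10.500, Ek 109.49
#>   SSR 3.263, model p-value 1.72e-05

eet_readout(simulate_excitation_spectrum(truth))
#> Excitation-spectrum energy-transfer readout (normalised at 570 nm)
#>   I495 (PUB) 0.8636  I565 (PEB) 1.0796  I620 raw 1.1567 (PCB 0.8097)
#>   PEB:PCB EET 1.3334; shares PUB 31.4% PEB 39.2% PCB 29.4%
```

`simulate_study()` writes a complete synthetic experiment (reflectance,
rapid light curves, excitation spectra, optional surfaces, manifest) over
the 4-intensity × 3-spectrum treatment grid, and `run_pipeline()` +
`summarise_treatments()` take it back to a tidy per-sample table and
treatment means ± SE.

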