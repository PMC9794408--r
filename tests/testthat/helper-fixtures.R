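# shared fixtures: coarse grids keep unit tests fast; the dense default
# grids are exercised by the acceptance suite

coarse_time <- seq(-30, 400, by = 2)
coarse_wl <- seq(555, 755, by = 10)

noiseless_truth <- function(...) ground_truth(noise_scale = 0, ...)

# noiseless surface on the coarse grids via the forward model (the
# simulate_surface preconditions ask for the full measurement window)
coarse_clean_surface <- function(truth = noiseless_truth()) {
  amps <- compartment_spectra(truth, coarse_wl)
  predict_surface(truth$model, amps, coarse_time, coarse_wl)
}

# piecewise-linear spectrum through anchor (wavelength, value) points
anchored_spectrum <- function(anchors) {
  spectrum_table(anchors$wavelength, anchors$value)
}
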