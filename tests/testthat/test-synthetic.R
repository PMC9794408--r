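test_that("zero-noise simulation equals the forward model bitwise", {
  truth <- noiseless_truth()
  sim <- simulate_surface(truth)
  amps <- compartment_spectra(truth, sim$surface$wavelength_nm)
  pred <- predict_surface(truth$model, amps, sim$surface$time_ps,
                          sim$surface$wavelength_nm)
  expect_identical(sim$surface$intensity, pred$intensity)
})

test_that("decoupled cascade yields one IRF-convolved exponential per trace", {
  truth <- noiseless_truth(
    model = compartment_model(tau_ab = 1e9, tau_bc = 1e9, tau_c = 220),
    emission_bands = list(
      A = data.frame(center = 585, fwhm = 45, height = 1),
      B = data.frame(center = 640, fwhm = 35, height = 0),
      C = data.frame(center = 715, fwhm = 60, height = 0)))
  sim <- simulate_surface(truth)
  t <- sim$surface$time_ps
  # with transfer off, k_A is the natural decay alone (up to 1e-9 rate)
  expected <- phycoflux:::emg_term(t, 1 / 1e9 + 1 / 1000,
                                   phycoflux:::fwhm_to_sigma(15), 0, 0L)
  shape <- compartment_spectra(truth, sim$surface$wavelength_nm)[, "A"]
  expect_equal(sim$surface$intensity, outer(expected, shape),
               tolerance = 1e-12)
})

test_that("seeding is reproducible and substreams differ", {
  t1 <- ground_truth(seed = 11)
  a <- simulate_surface(t1)
  b <- simulate_surface(t1)
  expect_identical(a$surface$intensity, b$surface$intensity)
  c2 <- simulate_surface(ground_truth(seed = 12))
  expect_false(identical(a$surface$intensity, c2$surface$intensity))

  r1 <- simulate_rlc(t1); r2 <- simulate_rlc(t1)
  expect_identical(r1$yield, r2$yield)
  expect_false(identical(r1$yield,
                         simulate_rlc(ground_truth(seed = 12))$yield))
})

test_that("simulated grids are validated against the measurement window", {
  truth <- ground_truth()
  expect_error(simulate_surface(truth, time_grid = seq(0, 500, 1)), "-50")
  expect_error(simulate_surface(truth, time_grid = seq(-50, 500, 5)),
               "step")
  expect_error(simulate_surface(truth,
                                wavelength_grid = seq(600, 760, 2)), "550")
  expect_error(simulate_reflectance(truth,
                                    wavelength_grid = seq(450, 800, 1)),
               "400")
})

test_that("reflectance generator honours its band construction", {
  empty <- ground_truth(pigment_bands = data.frame(center = numeric(),
                                                   fwhm = numeric(),
                                                   peak = numeric()),
                        pigment_offset = 0)
  r0 <- simulate_reflectance(empty)
  expect_true(all(r0$value == 1))

  r <- simulate_reflectance(ground_truth())
  d <- reflectance_to_absorbance(r)
  sel <- d$wavelength >= 650 & d$wavelength <= 700
  expect_equal(d$wavelength[sel][which.max(d$value[sel])], 680)
})

test_that("excitation generator is anchored and separates the 620 nm terms", {
  s <- simulate_excitation_spectrum(ground_truth())
  expect_equal(spectrum_value(s, 570), 1, tolerance = 1e-12)

  # phycocyanobilin weight zero: only direct chlorophyll excites at 620 nm
  no_pcb <- ground_truth(excitation = list(pub = 0.8, peb = 1, pcb = 0,
                                           chl620 = 0.3, fwhm = 30))
  s0 <- simulate_excitation_spectrum(no_pcb)
  raw620 <- spectrum_value(s0, 620) * attr(s0, "anchor_value")
  expect_equal(raw620, 0.3, tolerance = 1e-3)
})

test_that("generated tables satisfy the consuming modules' preconditions", {
  truth <- ground_truth()
  refl <- simulate_reflectance(truth)
  expect_true(all(refl$value > 0 & refl$value <= 1))
  expect_no_error(band_readout(baseline_correct(
    reflectance_to_absorbance(refl))))

  rlc <- simulate_rlc(truth)
  expect_no_error(fit_rlc(rlc))
  expect_true(all(rlc$yield >= 0 & rlc$yield <= 1))

  exc <- simulate_excitation_spectrum(truth)
  expect_no_error(eet_readout(exc))
})

test_that("ground truth survives a YAML round trip", {
  truth <- ground_truth(seed = 23, noise_scale = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$model$tau_ab, truth$model$tau_ab)
  expect_equal(back$seed, truth$seed)
  expect_equal(back$noise_scale, truth$noise_scale)
  expect_equal(back$pigment_bands, truth$pigment_bands)
  expect_equal(back$treatment_grid$spectrum, truth$treatment_grid$spectrum)
  # identical downstream behaviour
  a <- simulate_rlc(truth); b <- simulate_rlc(back)
  expect_identical(a$yield, b$yield)
})

test_that("invalid ground truths are rejected", {
  expect_error(ground_truth(noise_scale = -1))
  expect_error(ground_truth(pigment_bands = data.frame(center = 500,
                                                       fwhm = 0, peak = 1)),
               "widths")
  expect_error(ground_truth(treatment_grid = data.frame(intensity = 100,
                                                        spectrum = "shallow")),
               "350")
  expect_error(ground_truth(treatment_grid = data.frame(intensity = 350,
                                                        spectrum = "deep")),
               "labels")
})
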