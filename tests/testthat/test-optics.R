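test_that("reflectance-to-absorbance follows the decade law", {
  s <- spectrum_table(c(400, 500, 600, 700), c(1, 0.1, 0.5, 0.25))
  d <- reflectance_to_absorbance(s)
  expect_equal(d$value, c(0, 1, log10(2), log10(4)))

  expect_error(reflectance_to_absorbance(
    spectrum_table(c(400, 500), c(0.5, 0))), "500")
  expect_warning(reflectance_to_absorbance(
    spectrum_table(c(400, 500), c(1.02, 0.5))), "overshoot")

  # inverse round trip: D -> 10^-D -> D
  wl <- seq(400, 800, by = 5)
  d0 <- 0.3 + 0.5 * exp(-(wl - 565)^2 / 800)
  back <- reflectance_to_absorbance(spectrum_table(wl, 10^(-d0)))
  expect_lt(max(abs(back$value - d0)), 1e-12)
})

test_that("baseline correction zeroes the 750-800 nm mean and is idempotent", {
  wl <- seq(400, 820, by = 2)
  flat <- baseline_correct(spectrum_table(wl, rep(0.37, length(wl))))
  expect_lt(max(abs(flat$value)), 1e-12)

  shape <- 0.6 * exp(-(wl - 565)^2 / 900)
  a <- baseline_correct(spectrum_table(wl, shape))
  b <- baseline_correct(spectrum_table(wl, shape + 0.2))
  expect_equal(a$value, b$value, tolerance = 1e-12)
  expect_equal(attr(b, "baseline") - attr(a, "baseline"), 0.2)

  sel <- wl >= 750 & wl <= 800
  expect_lt(abs(mean(b$value[sel])), 1e-12)

  again <- baseline_correct(b)
  expect_equal(again$value, b$value, tolerance = 1e-12)

  expect_error(baseline_correct(spectrum_table(seq(400, 700, 2),
                                               rep(1, 151))), "750")
})

test_that("band readout applies the 0.7 phycocyanin overlap factor", {
  wl <- seq(400, 820, by = 1)
  pc_only <- spectrum_table(wl, exp(-4 * log(2) * (wl - 630)^2 / 30^2))
  ro <- band_readout(pc_only)
  expect_equal(ro$pc_raw_630, 1)
  expect_equal(ro$pc_corrected, 0.7)

  zero <- band_readout(spectrum_table(wl, rep(0, length(wl))))
  expect_equal(unlist(zero[c("pub_495", "pe_565", "pc_raw_630",
                             "pc_corrected", "chl_680")]),
               c(pub_495 = 0, pe_565 = 0, pc_raw_630 = 0,
                 pc_corrected = 0, chl_680 = 0))

  expect_error(band_readout(spectrum_table(seq(500, 800, 2), rep(1, 151))),
               "480")
})

test_that("generator round trip recovers band absorbances through optics", {
  truth <- ground_truth()
  refl <- simulate_reflectance(truth)
  absb <- baseline_correct(reflectance_to_absorbance(refl))
  # offset removed; residual limited only by the 680 nm band tail that
  # genuinely reaches the 750-800 nm baseline window
  expect_lt(max(abs(absb$value - attr(refl, "true_band_absorbance"))), 1e-7)

  ro <- band_readout(absb)
  pe_truth <- phycoflux:::gauss_band(565, 565, 35, 0.8) # the 565 band alone
  expect_lt(abs(ro$pe_565 - pe_truth) / pe_truth, 0.02)

  # single far band + offset: peak recovered to machine precision
  one <- ground_truth(pigment_bands = data.frame(center = 565, fwhm = 35,
                                                 peak = 0.8),
                      pigment_offset = 0.2)
  r1 <- simulate_reflectance(one)
  a1 <- baseline_correct(reflectance_to_absorbance(r1))
  expect_lt(abs(spectrum_value(a1, 565) - 0.8), 1e-9)
})

test_that("readouts ignore spectrum content confined above 750 nm", {
  wl <- seq(400, 820, by = 1)
  base <- 0.5 * exp(-4 * log(2) * (wl - 565)^2 / 35^2)
  bump <- ifelse(wl >= 760, 0.3 * exp(-(wl - 790)^2 / 50), 0)
  ro1 <- band_readout(baseline_correct(spectrum_table(wl, base)))
  ro2 <- band_readout(baseline_correct(spectrum_table(wl, base + bump)))
  # the >750 nm bump only shifts the baseline; band readings move together
  expect_equal(ro1$pe_565 - ro1$pub_495, ro2$pe_565 - ro2$pub_495,
               tolerance = 1e-12)
})

test_that("PEB:PCB absorbance ratio guards its denominator", {
  wl <- seq(400, 820, by = 1)
  both <- spectrum_table(wl, exp(-4 * log(2) * (wl - 565)^2 / 35^2) +
                               exp(-4 * log(2) * (wl - 630)^2 / 30^2))
  ro <- band_readout(both)
  expect_equal(peb_pcb_absorbance_ratio(ro), ro$pe_565 / (0.7 * ro$pc_raw_630))

  ro_zero <- band_readout(spectrum_table(wl, rep(0, length(wl))))
  expect_error(peb_pcb_absorbance_ratio(ro_zero), "undefined")
})

test_that("mean absorbance averages the photosynthetically active range", {
  wl <- seq(380, 820, by = 1)
  s <- spectrum_table(wl, rep(0.4, length(wl)))
  expect_equal(mean_absorbance(s), 0.4)
  expect_error(mean_absorbance(spectrum_table(seq(450, 800, 1), rep(1, 351))),
               "400")
})
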