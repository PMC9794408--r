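# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth, emulating the statistical structure the analysis assumes —
# a three-compartment emission cascade with compartment-associated spectra,
# Gaussian IRF and shot-like noise; multi-band pigment absorbance spectra;
# tanh-shaped rapid light curves; and excitation spectra with the
# chlorophyll overlap at 620 nm.

gauss_band <- function(wl, center, fwhm, height) {
  height * exp(-4 * log(2) * (wl - center)^2 / fwhm^2)
}

# Deterministic per-operation substream: one master seed, label-hashed
# offsets, everything kept inside 32-bit integer range.
substream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) * 69069 + h) %% 2147483647)
}

default_emission_bands <- function() {
  # Compartment-associated emission bands (center nm, fwhm nm, height):
  # A is pure phycoerythrin; B repeats the PE band at 70% plus phycocyanin
  # and chlorophyll emission; C has weak PE, red-shifted PC, an
  # allophycocyanin shoulder and strong chlorophyll (photosystem) emission.
  list(
    A = data.frame(center = 585, fwhm = 45, height = 1.0),
    B = data.frame(center = c(585, 640, 710),
                   fwhm = c(45, 35, 60),
                   height = c(0.7, 0.5, 0.4)),
    C = data.frame(center = c(585, 655, 675, 715),
                   fwhm = c(45, 35, 30, 60),
                   height = c(0.1, 0.35, 0.25, 0.8)))
}

default_pigment_bands <- function() {
  data.frame(center = c(440, 495, 535, 565, 630, 680),
             fwhm = c(50, 30, 25, 35, 30, 30),
             peak = c(0.9, 0.7, 0.6, 0.8, 0.45, 0.75))
}

default_treatment_grid <- function() {
  grid <- expand.grid(intensity = c(350, 80, 20, 2.5),
                      spectrum = c("mesophotic", "shallow"),
                      stringsAsFactors = FALSE)
  rbind(grid, data.frame(intensity = 350, spectrum = "shallow+red"))
}

#' Ground truth for the synthetic experiment
#'
#' Bundles everything the generators need: the kinetic model and
#' compartment-associated emission bands for time-resolved surfaces, pigment
#' absorbance bands for reflectance spectra, rapid-light-curve truth,
#' excitation-spectrum weights, noise levels, the treatment grid of the
#' emulated experiment (four intensities crossed with mesophotic/shallow
#' spectra, plus shallow+red at the highest intensity only), and a master
#' seed from which each generator derives a deterministic substream.
#'
#' @param model a [compartment_model()]; default the fitted constants
#'   (50 ps transfers, 1 ns natural decays, 220 ps terminal, 15 ps IRF).
#' @param emission_bands per-compartment band tables
#'   (`center`/`fwhm`/`height`), defaults as in [default truth][ground_truth].
#' @param noise_scale relative shot-noise factor for surfaces (default 0.02).
#' @param seed master integer seed.
#' @param pigment_bands data frame `center`/`fwhm`/`peak` of absorbance
#'   bands (defaults: 440, 495, 535, 565, 630, 680 nm).
#' @param pigment_offset flat non-pigment absorbance offset.
#' @param rlc list with `alpha`, `etr_max`, optional `absorbed` (defaults to
#'   the value implied by the pigment bands) and `noise_sd` (yield noise).
#' @param excitation list of chromophore weights `pub`, `peb`, `pcb`, the
#'   direct-chlorophyll amplitude `chl620` (default 3/7 of `pcb`, making
#'   the corrected 620 nm intensity exactly the PCB term) and band `fwhm`.
#' @param treatment_grid data frame `intensity`/`spectrum`; intensities must
#'   come from \{350, 80, 20, 2.5\} and labels from
#'   \{mesophotic, shallow, shallow+red\}.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(model = compartment_model(),
                         emission_bands = default_emission_bands(),
                         noise_scale = 0.02,
                         seed = 1L,
                         pigment_bands = default_pigment_bands(),
                         pigment_offset = 0.15,
                         rlc = list(alpha = 0.08, etr_max = 10,
                                    noise_sd = 0.02),
                         excitation = list(pub = 0.8, peb = 1, pcb = 0.75,
                                           fwhm = 30),
                         treatment_grid = default_treatment_grid()) {
  stopifnot(inherits(model, "compartment_model"))
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  for (b in emission_bands)
    if (any(b$fwhm <= 0) || any(b$height < 0))
      stop("emission band widths must be > 0 and heights >= 0", call. = FALSE)
  if (any(pigment_bands$fwhm <= 0) || any(pigment_bands$peak < 0))
    stop("pigment band widths must be > 0 and peaks >= 0", call. = FALSE)
  if (pigment_offset < 0) stop("pigment_offset must be >= 0", call. = FALSE)
  if (!all(treatment_grid$intensity %in% c(350, 80, 20, 2.5)))
    stop("treatment intensities must come from {350, 80, 20, 2.5}",
         call. = FALSE)
  if (!all(treatment_grid$spectrum %in%
           c("mesophotic", "shallow", "shallow+red")))
    stop("spectrum labels must come from {mesophotic, shallow, shallow+red}",
         call. = FALSE)
  if (is.null(excitation$chl620)) excitation$chl620 <- 3 / 7 * excitation$pcb
  if (is.null(rlc$noise_sd)) rlc$noise_sd <- 0.02
  structure(list(model = model, emission_bands = emission_bands,
                 noise_scale = noise_scale, seed = as.integer(seed),
                 pigment_bands = pigment_bands,
                 pigment_offset = pigment_offset,
                 rlc = rlc, excitation = excitation,
                 treatment_grid = treatment_grid),
            class = "ground_truth")
}

#' Compartment-associated emission spectra of a ground truth
#'
#' Realise the per-compartment emission band definitions on a wavelength
#' grid.
#'
#' @param truth a [ground_truth()].
#' @param wavelength_grid wavelengths (nm).
#' @return Matrix (`length(wavelength_grid)` x 3, columns A, B, C).
#' @export
compartment_spectra <- function(truth, wavelength_grid) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- vapply(truth$emission_bands, function(b) {
    s <- numeric(length(wavelength_grid))
    for (i in seq_len(nrow(b)))
      s <- s + gauss_band(wavelength_grid, b$center[i], b$fwhm[i],
                          b$height[i])
    s
  }, numeric(length(wavelength_grid)))
  matrix(out, ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
}

# pigment-band absorbance (without the flat offset) on a grid
pigment_absorbance <- function(truth, wavelength_grid) {
  b <- truth$pigment_bands
  s <- numeric(length(wavelength_grid))
  for (i in seq_len(nrow(b)))
    s <- s + gauss_band(wavelength_grid, b$center[i], b$fwhm[i], b$peak[i])
  s
}

# mean band absorbance over PAR (400-700 nm) implied by the pigment truth
true_mean_absorbance <- function(truth) {
  wl <- seq(400, 700, by = 1)
  mean(pigment_absorbance(truth, wl))
}

#' Simulate a time-resolved fluorescence surface
#'
#' Forward-models the surface from the ground truth ([predict_surface()])
#' and adds zero-mean shot-like Gaussian noise with standard deviation
#' `noise_scale * sqrt(max(signal, floor))` per cell (the floor keeps noise
#' alive where the signal vanishes; negative noisy values are allowed, as on
#' a real detector after background subtraction).
#'
#' @param truth a [ground_truth()].
#' @param time_grid strictly increasing times (ps) spanning at least
#'   \[-50, 500\] ps with step at most 2 ps.
#' @param wavelength_grid strictly increasing wavelengths (nm) spanning at
#'   least \[550, 760\] nm.
#' @param seed optional integer; default a substream of the truth's master
#'   seed.
#' @param floor_fraction noise floor as a fraction of the peak clean
#'   intensity.
#' @return List with `surface` (noisy [tw_surface()]), `clean` (noiseless
#'   surface) and `truth`.
#' @export
simulate_surface <- function(truth,
                             time_grid = seq(-50, 500, by = 1),
                             wavelength_grid = seq(550, 760, by = 2),
                             seed = NULL,
                             floor_fraction = 1e-3) {
  stopifnot(inherits(truth, "ground_truth"))
  check_grid(time_grid, "time_grid")
  check_grid(wavelength_grid, "wavelength_grid")
  if (time_grid[1] > -50 || time_grid[length(time_grid)] < 500 ||
      max(diff(time_grid)) > 2)
    stop("time grid must span [-50, 500] ps with step <= 2 ps",
         call. = FALSE)
  if (wavelength_grid[1] > 550 || wavelength_grid[length(wavelength_grid)] < 760)
    stop("wavelength grid must span [550, 760] nm", call. = FALSE)
  amps <- compartment_spectra(truth, wavelength_grid)
  clean <- predict_surface(truth$model, amps, time_grid, wavelength_grid)
  if (truth$noise_scale == 0) {
    return(list(surface = clean, clean = clean, truth = truth))
  }
  if (is.null(seed)) seed <- substream_seed(truth$seed, "surface")
  set.seed(seed)
  floor <- floor_fraction * max(clean$intensity)
  sd <- truth$noise_scale * sqrt(pmax(clean$intensity, floor))
  noisy <- clean$intensity +
    matrix(stats::rnorm(length(sd), sd = as.vector(sd)), nrow = nrow(sd))
  list(surface = tw_surface(time_grid, wavelength_grid, noisy),
       clean = clean, truth = truth)
}

#' Simulate a surface reflectance spectrum
#'
#' Builds the absorbance `D(lambda)` as the sum of the ground truth's
#' Gaussian pigment bands plus a flat non-pigment offset, and returns the
#' reflectance `R = 10^-D`. A round trip through
#' [reflectance_to_absorbance()] and [baseline_correct()] recovers the band
#' structure exactly.
#'
#' @param truth a [ground_truth()].
#' @param wavelength_grid wavelengths (nm) spanning at least \[400, 800\].
#' @return A reflectance [spectrum_table()]; the underlying band absorbance
#'   (offset excluded) is attached as attribute `true_band_absorbance`.
#' @export
simulate_reflectance <- function(truth,
                                 wavelength_grid = seq(400, 800, by = 1)) {
  stopifnot(inherits(truth, "ground_truth"))
  check_grid(wavelength_grid, "wavelength_grid")
  if (wavelength_grid[1] > 400 || wavelength_grid[length(wavelength_grid)] < 800)
    stop("wavelength grid must span [400, 800] nm", call. = FALSE)
  d_band <- pigment_absorbance(truth, wavelength_grid)
  out <- spectrum_table(wavelength_grid,
                        10^(-(d_band + truth$pigment_offset)))
  attr(out, "true_band_absorbance") <- d_band
  out
}

#' Simulate a rapid light curve
#'
#' Yields are generated by inverting the electron transport formula through
#' the tanh light response: `ETR(E) = ETRmax tanh(alpha E / ETRmax)` and
#' `yield = ETR / (E x psii_fraction x A)` (continued to `alpha /
#' (psii_fraction x A)` at `E = 0`), plus Gaussian yield noise. The absorbed
#' fraction defaults to the one implied by the truth's pigment bands, so the
#' synthetic study is internally coherent with its reflectance spectra.
#'
#' @param truth a [ground_truth()]; `truth$rlc` holds `alpha`, `etr_max`,
#'   `noise_sd` and optionally `absorbed`.
#' @param steps irradiance steps (umol photons m^-2 s^-1), nonnegative.
#' @param seed optional integer; default a substream of the master seed.
#' @return An [rlc_table()]; the generating parameters are attached as
#'   attribute `truth`.
#' @export
simulate_rlc <- function(truth,
                         steps = c(0, 60, 120, 180, 240, 300, 360, 420),
                         seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(steps < 0)) stop("irradiance steps must be nonnegative",
                           call. = FALSE)
  alpha <- truth$rlc$alpha
  etr_max <- truth$rlc$etr_max
  if (is.null(alpha) || alpha <= 0 || is.null(etr_max) || etr_max <= 0)
    stop("rlc truth requires alpha > 0 and etr_max > 0", call. = FALSE)
  absorbed <- truth$rlc$absorbed
  if (is.null(absorbed)) absorbed <- absorbed_fraction(true_mean_absorbance(truth))
  psii <- 0.15
  steps <- sort(steps)
  rate <- etr_max * tanh(alpha * steps / etr_max)
  yield <- ifelse(steps > 0, rate / (steps * psii * absorbed),
                  alpha / (psii * absorbed))
  if (truth$rlc$noise_sd > 0) {
    if (is.null(seed)) seed <- substream_seed(truth$seed, "rlc")
    set.seed(seed)
    yield <- yield + stats::rnorm(length(yield), sd = truth$rlc$noise_sd)
    yield <- pmax(yield, 0)    # a PAM instrument never reports negative yield
  }
  out <- rlc_table(steps, yield, absorbed, psii)
  attr(out, "truth") <- list(alpha = alpha, etr_max = etr_max,
                             ek = etr_max / alpha, absorbed = absorbed)
  out
}

#' Simulate a PSI fluorescence-excitation spectrum
#'
#' Weighted Gaussian contributions of phycourobilin (495 nm),
#' phycoerythrobilin (565 nm) and phycocyanobilin (620 nm), plus a direct
#' chlorophyll-a excitation term at 620 nm (default 3/7 of the PCB weight,
#' so PCB accounts for exactly 70% of the 620 nm intensity), normalised to
#' 1 at 570 nm.
#'
#' @param truth a [ground_truth()]; `truth$excitation` holds the weights.
#' @param wavelength_grid excitation wavelengths (nm) covering
#'   \[450, 650\].
#' @return A normalised excitation [spectrum_table()]; the generating
#'   weights and their implied PEB:PCB ratio are attached as attribute
#'   `truth`.
#' @export
simulate_excitation_spectrum <- function(truth,
                                         wavelength_grid = seq(450, 650, by = 1)) {
  stopifnot(inherits(truth, "ground_truth"))
  check_grid(wavelength_grid, "wavelength_grid")
  if (wavelength_grid[1] > 450 || wavelength_grid[length(wavelength_grid)] < 650)
    stop("wavelength grid must cover [450, 650] nm", call. = FALSE)
  ex <- truth$excitation
  v <- gauss_band(wavelength_grid, 495, ex$fwhm, ex$pub) +
    gauss_band(wavelength_grid, 565, ex$fwhm, ex$peb) +
    gauss_band(wavelength_grid, 620, ex$fwhm, ex$pcb) +
    gauss_band(wavelength_grid, 620, ex$fwhm, ex$chl620)
  out <- normalise_excitation(spectrum_table(wavelength_grid, v))
  attr(out, "truth") <- list(weights = ex,
                             peb_pcb_eet = ex$peb / ex$pcb)
  out
}

#' Write and read ground truth as a structured config file
#'
#' YAML serialisation of a [ground_truth()] (nested key-value sections).
#'
#' @param truth a [ground_truth()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    model = truth$model[c("tau_ab", "tau_bc", "tau_da", "tau_db", "tau_c",
                          "irf_fwhm", "irf_t0", "free")],
    emission_bands = lapply(truth$emission_bands,
                            function(b) lapply(as.list(b), as.numeric)),
    noise_scale = truth$noise_scale,
    seed = truth$seed,
    pigment_bands = lapply(as.list(truth$pigment_bands), as.numeric),
    pigment_offset = truth$pigment_offset,
    rlc = truth$rlc,
    excitation = truth$excitation,
    treatment_grid = list(intensity = truth$treatment_grid$intensity,
                          spectrum = truth$treatment_grid$spectrum))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  m <- obj$model
  ground_truth(
    model = compartment_model(m$tau_ab, m$tau_bc, m$tau_da, m$tau_db,
                              m$tau_c, m$irf_fwhm, m$irf_t0,
                              free = unlist(m$free)),
    emission_bands = lapply(obj$emission_bands, as.data.frame),
    noise_scale = obj$noise_scale,
    seed = obj$seed,
    pigment_bands = as.data.frame(obj$pigment_bands),
    pigment_offset = obj$pigment_offset,
    rlc = obj$rlc,
    excitation = obj$excitation,
    treatment_grid = data.frame(intensity = unlist(obj$treatment_grid$intensity),
                                spectrum = unlist(obj$treatment_grid$spectrum)))
}
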