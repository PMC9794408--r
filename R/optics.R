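# Reflectance-based pigment absorbance: D(lambda) = log10(1/R), baseline
# correction against the non-pigment 750-800 nm region, and band readouts at
# the canonical chromophore wavelengths.

#' Convert surface reflectance to absorbance
#'
#' `D(lambda) = log10(1 / R(lambda))` (base-10 absorbance convention).
#' Reflectance must be positive; values above 1 (calibration overshoot
#' against the white standard) are permitted with a warning and yield
#' negative absorbance.
#'
#' @param spectrum a [spectrum_table()] of reflectance fractions.
#' @return A [spectrum_table()] of absorbance.
#' @export
reflectance_to_absorbance <- function(spectrum) {
  r <- spectrum$value
  if (any(r <= 0)) {
    bad <- spectrum$wavelength[which(r <= 0)[1]]
    stop("non-positive reflectance at ", bad, " nm", call. = FALSE)
  }
  if (any(r > 1))
    warning(sum(r > 1), " reflectance value(s) > 1 (calibration overshoot)",
            call. = FALSE)
  spectrum_table(spectrum$wavelength, -log10(r))
}

#' Baseline-correct an absorbance spectrum
#'
#' Subtracts the mean absorbance between 750 and 800 nm, where photosynthetic
#' pigments do not absorb, removing non-pigment (scattering/skeleton)
#' contributions as a pure offset. Idempotent.
#'
#' @param spectrum a [spectrum_table()] of absorbance covering 750-800 nm.
#' @return Corrected [spectrum_table()]; the subtracted offset is attached as
#'   attribute `baseline`.
#' @export
baseline_correct <- function(spectrum) {
  wl <- spectrum$wavelength
  if (wl[1] > 750 || wl[length(wl)] < 800)
    stop("spectrum must cover 750-800 nm for baseline correction",
         call. = FALSE)
  sel <- wl >= 750 & wl <= 800
  base <- mean(spectrum$value[sel])
  out <- spectrum_table(wl, spectrum$value - base)
  attr(out, "baseline") <- base
  out
}

#' Chromophore band readouts from a corrected absorbance spectrum
#'
#' Reads absorbances at the chromophore-specific maxima used as proxies for
#' relative abundance: phycourobilin 495 nm, phycoerythrin 565 nm,
#' phycocyanin 630 nm and chlorophyll-a 680 nm. In the 590-640 nm overlap
#' region chlorophyll-a contributes ~30% and phycocyanin ~70%, so a 0.7
#' factor is applied to the 630 nm value (`pc_corrected`).
#'
#' @param spectrum baseline-corrected absorbance [spectrum_table()] covering
#'   at least 480-700 nm.
#' @param window optional `+/- window` nm band-maximum readout instead of the
#'   default point value with linear interpolation.
#' @return A list of class `band_readout`: `pub_495`, `pe_565`, `pc_raw_630`,
#'   `pc_corrected`, `chl_680`, `baseline`.
#' @export
band_readout <- function(spectrum, window = 0) {
  wl <- spectrum$wavelength
  if (wl[1] > 480 || wl[length(wl)] < 700)
    stop("spectrum must cover 480-700 nm for band readout", call. = FALSE)
  method <- if (window > 0) "window_max" else "interp"
  v <- spectrum_value(spectrum, c(495, 565, 630, 680), window, method)
  base <- attr(spectrum, "baseline")
  structure(list(pub_495 = v[1], pe_565 = v[2], pc_raw_630 = v[3],
                 pc_corrected = 0.7 * v[3], chl_680 = v[4],
                 baseline = if (is.null(base)) NA_real_ else base),
            class = "band_readout")
}

#' @export
print.band_readout <- function(x, ...) {
  cat("Pigment band absorbances (baseline-corrected)\n")
  cat(sprintf("  PUB 495 nm: %.4f   PE 565 nm: %.4f\n", x$pub_495, x$pe_565))
  cat(sprintf("  PC 630 nm:  %.4f   (x0.7 overlap-corrected: %.4f)\n",
              x$pc_raw_630, x$pc_corrected))
  cat(sprintf("  Chl-a 680 nm: %.4f   baseline: %s\n", x$chl_680,
              format(x$baseline)))
  invisible(x)
}

#' Phycoerythrobilin to phycocyanobilin absorbance ratio
#'
#' The 565 nm phycoerythrin absorbance divided by the overlap-corrected
#' 630 nm phycocyanin absorbance (`0.7 x` raw).
#'
#' @param readout a [band_readout()].
#' @return The PEB:PCB absorbance ratio.
#' @export
peb_pcb_absorbance_ratio <- function(readout) {
  stopifnot(inherits(readout, "band_readout"))
  if (!is.finite(readout$pc_corrected) || readout$pc_corrected <= 0)
    stop("undefined ratio: corrected PC absorbance is not positive",
         call. = FALSE)
  readout$pe_565 / readout$pc_corrected
}

#' Mean absorbance over the photosynthetically active range
#'
#' Average of a (baseline-corrected) absorbance spectrum over 400-700 nm,
#' the quantity feeding the absorbed fraction `A = 1 - 10^-D` used in
#' electron transport rates.
#'
#' @param spectrum absorbance [spectrum_table()] covering `lower`-`upper` nm.
#' @param lower,upper averaging window (nm).
#' @return Mean absorbance (unitless).
#' @export
mean_absorbance <- function(spectrum, lower = 400, upper = 700) {
  wl <- spectrum$wavelength
  if (wl[1] > lower || wl[length(wl)] < upper)
    stop("spectrum must cover ", lower, "-", upper, " nm", call. = FALSE)
  sel <- wl >= lower & wl <= upper
  # trapezoid mean is robust to uneven grids
  w <- trapz_weights(wl[sel])
  sum(w * spectrum$value[sel]) / sum(w)
}
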