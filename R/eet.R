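# Chromophore-resolved excitation-energy-transfer readouts from
# fluorescence-excitation spectra of the PSI band (detected at 720 nm).

#' Normalise an excitation spectrum at 570 nm
#'
#' @param spectrum a [spectrum_table()] of PSI-band fluorescence versus
#'   excitation wavelength, covering 570 nm.
#' @return The spectrum divided by its (interpolated) 570 nm value, with
#'   attribute `anchor_value` recording the divisor.
#' @export
normalise_excitation <- function(spectrum) {
  anchor <- spectrum_value(spectrum, 570)
  if (!is.finite(anchor) || anchor <= 0)
    stop("cannot normalise: value at 570 nm is not positive", call. = FALSE)
  out <- spectrum_table(spectrum$wavelength, spectrum$value / anchor)
  attr(out, "anchor_value") <- anchor
  out
}

#' Chromophore energy-transfer readout from an excitation spectrum
#'
#' Reads the normalised PSI-fluorescence excitation intensities at the
#' chromophore wavelengths — phycourobilin 495 nm, phycoerythrobilin 565 nm,
#' phycocyanobilin 620 nm — and applies the 0.7 factor at 620 nm, where the
#' remaining 30% of the signal comes from direct chlorophyll-a excitation.
#' The PEB:PCB energy-transfer ratio is `I565 / (0.7 I620)`, and percentage
#' shares are computed over the corrected trio.
#'
#' @param spectrum an excitation [spectrum_table()] covering 495-620 nm; it
#'   is normalised at 570 nm first if it is not already.
#' @param window optional Gaussian readout FWHM (nm) emulating a finite
#'   excitation bandwidth (e.g. 15 nm); default point readout.
#' @return A list of class `eet_readout`: `i495`, `i565`, `i620_raw`,
#'   `i620_pcb` (= 0.7 raw), `peb_pcb_eet`, and `shares` (percentages over
#'   PUB/PEB/PCB summing to 100).
#' @export
eet_readout <- function(spectrum, window = 0) {
  v570 <- spectrum_value(spectrum, 570)
  if (abs(v570 - 1) > 1e-9) spectrum <- normalise_excitation(spectrum)
  method <- if (window > 0) "gaussian" else "interp"
  v <- spectrum_value(spectrum, c(495, 565, 620), window, method)
  if (v[3] <= 0)
    stop("undefined ratio: 620 nm intensity is not positive", call. = FALSE)
  pcb <- 0.7 * v[3]
  shares <- 100 * c(pub = v[1], peb = v[2], pcb = pcb) / (v[1] + v[2] + pcb)
  structure(list(i495 = v[1], i565 = v[2], i620_raw = v[3], i620_pcb = pcb,
                 peb_pcb_eet = v[2] / pcb, shares = shares),
            class = "eet_readout")
}

#' @export
print.eet_readout <- function(x, ...) {
  cat("Excitation-spectrum energy-transfer readout (normalised at 570 nm)\n")
  cat(sprintf("  I495 (PUB) %.4f  I565 (PEB) %.4f  I620 raw %.4f (PCB %.4f)\n",
              x$i495, x$i565, x$i620_raw, x$i620_pcb))
  cat(sprintf("  PEB:PCB EET %.4f; shares PUB %.1f%% PEB %.1f%% PCB %.1f%%\n",
              x$peb_pcb_eet, x$shares[["pub"]], x$shares[["peb"]],
              x$shares[["pcb"]]))
  invisible(x)
}

#' Estimated phycourobilin contribution to light harvesting at 495 nm
#'
#' Combines the PUB:PEB ratios of concentration, absorbance and energy
#' transfer into a single fractional contribution. The default estimator
#' converts the energy-transfer ratio into odds, `r / (1 + r)`; the
#' combination rule is configurable and is always reported with its inputs,
#' as no unique rule follows from first principles.
#'
#' @param conc_ratio_pub_peb PUB:PEB concentration ratio, `> 0`.
#' @param abs_ratio PUB:PEB absorbance ratio, `> 0`.
#' @param eet_ratio PUB:PEB energy-transfer ratio, `> 0` (may be `Inf`).
#' @param estimator combination rule; `"eet_odds"` (default) returns
#'   `eet_ratio / (1 + eet_ratio)`.
#' @return List with `fraction`, `estimator`, `inputs`.
#' @export
pub_contribution_495 <- function(conc_ratio_pub_peb, abs_ratio, eet_ratio,
                                 estimator = c("eet_odds")) {
  estimator <- match.arg(estimator)
  if (any(c(conc_ratio_pub_peb, abs_ratio) <= 0) || eet_ratio <= 0 ||
      any(!is.finite(c(conc_ratio_pub_peb, abs_ratio))) || is.na(eet_ratio))
    stop("all ratios must be positive", call. = FALSE)
  frac <- if (is.infinite(eet_ratio)) 1 else eet_ratio / (1 + eet_ratio)
  list(fraction = frac, estimator = estimator,
       inputs = list(conc_ratio_pub_peb = conc_ratio_pub_peb,
                     abs_ratio = abs_ratio, eet_ratio = eet_ratio))
}
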