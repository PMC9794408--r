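#' Wavelength-indexed spectrum table
#'
#' Generic container for reflectance, absorbance and excitation spectra: a
#' data frame with strictly increasing `wavelength` (nm) and numeric `value`.
#'
#' @param wavelength strictly increasing wavelengths (nm).
#' @param value spectrum values (reflectance fraction, absorbance, ...).
#' @return A data frame of class `spectrum_table`.
#' @export
spectrum_table <- function(wavelength, value) {
  check_grid(wavelength, "wavelength")
  if (length(value) != length(wavelength) || any(!is.finite(value)))
    stop("value must be finite and match wavelength in length", call. = FALSE)
  structure(data.frame(wavelength = as.numeric(wavelength),
                       value = as.numeric(value)),
            class = c("spectrum_table", "data.frame"))
}

#' Read a spectrum value at given wavelengths
#'
#' Off-grid wavelengths are linearly interpolated between neighbouring grid
#' points. `window > 0` instead reads either the maximum over a `+/- window`
#' nm interval (`method = "window_max"`) or a Gaussian-weighted average with
#' FWHM `window` (`method = "gaussian"`), conventions offered for band maxima
#' and finite excitation bandwidths respectively.
#'
#' @param spectrum a [spectrum_table()].
#' @param at wavelengths (nm) to read; must lie within the grid coverage.
#' @param window half-width (nm, `window_max`) or FWHM (nm, `gaussian`).
#' @param method readout convention; default point interpolation.
#' @return Numeric vector of values at `at`.
#' @export
spectrum_value <- function(spectrum, at,
                           window = 0,
                           method = c("interp", "window_max", "gaussian")) {
  method <- match.arg(method)
  wl <- spectrum$wavelength
  v <- spectrum$value
  if (any(at < wl[1] | at > wl[length(wl)]))
    stop("requested wavelength outside spectrum coverage [",
         wl[1], ", ", wl[length(wl)], "] nm", call. = FALSE)
  if (window <= 0 || method == "interp")
    return(stats::approx(wl, v, xout = at)$y)
  vapply(at, function(a) {
    if (method == "window_max") {
      sel <- wl >= a - window & wl <= a + window
      max(v[sel])
    } else {
      s <- fwhm_to_sigma(window)
      w <- stats::dnorm(wl, a, s)
      sum(w * v) / sum(w)
    }
  }, numeric(1))
}

#' Read and write two-column spectrum files
#'
#' Delimited text with header `wavelength_nm,value`.
#'
#' @param spectrum a [spectrum_table()].
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(wavelength_nm = spectrum$wavelength,
                   value = spectrum$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum file must have columns wavelength_nm,value: ", path,
         call. = FALSE)
  spectrum_table(df$wavelength_nm, df$value)
}
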