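#' Time-resolved fluorescence surface
#'
#' Container for a fluorescence intensity matrix on a time (ps) by
#' wavelength (nm) grid — the object of global analysis.
#'
#' @param time_ps strictly increasing time grid (ps).
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param intensity numeric matrix, `length(time_ps)` rows and
#'   `length(wavelength_nm)` columns; no missing values.
#' @return An object of class `tw_surface` with elements `time_ps`,
#'   `wavelength_nm`, `intensity`.
#' @export
tw_surface <- function(time_ps, wavelength_nm, intensity) {
  check_grid(time_ps, "time_ps")
  check_grid(wavelength_nm, "wavelength_nm")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(time_ps) ||
      ncol(intensity) != length(wavelength_nm))
    stop("intensity must be a length(time) x length(wavelength) matrix",
         call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensity contains missing or non-finite values", call. = FALSE)
  dimnames(intensity) <- NULL
  structure(list(time_ps = as.numeric(time_ps),
                 wavelength_nm = as.numeric(wavelength_nm),
                 intensity = intensity),
            class = "tw_surface")
}

#' @export
print.tw_surface <- function(x, ...) {
  cat(sprintf(
    "Time-resolved fluorescence surface: %d times (%.1f..%.1f ps) x %d wavelengths (%.0f..%.0f nm)\n",
    length(x$time_ps), min(x$time_ps), max(x$time_ps),
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Read and write surface matrices as delimited text
#'
#' The on-disk format is a CSV matrix whose first row holds the wavelength
#' grid (nm) under a leading `time_ps` column label, and whose first column
#' holds the time grid (ps).
#'
#' @param surface a [tw_surface()].
#' @param path file path.
#' @return `write_surface` invisibly returns `path`; `read_surface` returns a
#'   [tw_surface()].
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "tw_surface"))
  df <- data.frame(time_ps = surface$time_ps, surface$intensity,
                   check.names = FALSE)
  names(df) <- c("time_ps", format(surface$wavelength_nm, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_ps")
    stop("not a surface file (first column must be time_ps): ", path,
         call. = FALSE)
  wl <- as.numeric(names(df)[-1])
  if (any(is.na(wl)))
    stop("non-numeric wavelength header in ", path, call. = FALSE)
  tw_surface(df[[1]], wl, as.matrix(df[-1]))
}

# trapezoid weights for integrating columns of a surface over wavelength
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}
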