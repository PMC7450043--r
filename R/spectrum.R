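#' One emission scan
#'
#' A CFP emission spectrum: excitation 430 nm, emission recorded from 450
#' to 600 nm inclusive at 1 nm intervals (151 points), at a stated
#' acquisition temperature. Intensities are arbitrary fluorescence units
#' and may be negative after corrections applied elsewhere.
#'
#' @param wavelength Integer wavelength grid, nm.
#' @param intensity Numeric intensities, same length.
#' @param temperature Acquisition temperature, degC.
#' @return A list of class `spectrum_record` with elements `wavelength`,
#'   `intensity`, `temperature`.
#' @export
spectrum_record <- function(wavelength, intensity, temperature = 25) {
  wavelength <- as.integer(round(wavelength))
  intensity <- as.numeric(intensity)
  validate_spectrum_grid(wavelength, length(intensity))
  structure(
    list(wavelength = wavelength, intensity = intensity,
         temperature = as.numeric(temperature)),
    class = "spectrum_record"
  )
}

# Enforces the full 450-600 nm grid at 1 nm steps (151 points, strictly
# increasing) and intensity/wavelength length agreement.
validate_spectrum_grid <- function(wavelength, n_intensity) {
  expected <- 450:600
  if (length(wavelength) != n_intensity) {
    rlang::abort("Spectrum wavelength and intensity lengths differ.",
                 class = "nascentfret_grid_error")
  }
  if (length(wavelength) != length(expected) ||
      !identical(as.integer(wavelength), as.integer(expected))) {
    rlang::abort(
      sprintf(paste0("Invalid emission grid: expected the complete ",
                     "450-600 nm scan at 1 nm intervals (151 points), ",
                     "got %d points."), length(wavelength)),
      class = "nascentfret_grid_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %d-%d nm, %d points, %g degC, peak %.4g\n",
              min(x$wavelength), max(x$wavelength), length(x$wavelength),
              x$temperature, max(x$intensity)))
  invisible(x)
}
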