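#' Generative parameters of the synthetic assay
#'
#' Everything the reaction simulator needs besides the per-condition target
#' FRET: stall ratios, readthrough-chain concentration, donor photophysics,
#' background levels, the scintillation-counting constants of the
#' concentration equation, and noise settings.
#'
#' Defaults describe the accepted-sample regime of the assay: small,
#' matched stalls (`s = 0.1`), 2% multiplicative spectral noise, Poisson
#' counting statistics over a 30-minute scintillation window, and a 1%/degC
#' linear loss of donor brightness away from the 25 degC reference (which
#' cancels in the FRET ratio).
#'
#' @param s_d,s_da Stalled-to-readthrough chain ratio in the D and DA
#'   reactions (unitless, >= 0).
#' @param rnc_conc True readthrough-chain (RNC) concentration, nM.
#' @param donor_brightness Donor fluorescence per nM of unquenched chains at
#'   the reference temperature (arbitrary units).
#' @param brightness_temp_coeff Fractional donor brightness loss per degC
#'   above 25 degC.
#' @param bg_level Baseline fluorescence intensity added to every spectrum.
#' @param cpm_background Background scintillation rate, counts/min.
#' @param sa Specific activity of \[14C\]Lys, dpm/pmol.
#' @param ce Counting efficiency for 14C, in (0, 1].
#' @param vol Counted sample volume, ml.
#' @param count_minutes Scintillation counting time, min; realized counts
#'   are Poisson over this window and reported back as counts/min.
#' @param noise_cv Fractional Gaussian noise on spectral intensities
#'   (sd = `noise_cv` times the noise-free intensity). 0 disables.
#' @param count_noise Logical; draw counts from the Poisson model (`TRUE`)
#'   or return their expectation (`FALSE`).
#' @return A list of class `generative_params`.
#' @export
#' @examples
#' generative_params()                 # study defaults
#' noise_free(generative_params())     # deterministic variant
generative_params <- function(s_d = 0.1, s_da = 0.1, rnc_conc = 400,
                              donor_brightness = 100,
                              brightness_temp_coeff = 0.01,
                              bg_level = 2000, cpm_background = 100,
                              sa = 10, ce = 0.95, vol = 0.5,
                              count_minutes = 30,
                              noise_cv = 0.02, count_noise = TRUE) {
  p <- list(
    s_d = s_d, s_da = s_da, rnc_conc = rnc_conc,
    donor_brightness = donor_brightness,
    brightness_temp_coeff = brightness_temp_coeff,
    bg_level = bg_level, cpm_background = cpm_background,
    sa = sa, ce = ce, vol = vol, count_minutes = count_minutes,
    noise_cv = noise_cv, count_noise = isTRUE(count_noise)
  )
  num <- vapply(p[setdiff(names(p), "count_noise")], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) {
    rlang::abort("All generative parameters must be finite scalars.",
                 class = "nascentfret_bad_param")
  }
  if (p$s_d < 0 || p$s_da < 0) {
    rlang::abort("Stall ratios must be non-negative.",
                 class = "nascentfret_bad_param")
  }
  if (p$ce <= 0 || p$ce > 1) {
    rlang::abort("Counting efficiency ce must be in (0, 1].",
                 class = "nascentfret_bad_param")
  }
  if (p$sa <= 0 || p$vol <= 0 || p$rnc_conc <= 0 ||
      p$donor_brightness <= 0 || p$count_minutes <= 0) {
    rlang::abort("sa, vol, rnc_conc, donor_brightness and count_minutes must be positive.",
                 class = "nascentfret_bad_param")
  }
  if (p$noise_cv < 0 || p$bg_level < 0 || p$cpm_background < 0) {
    rlang::abort("noise_cv, bg_level and cpm_background must be non-negative.",
                 class = "nascentfret_bad_param")
  }
  structure(p, class = "generative_params")
}

#' Turn off all stochastic components of a parameter set
#'
#' @param params A [generative_params()] object.
#' @return The same parameters with spectral noise disabled and counts
#'   returned at their expectation.
#' @export
noise_free <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  params$noise_cv <- 0
  params$count_noise <- FALSE
  params
}
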