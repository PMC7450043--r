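# Measurement math: peak extraction, blank correction, concentration from
# scintillation counts, net fluorescence per nM, FRET efficiency by donor
# quenching, and readthrough QC.

#' Average of the five highest emission intensities
#'
#' The donor signal of a scan is summarised as the arithmetic mean of its
#' five largest intensities (which for CFP sit near 475 nm). Selection runs
#' over the full grid; ties are broken toward the lower wavelength.
#'
#' @param spectrum A [spectrum_record()].
#' @param n_peaks Number of points averaged (the assay convention is 5).
#' @return List of class `peak_intensity`: `value` (the mean) and
#'   `wavelengths_used` (the contributing wavelengths).
#' @export
extract_peak_intensity <- function(spectrum, n_peaks = 5L) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  if (length(spectrum$intensity) < n_peaks) {
    rlang::abort(sprintf("Need at least %d points to form a peak average.",
                         n_peaks),
                 class = "nascentfret_grid_error")
  }
  ord <- order(-spectrum$intensity, spectrum$wavelength)[seq_len(n_peaks)]
  structure(
    list(value = mean(spectrum$intensity[ord]),
         wavelengths_used = sort(spectrum$wavelength[ord])),
    class = "peak_intensity"
  )
}

#' Nascent-chain concentration from scintillation counts
#'
#' \deqn{[RNC] = (cpm_S - cpm_B) / (CE \cdot SA \cdot vol)}
#'
#' where `cpm_s` is the sample count rate (D or DA), `cpm_b` the matching
#' blank (BD or BDA), `ce` the counting efficiency, `sa` the specific
#' activity of the 14C label in dpm/pmol and `vol` the counted volume in
#' ml; the result is in nM. A non-positive concentration is flagged, never
#' silently clipped.
#'
#' @param cpm_s Sample counts/min.
#' @param cpm_b Blank counts/min.
#' @param ce Counting efficiency in (0, 1].
#' @param sa Specific activity, dpm/pmol.
#' @param vol Sample volume, ml.
#' @return List of class `rnc_concentration`: `value` (nM), the inputs,
#'   and `flagged` (`TRUE` when `value <= 0`).
#' @export
#' @examples
#' rnc_concentration(2000, 100, ce = 0.95, sa = 10, vol = 0.5)$value  # 400
rnc_concentration <- function(cpm_s, cpm_b, ce, sa, vol) {
  if (!is.finite(ce) || ce <= 0 || ce > 1) {
    rlang::abort("Counting efficiency ce must be in (0, 1].",
                 class = "nascentfret_bad_param")
  }
  if (!is.finite(sa) || sa <= 0 || !is.finite(vol) || vol <= 0) {
    rlang::abort("sa and vol must be positive.",
                 class = "nascentfret_bad_param")
  }
  value <- (cpm_s - cpm_b) / (ce * sa * vol)
  structure(
    list(value = value, cpm_s = cpm_s, cpm_b = cpm_b,
         ce = ce, sa = sa, vol = vol, flagged = value <= 0),
    class = "rnc_concentration"
  )
}

#' Net blank-corrected fluorescence per nM nascent chain
#'
#' `(sample peak - blank peak) / concentration`; the D sample is corrected
#' with the BD blank and the DA sample with the BDA blank. This is the
#' `F_D` / `F_DA` quantity entering the FRET ratio.
#'
#' @param sample_peak,blank_peak [extract_peak_intensity()] results (or
#'   bare numbers).
#' @param conc An [rnc_concentration()] (or a bare positive number, nM).
#' @return Fluorescence units per nM.
#' @export
net_intensity_per_nm <- function(sample_peak, blank_peak, conc) {
  pv <- function(x) if (inherits(x, "peak_intensity")) x$value else x
  cv <- if (inherits(conc, "rnc_concentration")) conc$value else conc
  if (!is.finite(cv) || cv <= 0) {
    rlang::abort(
      "Unusable experiment: non-positive nascent-chain concentration (sample counts did not exceed blank counts).",
      class = "nascentfret_unusable_experiment"
    )
  }
  (pv(sample_peak) - pv(blank_peak)) / cv
}

#' FRET efficiency by donor quenching
#'
#' \deqn{E_{FRET} = 1 - F_{DA} / F_D}
#'
#' `f_da` and `f_d` are the net 14C-corrected fluorescence per nM nascent
#' chain in the donor+acceptor and donor-only samples. The result is not
#' clipped: noise can produce small negative efficiencies, which are
#' reported as-is so replicate averages stay unbiased.
#'
#' @param f_da,f_d Net intensities per nM; `f_d` must be positive.
#' @return FRET efficiency (unitless fraction).
#' @export
#' @examples
#' fret_efficiency(0.604, 1)  # 0.396
fret_efficiency <- function(f_da, f_d) {
  if (any(!is.finite(f_d)) || any(f_d <= 0)) {
    rlang::abort("Donor-only net intensity F_D must be positive.",
                 class = "nascentfret_unusable_experiment"
    )
  }
  1 - f_da / f_d
}

# Per-probe acceptance bands for the D/DA readthrough ratio. The band for
# the 567 construct is tighter; probe 389 (the CFP-tether control) reuses
# the 487 band, which the assay does not specify separately.
.qc_bands <- list(`487` = c(0.80, 1.20),
                  `567` = c(0.85, 1.15),
                  `389` = c(0.80, 1.20))

#' Readthrough-ratio quality control
#'
#' Samples are usable only when amber-codon readthrough was similar in the
#' D and DA reactions; otherwise stalled zero-FRET chains bias the
#' apparent efficiency. Accept iff the D/DA ratio falls within 0.80-1.20
#' for probe 487 (and the probe-389 control) or 0.85-1.15 for probe 567,
#' bounds inclusive.
#'
#' @param readthrough_ratio Positive D/DA readthrough ratio.
#' @param probe_site Acceptor residue (389, 487 or 567).
#' @return Logical pass/fail.
#' @export
qc_readthrough <- function(readthrough_ratio, probe_site) {
  band <- .qc_bands[[as.character(probe_site)]]
  if (is.null(band)) {
    rlang::abort(paste0("No QC band defined for probe site ", probe_site),
                 class = "nascentfret_bad_condition")
  }
  if (any(!is.finite(readthrough_ratio)) || any(readthrough_ratio <= 0)) {
    rlang::abort("Readthrough ratio must be positive.",
                 class = "nascentfret_bad_param")
  }
  readthrough_ratio >= band[1] & readthrough_ratio <= band[2]
}

#' Compute the FRET efficiency of one matched-quadruple experiment
#'
#' Runs the full per-experiment measurement: peak-extracts all four
#' spectra, blank-corrects (D against BD, DA against BDA), converts counts
#' to concentrations, forms the net per-nM intensities and the donor
#' quenching ratio, and attaches the readthrough QC verdict. QC failure
#' does not suppress the estimate; the row carries `qc_pass = FALSE` and
#' downstream aggregation decides.
#'
#' @param set A `reaction_set` (simulated or read from a bundle).
#' @return One-row tibble: experiment id, condition fields, `e_fret`,
#'   intermediates (`peak_d`, `peak_da`, `conc_d`, `conc_da`, `f_d`,
#'   `f_da`), `readthrough_ratio`, `qc_pass`, `conc_flagged`.
#' @export
compute_experiment_fret <- function(set) {
  stopifnot(inherits(set, "reaction_set"))
  s <- set$samples
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Stage '", name, "' failed for experiment ",
                          set$experiment_id, ": ", conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }
  peaks <- stage("peak extraction",
                 lapply(s, function(x) extract_peak_intensity(x$spectrum)))
  conc_d <- stage("concentration",
                  rnc_concentration(s$D$cpm, s$BD$cpm, s$D$ce, s$D$sa,
                                    s$D$vol))
  conc_da <- stage("concentration",
                   rnc_concentration(s$DA$cpm, s$BDA$cpm, s$DA$ce, s$DA$sa,
                                     s$DA$vol))
  f_d <- stage("net intensity",
               net_intensity_per_nm(peaks$D, peaks$BD, conc_d))
  f_da <- stage("net intensity",
                net_intensity_per_nm(peaks$DA, peaks$BDA, conc_da))
  e <- stage("FRET ratio", fret_efficiency(f_da, f_d))
  flagged <- conc_d$flagged || conc_da$flagged
  key <- set$condition
  dplyr::bind_cols(
    tibble::tibble(experiment_id = set$experiment_id),
    condition_fields(key),
    tibble::tibble(
      e_fret = e, f_d = f_d, f_da = f_da,
      peak_d = peaks$D$value, peak_da = peaks$DA$value,
      conc_d = conc_d$value, conc_da = conc_da$value,
      readthrough_ratio = set$readthrough_ratio,
      qc_pass = qc_readthrough(set$readthrough_ratio, key$probe_site),
      conc_flagged = flagged
    )
  )
}
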