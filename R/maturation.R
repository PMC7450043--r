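# CFTR maturation from immunoblot band intensities: band B is the
# core-glycosylated ER form, band C the maturely glycosylated post-Golgi
# form; the band-C level indexes trafficking.

#' Maturation efficiency of a blot lane
#'
#' Percent of CFTR in the mature form: `100 * C / (B + C)`.
#'
#' @param band_b,band_c Non-negative band intensities (vectorised).
#' @return Percent mature, in `[0, 100]`.
#' @export
#' @examples
#' maturation_efficiency(band_b = 300, band_c = 100)  # 25
maturation_efficiency <- function(band_b, band_c) {
  if (any(band_b < 0) || any(band_c < 0)) {
    rlang::abort("Band intensities must be non-negative.",
                 class = "nascentfret_bad_param")
  }
  tot <- band_b + band_c
  if (any(tot == 0)) {
    rlang::abort("Cannot compute maturation of a lane with B + C = 0.",
                 class = "nascentfret_bad_param")
  }
  100 * band_c / tot
}

#' Mutant band-C level relative to wild type
#'
#' Loading-normalised mature-CFTR quantification: each mutant lane's band
#' C over its loading control, expressed as a percentage of the mean
#' wild-type loading-normalised band C, then averaged over mutant
#' replicate lanes (mean, SEM). Normalising to the loading control (not
#' to percent-mature) matches the "band C protein relative to wild-type
#' levels" convention; the normalisation makes the result invariant to
#' global intensity rescaling.
#'
#' @param lanes Tibble of blot lanes with columns `construct`,
#'   `band_b`, `band_c`, `loading_control` (as from
#'   [simulate_blot_table()]).
#' @param construct Mutant construct label to quantify.
#' @param reference Reference construct label (default `"WT"`).
#' @return List of class `maturation_result`: `construct`,
#'   `relative_to_reference` (percent, mean), `sem`, `n`,
#'   `per_replicate` (percent), `percent_c` (mean maturation efficiency
#'   of the mutant lanes).
#' @export
relative_trafficking <- function(lanes, construct, reference = "WT") {
  mut <- lanes[lanes$construct == construct, , drop = FALSE]
  ref <- lanes[lanes$construct == reference, , drop = FALSE]
  if (nrow(mut) == 0L || nrow(ref) == 0L) {
    rlang::abort("Need at least one lane each for mutant and reference.",
                 class = "nascentfret_bad_param")
  }
  if (any(mut$loading_control <= 0) || any(ref$loading_control <= 0)) {
    rlang::abort("Loading controls must be positive.",
                 class = "nascentfret_bad_param")
  }
  ref_norm <- ref$band_c / ref$loading_control
  if (mean(ref_norm) <= 0) {
    rlang::abort("Reference band C is zero in all replicates.",
                 class = "nascentfret_bad_param")
  }
  rel <- 100 * (mut$band_c / mut$loading_control) / mean(ref_norm)
  n <- length(rel)
  structure(
    list(construct = construct, reference = reference,
         relative_to_reference = mean(rel),
         sem = if (n > 1) stats::sd(rel) / sqrt(n) else 0,
         n = n, per_replicate = rel,
         percent_c = mean(maturation_efficiency(mut$band_b, mut$band_c))),
    class = "maturation_result"
  )
}

#' @export
print.maturation_result <- function(x, ...) {
  cat(sprintf(
    "<maturation_result> %s band C = %.2f%% +/- %.2f%% of %s (n = %d)\n",
    x$construct, x$relative_to_reference, x$sem, x$reference, x$n))
  invisible(x)
}
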