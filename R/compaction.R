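# Replicate aggregation and the study's comparisons: condition profiles,
# Student's t contrasts, length scans, folding-window detection,
# bound/released pairing, thermal curves and difference curves.

#' Aggregate replicate FRET results into a condition profile
#'
#' Mean, sample SD (n-1 denominator) and SEM = sd/sqrt(n) over the
#' qc-passing replicates of one condition. QC-failed replicates are
#' excluded (and counted) unless `include_qc_failed`. A single usable
#' replicate yields SEM 0 with an explicit low-n flag; such profiles are
#' refused by the statistical comparisons.
#'
#' @param results Tibble of per-experiment rows from
#'   [compute_experiment_fret()], all sharing one condition.
#' @param include_qc_failed Keep QC-failed replicates in the statistics.
#' @return List of class `condition_profile`: `condition`, `replicate_e`,
#'   `mean`, `sem`, `n`, `n_excluded`, `low_n`.
#' @export
aggregate_profile <- function(results, include_qc_failed = FALSE) {
  cond <- unique(results[, c("construct", "probe_site", "truncation",
                             "ribosome_state", "temperature")])
  if (nrow(cond) != 1L) {
    rlang::abort("All replicates of a profile must share one condition.",
                 class = "nascentfret_bad_condition")
  }
  keep <- if (include_qc_failed) rep(TRUE, nrow(results)) else results$qc_pass
  e <- results$e_fret[keep]
  n <- length(e)
  if (n == 0L) {
    rlang::abort("No usable (QC-passing) replicates for this condition.",
                 class = "nascentfret_unusable_experiment")
  }
  key <- condition_key(cond$construct, cond$probe_site, cond$truncation,
                       cond$ribosome_state, cond$temperature)
  structure(
    list(condition = key, replicate_e = e, mean = mean(e),
         sem = if (n > 1) stats::sd(e) / sqrt(n) else 0,
         n = n, n_excluded = nrow(results) - n, low_n = n == 1L),
    class = "condition_profile"
  )
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("<condition_profile> %s: E = %.4f +/- %.4f (SEM), n = %d%s\n",
              format(x$condition), x$mean, x$sem, x$n,
              if (x$n_excluded) sprintf(" (%d QC-excluded)", x$n_excluded)
              else ""))
  invisible(x)
}

# Two-sample Student's t from the textbook formulas (pooled variance by
# default, Welch optional, paired optional). Implemented directly rather
# than through stats::t.test so degenerate zero-variance groups behave:
# identical groups give t = 0, two-tailed p = 1. One-tailed direction is
# fixed as mean(a) > mean(b).
.student_t <- function(a, b, tail, var_equal = TRUE, paired = FALSE) {
  na <- length(a); nb <- length(b)
  if (paired) {
    if (na != nb) {
      rlang::abort("Paired comparison needs equal replicate counts.",
                   class = "nascentfret_bad_param")
    }
    d <- a - b
    se <- stats::sd(d) / sqrt(na)
    df <- na - 1
    tstat <- if (se == 0) ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf)
             else mean(d) / se
  } else if (var_equal) {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    tstat <- if (se == 0) ifelse(mean(a) == mean(b), 0,
                                 sign(mean(a) - mean(b)) * Inf)
             else (mean(a) - mean(b)) / se
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    tstat <- if (se == 0) ifelse(mean(a) == mean(b), 0,
                                 sign(mean(a) - mean(b)) * Inf)
             else (mean(a) - mean(b)) / se
  }
  p <- if (tail == "two") 2 * stats::pt(-abs(tstat), df)
       else stats::pt(tstat, df, lower.tail = FALSE)
  list(t = tstat, df = df, p = min(p, 1))
}

#' Compare two condition profiles with Student's t test
#'
#' Two-sample t test on the replicate FRET values, pooled-variance by
#' default (the study's convention); Welch and paired variants are
#' available. The one-tailed alternative is fixed in the direction
#' mean(a) > mean(b) — pass the wild-type profile as `a`.
#'
#' @param a,b [aggregate_profile()] objects with at least two replicates
#'   each.
#' @param tail `"two"` (default) or `"one"`.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @param paired Paired test on per-replicate differences.
#' @return List of class `comparison_result`: `difference` (mean a minus
#'   mean b), `t_statistic`, `degrees_of_freedom`, `p_value`, `tail`,
#'   `n_a`, `n_b`.
#' @export
compare_conditions <- function(a, b, tail = c("two", "one"),
                               var_equal = TRUE, paired = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(a, "condition_profile"),
            inherits(b, "condition_profile"))
  if (a$n < 2 || b$n < 2) {
    rlang::abort("Both groups need at least two usable replicates.",
                 class = "nascentfret_insufficient_replicates")
  }
  st <- .student_t(a$replicate_e, b$replicate_e, tail, var_equal, paired)
  structure(
    list(difference = a$mean - b$mean, t_statistic = st$t,
         degrees_of_freedom = st$df, p_value = st$p, tail = tail,
         n_a = a$n, n_b = b$n,
         condition_a = a$condition, condition_b = b$condition),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> diff = %.4f, t(%.4g) = %.4f, %s-tailed p = %.4g\n",
    x$difference, x$degrees_of_freedom, x$t_statistic, x$tail, x$p_value))
  invisible(x)
}

# Extract the truncation of each profile in a list.
.profile_truncations <- function(profiles) {
  vapply(profiles, function(p) p$condition$truncation, integer(1))
}

#' Per-truncation wild-type versus mutant comparison
#'
#' Pairs two profile series on a shared truncation grid and reports, per
#' truncation, the difference of means (reference minus mutant) with the
#' Student's t test.
#'
#' @param reference,mutant Lists of [aggregate_profile()] objects over the
#'   same truncations (e.g. wild type and one mutant).
#' @param tail Passed to [compare_conditions()].
#' @return Tibble ordered by truncation: `truncation`, `mean_ref`,
#'   `sem_ref`, `n_ref`, `mean_mut`, `sem_mut`, `n_mut`, `difference`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
length_scan <- function(reference, mutant, tail = "two") {
  tr_ref <- .profile_truncations(reference)
  tr_mut <- .profile_truncations(mutant)
  if (!setequal(tr_ref, tr_mut) || anyDuplicated(tr_ref) ||
      anyDuplicated(tr_mut)) {
    rlang::abort(
      paste0("Mismatched truncation grids: reference {",
             paste(sort(tr_ref), collapse = ", "), "} vs mutant {",
             paste(sort(tr_mut), collapse = ", "), "}."),
      class = "nascentfret_grid_mismatch"
    )
  }
  ord <- sort(tr_ref)
  rows <- lapply(ord, function(tr) {
    a <- reference[[which(tr_ref == tr)]]
    b <- mutant[[which(tr_mut == tr)]]
    cmp <- compare_conditions(a, b, tail = tail)
    tibble::tibble(
      truncation = tr,
      mean_ref = a$mean, sem_ref = a$sem, n_ref = a$n,
      mean_mut = b$mean, sem_mut = b$sem, n_mut = b$n,
      difference = cmp$difference, t_statistic = cmp$t_statistic,
      degrees_of_freedom = cmp$degrees_of_freedom, p_value = cmp$p_value
    )
  })
  dplyr::bind_rows(rows)
}

#' Detect the folding window of a length scan
#'
#' The maximal contiguous run of truncations at which the mutant mean is
#' significantly below the reference (p < alpha and positive
#' reference-minus-mutant difference). An empty window (no significant
#' truncation) is returned with `NA` bounds.
#'
#' @param scan A [length_scan()] table, ordered by truncation.
#' @param alpha Significance level (the study convention is 0.05, with no
#'   multiple-testing correction).
#' @return List of class `folding_window`: `start_truncation`,
#'   `end_truncation`, `n_truncations`, `alpha`, `scan` (the significant
#'   rows of the window).
#' @export
detect_folding_window <- function(scan, alpha = 0.05) {
  sig <- scan$p_value < alpha & scan$difference > 0
  runs <- rle(sig)
  out <- list(start_truncation = NA_integer_, end_truncation = NA_integer_,
              n_truncations = 0L, alpha = alpha,
              scan = scan[0, , drop = FALSE])
  if (any(sig)) {
    true_runs <- which(runs$values)
    best <- true_runs[which.max(runs$lengths[true_runs])]
    end_idx <- cumsum(runs$lengths)
    idx <- (end_idx[best] - runs$lengths[best] + 1):end_idx[best]
    out$start_truncation <- scan$truncation[idx[1]]
    out$end_truncation <- scan$truncation[idx[length(idx)]]
    out$n_truncations <- length(idx)
    out$scan <- scan[idx, , drop = FALSE]
  }
  structure(out, class = "folding_window")
}

#' @export
print.folding_window <- function(x, ...) {
  if (x$n_truncations == 0L) cat("<folding_window> empty\n")
  else cat(sprintf("<folding_window> truncations %d-%d (%d points, alpha %g)\n",
                   x$start_truncation, x$end_truncation, x$n_truncations,
                   x$alpha))
  invisible(x)
}

#' Cytosolically exposed chain length
#'
#' A ribosome-bound chain keeps its C-terminal `tunnel_offset` residues
#' (~30-40) inside the exit tunnel; a released chain is exposed to its
#' truncation point.
#'
#' @param truncation Truncation residue.
#' @param ribosome_state `"bound"` or `"released"`.
#' @param tunnel_offset Residues sequestered in the exit tunnel.
#' @return Last cytosolically exposed residue.
#' @export
exposed_length <- function(truncation, ribosome_state, tunnel_offset = 35) {
  if (ribosome_state == "bound") truncation - tunnel_offset else truncation
}

#' Bound-versus-released contrast with an exposure-equivalence check
#'
#' Compares a ribosome-bound profile against a released one whose shorter
#' truncation exposes the same residues (released truncation = bound
#' truncation - tunnel offset). The pairing is accepted when the implied
#' offset lies within the stated exit-tunnel band; otherwise the contrast
#' is refused with both exposed ranges named, because FRET differences
#' could then reflect chain length rather than ribosome attachment.
#'
#' @param bound,released [aggregate_profile()] objects in the matching
#'   ribosome states.
#' @param offset_band Acceptable exit-tunnel offsets (residues).
#' @param tail Passed to [compare_conditions()].
#' @return A `comparison_result` with an `equivalence` element recording
#'   the implied offset and the shared exposed range.
#' @export
release_comparison <- function(bound, released, offset_band = c(30, 40),
                               tail = "two") {
  stopifnot(inherits(bound, "condition_profile"),
            inherits(released, "condition_profile"))
  if (bound$condition$ribosome_state != "bound" ||
      released$condition$ribosome_state != "released") {
    rlang::abort("Arguments must be a bound profile and a released profile.",
                 class = "nascentfret_bad_condition")
  }
  tb <- bound$condition$truncation
  tr <- released$condition$truncation
  offset <- tb - tr
  if (offset < offset_band[1] || offset > offset_band[2]) {
    rlang::abort(
      sprintf(paste0("Non-equivalent pairing: bound truncation %d exposes ",
                     "residues up to ~%d-%d (offset band %d-%d), released ",
                     "truncation %d exposes residues up to %d."),
              tb, tb - offset_band[2], tb - offset_band[1],
              offset_band[1], offset_band[2], tr, tr),
      class = "nascentfret_pairing_error"
    )
  }
  cmp <- compare_conditions(bound, released, tail = tail)
  cmp$equivalence <- list(exposure_equivalent = TRUE, tunnel_offset = offset,
                          exposed_up_to = tr)
  cmp
}

#' Per-temperature condition profiles of a thermal series
#'
#' Groups replicate FRET results by measurement temperature and profiles
#' each group; replicate counts may differ across temperatures. A
#' monotonicity diagnostic (is the mean curve non-increasing with
#' temperature?) is reported, not enforced.
#'
#' @param results Tibble of [compute_experiment_fret()] rows for one
#'   construct/truncation/probe/state across temperatures.
#' @param include_qc_failed Passed to [aggregate_profile()].
#' @return Tibble ordered by temperature: `temperature`, `mean`, `sem`,
#'   `n`, `replicate_e` (list-column), with attribute
#'   `monotone_nonincreasing`.
#' @export
thermal_curve <- function(results, include_qc_failed = FALSE) {
  if (any(results$temperature < 4) || any(results$temperature > 50)) {
    rlang::abort("Temperatures must lie within the assay range 4-50 degC.",
                 class = "nascentfret_bad_param")
  }
  temps <- sort(unique(results$temperature))
  rows <- lapply(temps, function(tt) {
    pr <- aggregate_profile(results[results$temperature == tt, ],
                            include_qc_failed = include_qc_failed)
    tibble::tibble(temperature = tt, mean = pr$mean, sem = pr$sem,
                   n = pr$n, replicate_e = list(pr$replicate_e))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "monotone_nonincreasing") <-
    all(diff(out$mean) <= 1e-12)
  out
}

#' Wild-type minus mutant thermal difference curve
#'
#' Per shared temperature: difference of mean FRET, propagated SEM
#' `sqrt(sem_ref^2 + sem_mut^2)`, and a one-tailed Student's t p-value in
#' the direction reference > mutant (the construction used for
#' denaturation difference plots).
#'
#' @param reference,mutant [thermal_curve()] tables on a common
#'   temperature grid.
#' @param tail `"one"` (default, reference > mutant) or `"two"`.
#' @return Tibble: `temperature`, `delta_mean`, `delta_sem`,
#'   `t_statistic`, `p_value`, `n_ref`, `n_mut`.
#' @export
delta_fret <- function(reference, mutant, tail = "one") {
  if (!isTRUE(all.equal(reference$temperature, mutant$temperature))) {
    rlang::abort(
      paste0("Temperature grids differ: {",
             paste(reference$temperature, collapse = ", "), "} vs {",
             paste(mutant$temperature, collapse = ", "), "}."),
      class = "nascentfret_grid_mismatch"
    )
  }
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    a <- reference$replicate_e[[i]]
    b <- mutant$replicate_e[[i]]
    st <- .student_t(a, b, tail)
    tibble::tibble(
      temperature = reference$temperature[i],
      delta_mean = reference$mean[i] - mutant$mean[i],
      delta_sem = sqrt(reference$sem[i]^2 + mutant$sem[i]^2),
      t_statistic = st$t, p_value = st$p,
      n_ref = reference$n[i], n_mut = mutant$n[i]
    )
  })
  dplyr::bind_rows(rows)
}
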