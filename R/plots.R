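# Line-with-error-band renderings of length scans and thermal curves.
# ggplot2 is suggested, not imported; these helpers are optional sugar.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("Plotting requires the ggplot2 package.",
                 class = "nascentfret_missing_dependency")
  }
}

#' Plot a length scan (reference vs mutant compaction profile)
#'
#' @param scan A [length_scan()] table.
#' @param labels Names for the two series.
#' @return A ggplot object.
#' @export
plot_length_scan <- function(scan, labels = c("wild type", "mutant")) {
  .need_ggplot()
  long <- dplyr::bind_rows(
    tibble::tibble(truncation = scan$truncation, series = labels[1],
                   mean = scan$mean_ref, sem = scan$sem_ref),
    tibble::tibble(truncation = scan$truncation, series = labels[2],
                   mean = scan$mean_mut, sem = scan$sem_mut)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truncation,
                                     y = 100 * .data$mean,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * (.data$mean - .data$sem),
                                      ymax = 100 * (.data$mean + .data$sem)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "truncation residue", y = "FRET efficiency (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot thermal denaturation curves
#'
#' @param curves Named list of [thermal_curve()] tables (one per
#'   construct).
#' @return A ggplot object.
#' @export
plot_thermal <- function(curves) {
  .need_ggplot()
  long <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    tc <- curves[[nm]]
    tibble::tibble(series = nm, temperature = tc$temperature,
                   mean = tc$mean, sem = tc$sem)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$temperature,
                                     y = 100 * .data$mean,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * (.data$mean - .data$sem),
                                      ymax = 100 * (.data$mean + .data$sem)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "temperature (°C)", y = "FRET efficiency (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
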