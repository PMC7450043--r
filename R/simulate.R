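# Synthetic reaction generator: emulates matched four-reaction (D/DA/BD/BDA)
# in vitro translation experiments as spectra + scintillation counts.

.wavelength_grid <- 450:600

#' CFP emission line shape
#'
#' Fixed documented donor line shape: a two-Gaussian mixture (main peak
#' 476 nm, sd 12 nm; shoulder 503 nm, relative amplitude 0.85, sd 18 nm)
#' normalised to unit peak over the 450-600 nm measurement grid. The exact
#' shape is irrelevant to the FRET ratio by construction; it only has to
#' place the emission maximum near 475 nm with a realistic top-5 window.
#'
#' @param wavelength Wavelengths in nm.
#' @return Relative emission intensity, unit peak on the standard grid.
#' @export
cfp_emission_shape <- function(wavelength = .wavelength_grid) {
  raw <- function(l) {
    exp(-(l - 476)^2 / (2 * 12^2)) + 0.85 * exp(-(l - 503)^2 / (2 * 18^2))
  }
  raw(wavelength) / max(raw(.wavelength_grid))
}

# Donor brightness at temperature T (linear loss from the 25 degC reference).
.brightness_at <- function(params, temperature) {
  params$donor_brightness *
    (1 - params$brightness_temp_coeff * (temperature - 25))
}

# Fluorescent chain population per role, in units of rnc_conc:
# D carries readthrough + stalled unquenched donors; DA carries quenched
# readthrough donors + unquenched stalled donors; blanks carry none.
.population_signal <- function(params, role, e_chain) {
  switch(role,
    D   = 1 + params$s_d,
    DA  = (1 - e_chain) + params$s_da,
    BD  = 0,
    BDA = 0,
    rlang::abort(paste0("Unknown reaction role: ", role),
                 class = "nascentfret_bad_role")
  )
}

#' Simulate one CFP emission spectrum
#'
#' Emission on the 450-600 nm grid (1 nm steps):
#' `brightness(T) * population_signal * shape(lambda) + bg_level`, with
#' optional multiplicative Gaussian noise
#' (`sd = noise_cv * noise-free intensity`).
#'
#' @param params A [generative_params()] object.
#' @param role One of `"D"`, `"DA"`, `"BD"`, `"BDA"`.
#' @param e_chain Per-chain FRET of readthrough chains (ignored for
#'   blanks).
#' @param temperature Acquisition temperature, degC.
#' @return A [spectrum_record()].
#' @export
simulate_spectrum <- function(params, role, e_chain = 0, temperature = 25) {
  stopifnot(inherits(params, "generative_params"))
  signal <- .population_signal(params, role, e_chain)
  mu <- .brightness_at(params, temperature) * params$rnc_conc * signal *
    cfp_emission_shape(.wavelength_grid) + params$bg_level
  intensity <- mu
  if (params$noise_cv > 0) {
    intensity <- mu + stats::rnorm(length(mu), 0, params$noise_cv * mu)
  }
  spectrum_record(.wavelength_grid, intensity, temperature)
}

#' Simulate a scintillation count rate
#'
#' Only readthrough chains carry the 14C label (it enters via the
#' suppressor tRNA), so D and DA reactions count
#' `ce * sa * vol * rnc_conc + cpm_background` while blanks count
#' background only. Realized counts are Poisson over the
#' `count_minutes` window, reported as counts/min.
#'
#' @inheritParams simulate_spectrum
#' @return Counts per minute (scalar).
#' @export
simulate_counts <- function(params, role) {
  stopifnot(inherits(params, "generative_params"))
  if (!role %in% c("D", "DA", "BD", "BDA")) {
    rlang::abort(paste0("Unknown reaction role: ", role),
                 class = "nascentfret_bad_role")
  }
  mean_cpm <- if (role %in% c("D", "DA")) {
    params$ce * params$sa * params$vol * params$rnc_conc +
      params$cpm_background
  } else {
    params$cpm_background
  }
  if (!params$count_noise) return(mean_cpm)
  stats::rpois(1, mean_cpm * params$count_minutes) / params$count_minutes
}

# 31-bit deterministic substream seed from (master seed, condition,
# replicate): polynomial string hash, all arithmetic exact in doubles.
derive_seed <- function(seed, key, replicate = 1L) {
  s <- paste(condition_string(key), replicate, sep = "#")
  h <- 0
  m <- 2147483629
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

#' Simulate one matched four-reaction experiment
#'
#' Builds the per-chain FRET from the condition's target apparent value in
#' the ground-truth table (general stall inversion, so the noise-free
#' pipeline output reproduces the target exactly), then emits D, DA, BD and
#' BDA samples with spectra and counts, plus the realized readthrough
#' ratio `(1 + s_da) / (1 + s_d)` carried as metadata.
#'
#' @param key A [condition_key()].
#' @param truth Ground-truth table; defaults to the packaged fixture.
#' @param params A [generative_params()] object.
#' @param seed Master seed; the actual stream is a deterministic
#'   per-(condition, replicate) substream, so the same `(key, seed,
#'   replicate)` always yields a bit-identical result. `NULL` leaves the
#'   RNG state alone.
#' @param replicate Replicate index used in substream derivation and
#'   sample ids.
#' @param e_chain Optional per-chain FRET override; bypasses the
#'   ground-truth lookup (used to drive the generator directly on a grid).
#' @return A list of class `reaction_set`: `experiment_id`, `condition`,
#'   `samples` (named `D`, `DA`, `BD`, `BDA`), `readthrough_ratio`,
#'   `provenance`, and the ground-truth `e_chain` as attribute
#'   `"e_chain_truth"`.
#' @export
#' @examples
#' key <- condition_key("WT", 487, 624)
#' rs <- simulate_reaction_set(key, seed = 1)
#' compute_experiment_fret(rs)$e_fret
simulate_reaction_set <- function(key, truth = ground_truth_table(),
                                  params = generative_params(),
                                  seed = NULL, replicate = 1L,
                                  e_chain = NULL) {
  stopifnot(inherits(key, "condition_key"),
            inherits(params, "generative_params"))
  if (is.null(e_chain)) {
    e_app <- gt_lookup(truth, key)
    e_chain <- chain_fret_general(e_app, params$s_d, params$s_da)
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, key, replicate))
  roles <- c("D", "DA", "BD", "BDA")
  ratio <- (1 + params$s_da) / (1 + params$s_d)
  experiment_id <- paste0(condition_string(key), "_rep", replicate)
  samples <- lapply(roles, function(role) {
    structure(list(
      sample_id = paste(experiment_id, role, sep = "_"),
      role = role,
      condition = key,
      spectrum = simulate_spectrum(params, role, e_chain, key$temperature),
      cpm = simulate_counts(params, role),
      readthrough_ratio = ratio,
      ce = params$ce, sa = params$sa, vol = params$vol
    ), class = "reaction_sample")
  })
  names(samples) <- roles
  structure(
    list(experiment_id = experiment_id, condition = key, samples = samples,
         readthrough_ratio = ratio, provenance = "simulated",
         schema_version = "nascent-fret/1"),
    class = "reaction_set", e_chain_truth = e_chain
  )
}

#' Simulate replicate experiments for one condition
#'
#' @inheritParams simulate_reaction_set
#' @param n Number of independent replicates (>= 1).
#' @return List of `n` reaction sets with independent noise substreams.
#' @export
simulate_experiment_series <- function(key, truth = ground_truth_table(),
                                       n = 4, params = generative_params(),
                                       seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rlang::abort("n must be a positive replicate count.",
                 class = "nascentfret_bad_param")
  }
  lapply(seq_len(n), function(r) {
    simulate_reaction_set(key, truth, params, seed = seed, replicate = r)
  })
}

#' Simulate a thermal denaturation series
#'
#' One condition measured across a temperature ladder. Donor brightness
#' falls with temperature in D and DA alike (and cancels in the FRET
#' ratio); the apparent FRET follows the condition's fixture denaturation
#' curve via temperature interpolation in the ground-truth table.
#'
#' @inheritParams simulate_experiment_series
#' @param temperatures Temperatures in degC, each within `[4, 50]`.
#' @return Flat list of reaction sets (`n` replicates per temperature);
#'   each set's condition carries its temperature.
#' @export
simulate_thermal_series <- function(key, truth = ground_truth_table(),
                                    temperatures, n = 3,
                                    params = generative_params(),
                                    seed = NULL) {
  if (any(temperatures < 4) || any(temperatures > 50)) {
    rlang::abort("Temperatures must lie within the assay range 4-50 degC.",
                 class = "nascentfret_bad_param")
  }
  out <- lapply(temperatures, function(tt) {
    k <- condition_key(key$construct, key$probe_site, key$truncation,
                       key$ribosome_state, temperature = tt)
    simulate_experiment_series(k, truth, n = n, params = params, seed = seed)
  })
  unlist(out, recursive = FALSE)
}

#' Simulate an immunoblot band-intensity table
#'
#' Emits replicate lanes (band B = core-glycosylated, band C = mature,
#' plus a loading control) whose loading-normalised band C matches the
#' requested fraction of the wild-type level. Mutant lanes accumulate in
#' band B what they fail to mature into band C.
#'
#' @param relative_band_c Named numeric vector of band-C levels relative
#'   to wild type, in `[0, 1]`; must contain `"WT"`.
#' @param n Replicate lanes per construct.
#' @param noise_cv Fractional Gaussian noise on every intensity; 0 for
#'   noise-free lanes.
#' @param seed Optional seed.
#' @return Tibble with columns `construct`, `replicate`, `band_b`,
#'   `band_c`, `loading_control`.
#' @export
#' @examples
#' simulate_blot_table(c(WT = 1, "A455E+PT" = 0.2), n = 4, noise_cv = 0)
simulate_blot_table <- function(relative_band_c, n = 4, noise_cv = 0,
                                seed = NULL) {
  if (is.null(names(relative_band_c)) || !"WT" %in% names(relative_band_c)) {
    rlang::abort("relative_band_c must be named and include \"WT\".",
                 class = "nascentfret_bad_param")
  }
  if (any(relative_band_c < 0) || any(relative_band_c > 1)) {
    rlang::abort("relative_band_c fractions must lie in [0, 1].",
                 class = "nascentfret_bad_param")
  }
  if (!is.null(seed)) set.seed(seed)
  base_c <- 450   # wild-type band C intensity
  base_b <- 200   # band B floor in a fully maturing lane
  loading <- 1000
  jitter <- function(x) {
    if (noise_cv <= 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, noise_cv)), 0)
  }
  rows <- lapply(names(relative_band_c), function(cn) {
    frac <- relative_band_c[[cn]]
    tibble::tibble(
      construct = cn,
      replicate = seq_len(n),
      band_b = jitter(rep(base_b + base_c * (1 - frac), n)),
      band_c = jitter(rep(base_c * frac, n)),
      loading_control = jitter(rep(loading, n))
    )
  })
  dplyr::bind_rows(rows)
}
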