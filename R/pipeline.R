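# End-to-end orchestration: scenario -> simulate -> per-experiment FRET ->
# profiles / length scans / windows / thermal curves / maturation -> TSV
# outputs plus a run manifest with content hashes.

.read_scenario <- function(scenario) {
  if (is.character(scenario) && length(scenario) == 1L) {
    if (grepl("\\.ya?ml$", scenario)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        rlang::abort("Reading YAML scenarios requires the yaml package.",
                     class = "nascentfret_scenario_error")
      }
      scenario <- yaml::read_yaml(scenario)
    } else {
      scenario <- jsonlite::read_json(scenario, simplifyVector = TRUE)
    }
  }
  if (!is.list(scenario)) {
    rlang::abort("Scenario must be a list or a JSON/YAML file path.",
                 class = "nascentfret_scenario_error")
  }
  scenario
}

.validate_scenario <- function(sc) {
  if (is.null(sc$seed)) {
    rlang::abort("Scenario validation: a seed is required for simulation runs.",
                 class = "nascentfret_scenario_error")
  }
  if (is.null(sc$conditions) || length(sc$conditions) == 0L) {
    rlang::abort("Scenario validation: no conditions given.",
                 class = "nascentfret_scenario_error")
  }
  if (is.data.frame(sc$conditions)) {
    sc$conditions <- lapply(seq_len(nrow(sc$conditions)),
                            function(i) as.list(sc$conditions[i, ]))
  }
  for (cd in sc$conditions) {
    n <- cd$n %||% sc$n %||% 4
    if (!is.numeric(n) || n < 1) {
      rlang::abort("Scenario validation: every condition needs a positive replicate count.",
                   class = "nascentfret_scenario_error")
    }
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.scenario_params <- function(sc) {
  args <- sc$params %||% list()
  if (!is.null(sc$noise_cv)) args$noise_cv <- sc$noise_cv
  if (isTRUE(sc$noise_off)) {
    noise_free(do.call(generative_params, args))
  } else {
    do.call(generative_params, args)
  }
}

.condition_from_list <- function(cd) {
  condition_key(cd$construct, cd$probe_site, cd$truncation,
                cd$ribosome_state %||% "bound",
                cd$temperature %||% 25)
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulates every condition of a scenario, computes per-experiment FRET,
#' aggregates profiles, and — where the scenario's conditions support them
#' — emits length scans with folding windows (per mutant construct against
#' the scenario's reference over shared truncations) and thermal
#' difference curves (per construct over shared temperatures). An optional
#' `blot` block adds maturation quantification. All tables are written as
#' TSV under `out_dir` together with `manifest.json` listing every output
#' file with an md5 content hash, the seed, package version and QC
#' exclusion counts. Rerunning the same scenario reproduces every output
#' byte for byte.
#'
#' @param scenario A list (or JSON/YAML path) with elements:
#'   `seed` (required); `conditions`, a list of condition specs
#'   (`construct`, `probe_site`, `truncation`, optional `ribosome_state`,
#'   `temperature`/`temperatures`, `n`); optional `n` (default replicate
#'   count, 4), `noise_cv`, `noise_off`, `params` (overrides for
#'   [generative_params()]), `alpha` (default 0.05), `reference`
#'   (default `"WT"`), `keep_qc_failed`, and `blot` (list with
#'   `relative_band_c`, optional `n`, `noise_cv`).
#' @param out_dir Output directory.
#' @return Invisible list with the results table, profiles, scans,
#'   windows, thermal tables, maturation results and manifest.
#' @export
run_pipeline <- function(scenario, out_dir) {
  sc <- .validate_scenario(.read_scenario(scenario))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .scenario_params(sc)
  truth <- ground_truth_table()
  alpha <- sc$alpha %||% 0.05
  reference <- sc$reference %||% "WT"
  keep_qc <- isTRUE(sc$keep_qc_failed)

  # Simulate and measure every condition (expanding temperature ladders).
  results <- list()
  for (cd in sc$conditions) {
    n <- cd$n %||% sc$n %||% 4
    temps <- cd$temperatures %||% (cd$temperature %||% 25)
    for (tt in temps) {
      cd$temperature <- tt
      key <- .condition_from_list(cd)
      sets <- simulate_experiment_series(key, truth, n = n, params = params,
                                         seed = sc$seed)
      results <- c(results, lapply(sets, compute_experiment_fret))
    }
  }
  results <- dplyr::bind_rows(results)
  files <- character(0)
  write_out <- function(tbl, name) {
    p <- file.path(out_dir, name)
    write_results(tbl, p, seed = sc$seed)
    files <<- c(files, p)
    p
  }
  write_out(results, "results.tsv")

  # Profiles per condition.
  grp <- dplyr::group_split(dplyr::group_by(
    results, .data$construct, .data$probe_site, .data$truncation,
    .data$ribosome_state, .data$temperature))
  profiles <- lapply(grp, aggregate_profile, include_qc_failed = keep_qc)
  profile_tbl <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::bind_cols(condition_fields(p$condition),
                     tibble::tibble(mean_e = p$mean, sem = p$sem, n = p$n,
                                    n_excluded = p$n_excluded))
  }))
  write_out(profile_tbl, "profiles.tsv")

  # Length scans and folding windows: per (probe, state) group at the
  # reference temperature, mutant constructs sharing >= 2 truncations
  # with the reference.
  pick <- function(construct, probe, state) {
    Filter(function(p) {
      k <- p$condition
      k$construct == construct && k$probe_site == probe &&
        k$ribosome_state == state && k$temperature == 25
    }, profiles)
  }
  scans <- list(); windows <- list()
  combos <- unique(profile_tbl[profile_tbl$temperature == 25,
                               c("construct", "probe_site",
                                 "ribosome_state")])
  combos <- combos[combos$construct != reference, , drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    cn <- combos$construct[i]; pb <- combos$probe_site[i]
    st <- combos$ribosome_state[i]
    ref_p <- pick(reference, pb, st)
    mut_p <- pick(cn, pb, st)
    shared <- intersect(.profile_truncations(ref_p),
                        .profile_truncations(mut_p))
    if (length(shared) < 1L) next
    ref_p <- Filter(function(p) p$condition$truncation %in% shared, ref_p)
    mut_p <- Filter(function(p) p$condition$truncation %in% shared, mut_p)
    scan <- length_scan(ref_p, mut_p)
    tag <- paste0(gsub("[^A-Za-z0-9]+", "_", cn), "_probe", pb, "_", st)
    scans[[tag]] <- scan
    write_out(scan, paste0("scan_", tag, ".tsv"))
    win <- detect_folding_window(scan, alpha = alpha)
    windows[[tag]] <- win
    write_out(tibble::tibble(construct = cn, probe_site = pb,
                             ribosome_state = st,
                             start_truncation = win$start_truncation,
                             end_truncation = win$end_truncation,
                             n_truncations = win$n_truncations,
                             alpha = alpha),
              paste0("window_", tag, ".tsv"))
  }

  # Thermal curves and difference curves where a condition spans >= 2
  # temperatures.
  thermals <- list(); deltas <- list()
  tgrp <- unique(results[, c("construct", "probe_site", "truncation",
                             "ribosome_state")])
  for (i in seq_len(nrow(tgrp))) {
    sel <- results$construct == tgrp$construct[i] &
      results$probe_site == tgrp$probe_site[i] &
      results$truncation == tgrp$truncation[i] &
      results$ribosome_state == tgrp$ribosome_state[i]
    if (length(unique(results$temperature[sel])) < 2L) next
    tc <- thermal_curve(results[sel, ], include_qc_failed = keep_qc)
    tag <- paste0(gsub("[^A-Za-z0-9]+", "_", tgrp$construct[i]),
                  "_probe", tgrp$probe_site[i], "_trunc",
                  tgrp$truncation[i], "_", tgrp$ribosome_state[i])
    thermals[[tag]] <- tc
    write_out(dplyr::select(tc, -"replicate_e"),
              paste0("thermal_", tag, ".tsv"))
  }
  for (tag in names(thermals)) {
    if (startsWith(tag, gsub("[^A-Za-z0-9]+", "_", reference))) next
    ref_tag <- sub("^[A-Za-z0-9_]+?_probe", paste0(reference, "_probe"),
                   tag)
    if (!ref_tag %in% names(thermals)) next
    dc <- delta_fret(thermals[[ref_tag]], thermals[[tag]])
    deltas[[tag]] <- dc
    write_out(dc, paste0("delta_", tag, ".tsv"))
  }

  # Maturation block.
  maturation <- NULL
  if (!is.null(sc$blot)) {
    lanes <- simulate_blot_table(unlist(sc$blot$relative_band_c),
                                 n = sc$blot$n %||% 4,
                                 noise_cv = sc$blot$noise_cv %||% 0,
                                 seed = sc$seed)
    write_out(lanes, "blot_lanes.tsv")
    muts <- setdiff(unique(lanes$construct), reference)
    maturation <- dplyr::bind_rows(lapply(muts, function(cn) {
      m <- relative_trafficking(lanes, cn, reference)
      tibble::tibble(construct = cn,
                     relative_to_reference = m$relative_to_reference,
                     sem = m$sem, n = m$n, percent_c = m$percent_c)
    }))
    write_out(maturation, "maturation.tsv")
  }

  manifest <- list(
    package = "nascentFRET",
    version = as.character(utils::packageVersion("nascentFRET")),
    seed = sc$seed,
    n_experiments = nrow(results),
    n_qc_excluded = sum(!results$qc_pass),
    files = lapply(files, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, profiles = profiles, scans = scans,
                 windows = windows, thermal = thermals, delta = deltas,
                 maturation = maturation, manifest = manifest))
}
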