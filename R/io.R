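# Plain-text, versioned serialisation of experiment bundles and result
# tables: metadata as TSV, spectra as one CSV per sample, results as TSV
# with a commented header. Everything is diff-able and round-trips at full
# float precision.

.schema_version <- "nascent-fret/1"

# 17 significant digits guarantee an exact double round trip (the default
# shortest-representation writer can be off by one ulp).
.fmt17 <- function(x) sprintf("%.17g", x)

#' Write an experiment bundle to a directory
#'
#' Lays out `metadata.tsv` (one row per reaction sample: role, condition
#' fields, counts, readthrough ratio, counting constants, schema version)
#' and one `*.csv` spectrum per sample (`wavelength_nm`, `intensity`).
#'
#' @param set A `reaction_set` (see [simulate_reaction_set()]).
#' @param dir Output directory; created if needed.
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(set, dir) {
  stopifnot(inherits(set, "reaction_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dplyr::bind_rows(lapply(set$samples, function(s) {
    dplyr::bind_cols(
      tibble::tibble(experiment_id = set$experiment_id,
                     sample_id = s$sample_id, role = s$role),
      condition_fields(s$condition),
      tibble::tibble(cpm = .fmt17(s$cpm),
                     readthrough_ratio = .fmt17(s$readthrough_ratio),
                     ce = s$ce, sa = s$sa, vol = s$vol,
                     spectrum_file = paste0(s$sample_id, ".csv"),
                     provenance = set$provenance,
                     schema_version = set$schema_version)
    )
  }))
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"), progress = FALSE)
  for (s in set$samples) {
    readr::write_csv(
      tibble::tibble(wavelength_nm = s$spectrum$wavelength,
                     intensity = .fmt17(s$spectrum$intensity),
                     temperature = s$spectrum$temperature),
      file.path(dir, paste0(s$sample_id, ".csv")), progress = FALSE
    )
  }
  invisible(dir)
}

#' Read and validate an experiment bundle
#'
#' Enforces the bundle invariants with distinct error classes: schema
#' version match (`nascentfret_schema_error`), exactly one sample per role
#' D/DA/BD/BDA (`nascentfret_missing_role`), a shared condition across the
#' quadruple, and the complete 151-point emission grid
#' (`nascentfret_grid_error`).
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `reaction_set`.
#' @export
read_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) {
    rlang::abort(paste0("No metadata.tsv under ", dir),
                 class = "nascentfret_io_error")
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            cpm = readr::col_character(),
                            readthrough_ratio = readr::col_character()))
  # base strtod is correctly rounded; the fast parser can be one ulp off
  meta$cpm <- as.numeric(meta$cpm)
  meta$readthrough_ratio <- as.numeric(meta$readthrough_ratio)
  bad_schema <- setdiff(unique(meta$schema_version), .schema_version)
  if (length(bad_schema)) {
    rlang::abort(
      sprintf("Schema version mismatch: bundle declares \"%s\", reader supports \"%s\".",
              bad_schema[1], .schema_version),
      class = "nascentfret_schema_error"
    )
  }
  roles <- c("D", "DA", "BD", "BDA")
  missing <- setdiff(roles, meta$role)
  if (length(missing) || nrow(meta) != 4L || anyDuplicated(meta$role)) {
    rlang::abort(
      paste0("Incomplete quadruple: expected exactly one sample per role ",
             "D, DA, BD, BDA",
             if (length(missing))
               paste0("; missing role(s): ", paste(missing, collapse = ", "))
             else "; duplicated or extra roles present", "."),
      class = "nascentfret_missing_role"
    )
  }
  conds <- unique(meta[, c("construct", "probe_site", "truncation",
                           "ribosome_state", "temperature")])
  if (nrow(conds) != 1L) {
    rlang::abort("All four samples of a bundle must share one condition.",
                 class = "nascentfret_io_error")
  }
  key <- condition_key(conds$construct, conds$probe_site, conds$truncation,
                       conds$ribosome_state, conds$temperature)
  samples <- lapply(roles, function(role) {
    row <- meta[meta$role == role, ]
    sp <- readr::read_csv(file.path(dir, row$spectrum_file),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            intensity = readr::col_character()))
    sp$intensity <- as.numeric(sp$intensity)
    spec <- spectrum_record(sp$wavelength_nm, sp$intensity,
                            if ("temperature" %in% names(sp))
                              sp$temperature[1] else key$temperature)
    structure(list(
      sample_id = row$sample_id, role = role, condition = key,
      spectrum = spec, cpm = row$cpm,
      readthrough_ratio = row$readthrough_ratio,
      ce = row$ce, sa = row$sa, vol = row$vol
    ), class = "reaction_sample")
  })
  names(samples) <- roles
  structure(
    list(experiment_id = meta$experiment_id[1], condition = key,
         samples = samples,
         readthrough_ratio = samples$D$readthrough_ratio,
         provenance = meta$provenance[1],
         schema_version = .schema_version),
    class = "reaction_set"
  )
}

#' Write a FRET results table
#'
#' TSV with a fixed column order and a commented header carrying the
#' schema version and, when given, seed provenance. QC-failed experiments
#' are written with their flag set rather than dropped; exclusion is an
#' analysis-stage decision.
#'
#' @param results Tibble of results, e.g. rows from
#'   [compute_experiment_fret()].
#' @param path Output file path.
#' @param seed Optional seed recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL) {
  header <- c(
    paste0("# schema: ", .schema_version),
    if (!is.null(seed)) paste0("# seed: ", seed),
    paste0("# written: nascentFRET ",
           as.character(utils::packageVersion("nascentFRET")))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  close(con); on.exit()
  readr::write_tsv(results, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
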