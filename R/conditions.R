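#' Construct labels and their mutation content
#'
#' Maps each construct label used in the assay to the set of CFTR residue
#' substitutions it carries. `"WT"` is the wild-type CFP-NBD1 fusion;
#' `"+PT"` constructs carry the S492P/I539T second-site suppressor pair in
#' addition to the disease mutation.
#'
#' @return Named list; each element is a character vector of substitutions
#'   (empty for wild type).
#' @export
#' @examples
#' construct_mutations()[["A455E+PT"]]
construct_mutations <- function() {
  list(
    "WT"       = character(0),
    "L441P"    = "L441P",
    "A455E"    = "A455E",
    "M470V"    = "M470V",
    "S492F"    = "S492F",
    "I507del"  = "I507del",
    "F508del"  = "F508del",
    "V520F"    = "V520F",
    "G551D"    = "G551D",
    "L558S"    = "L558S",
    "A559T"    = "A559T",
    "R560K"    = "R560K",
    "R560T"    = "R560T",
    "A455E+PT" = c("A455E", "S492P", "I539T"),
    "L558S+PT" = c("L558S", "S492P", "I539T")
  )
}

#' Acceptor probe sites with a defined readthrough QC band
#'
#' @keywords internal
.probe_sites <- c(389L, 487L, 567L)

#' Define one experimental condition
#'
#' A condition key identifies a single assay condition: the construct (which
#' fixes the mutation set), the CFTR residue carrying the acceptor dye (an
#' amber-codon site), the truncation residue at which the nascent chain ends,
#' whether the chain is still ribosome-bound or has been released with
#' RNase A, and the measurement temperature.
#'
#' @param construct Construct label; must be a name in
#'   [construct_mutations()].
#' @param probe_site Acceptor residue, one of 389, 487, 567.
#' @param truncation Truncation residue (chain end); must exceed
#'   `probe_site`.
#' @param ribosome_state `"bound"` or `"released"`.
#' @param temperature Measurement temperature in degrees Celsius, within
#'   the assay range 4-50.
#' @return A list of class `condition_key`.
#' @export
#' @examples
#' condition_key("WT", probe_site = 487, truncation = 654)
condition_key <- function(construct, probe_site, truncation,
                          ribosome_state = c("bound", "released"),
                          temperature = 25) {
  ribosome_state <- match.arg(ribosome_state)
  muts <- construct_mutations()
  if (!is.character(construct) || length(construct) != 1L ||
      !construct %in% names(muts)) {
    rlang::abort(
      paste0("Unknown construct label: ", format(construct)[1],
             ". Known labels: ", paste(names(muts), collapse = ", ")),
      class = "nascentfret_bad_condition"
    )
  }
  probe_site <- as.integer(probe_site)
  truncation <- as.integer(truncation)
  if (!probe_site %in% .probe_sites) {
    rlang::abort(
      paste0("Unknown probe site ", probe_site,
             "; expected one of ", paste(.probe_sites, collapse = ", ")),
      class = "nascentfret_bad_condition"
    )
  }
  if (truncation <= probe_site) {
    rlang::abort(
      "The acceptor probe site must lie before the truncation residue.",
      class = "nascentfret_bad_condition"
    )
  }
  if (!is.finite(temperature) || temperature < 4 || temperature > 50) {
    rlang::abort(
      "Temperature must be within the assay range of 4-50 degrees C.",
      class = "nascentfret_bad_condition"
    )
  }
  structure(
    list(
      construct = construct,
      mutations = muts[[construct]],
      probe_site = probe_site,
      truncation = truncation,
      ribosome_state = ribosome_state,
      temperature = as.numeric(temperature)
    ),
    class = "condition_key"
  )
}

#' @export
format.condition_key <- function(x, ...) {
  sprintf("%s/probe%d/trunc%d/%s/%g degC",
          x$construct, x$probe_site, x$truncation, x$ribosome_state,
          x$temperature)
}

#' @export
print.condition_key <- function(x, ...) {
  cat("<condition_key>", format(x), "\n")
  invisible(x)
}

# Canonical string used for hashing / identifiers; excludes temperature when
# asked so thermal series share an experiment family name.
condition_string <- function(key, with_temperature = TRUE) {
  stopifnot(inherits(key, "condition_key"))
  base <- paste(key$construct, key$probe_site, key$truncation,
                key$ribosome_state, sep = "_")
  if (with_temperature) paste(base, key$temperature, sep = "_") else base
}

# One-row tibble of the identifying fields, used when flattening results.
condition_fields <- function(key) {
  tibble::tibble(
    construct = key$construct,
    probe_site = key$probe_site,
    truncation = key$truncation,
    ribosome_state = key$ribosome_state,
    temperature = key$temperature
  )
}

same_condition <- function(a, b) {
  identical(condition_string(a), condition_string(b))
}
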