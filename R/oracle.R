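#' Apparent FRET of a stalled/readthrough chain population
#'
#' The assay measures a population FRET, not a per-chain FRET. Reactions
#' contain both readthrough chains (full acceptor incorporation, per-chain
#' donor quench `e_chain`) and stalled chains that terminated at the amber
#' codon. Stalled chains fluoresce as unquenched donors but carry no 14C
#' label (the label enters only through the suppressor tRNA), so the
#' measured fluorescence-per-nM is inflated by the stall ratio. With stall
#' ratios `s_d` and `s_da` (stalled : readthrough chains) in the donor-only
#' and donor+acceptor reactions, the apparent efficiency reported by the
#' donor-quenching ratio is
#'
#' \deqn{E_{app} = 1 - \frac{(1 - E_{chain}) + s_{DA}}{1 + s_D}}
#'
#' For matched stalls (`s_d == s_da == s`) this reduces to
#' `e_chain / (1 + s)`; mismatched stalls bias the apparent value, which is
#' what the readthrough-ratio QC band guards against.
#'
#' @param e_chain Per-chain donor quench of acceptor-labelled readthrough
#'   chains, in `[0, 1]`.
#' @param s_d,s_da Stalled-to-readthrough chain ratio in the D and DA
#'   reactions (non-negative).
#' @return Apparent FRET efficiency (unitless). Vectorised.
#' @seealso [chain_fret()] for the matched-stall inverse.
#' @export
#' @examples
#' apparent_fret(0.5, 0, 0)        # no stalls: identity
#' apparent_fret(0.5, 0.25, 0.25)  # matched stalls dilute FRET
#' apparent_fret(0.5, 0.5, 0)      # mismatch inflates it
apparent_fret <- function(e_chain, s_d, s_da) {
  if (any(!is.finite(e_chain)) || any(e_chain < 0) || any(e_chain > 1)) {
    rlang::abort("e_chain must lie in [0, 1].",
                 class = "nascentfret_bad_param")
  }
  if (any(!is.finite(s_d)) || any(s_d < 0) ||
      any(!is.finite(s_da)) || any(s_da < 0)) {
    rlang::abort("Stall ratios s_d and s_da must be non-negative.",
                 class = "nascentfret_bad_param")
  }
  1 - ((1 - e_chain) + s_da) / (1 + s_d)
}

#' Chain-level FRET that yields a target apparent FRET under matched stalls
#'
#' Inverse of [apparent_fret()] when both reactions share one stall ratio
#' `s`: `e_chain = e_app * (1 + s)`. Used to build synthetic fixtures whose
#' pipeline output reproduces a stated apparent mean.
#'
#' @param e_app Target apparent FRET efficiency in `[0, 1]`.
#' @param s Shared stall ratio (non-negative).
#' @return Per-chain FRET efficiency. Errors if the inversion is infeasible
#'   (`e_app * (1 + s) > 1`), reporting the maximum feasible `s`.
#' @export
#' @examples
#' chain_fret(0.4, 0.25)   # 0.5
#' chain_fret(0.396, 0.2)  # 0.4752
chain_fret <- function(e_app, s) {
  if (any(!is.finite(e_app)) || any(e_app < 0) || any(e_app > 1)) {
    rlang::abort("e_app must lie in [0, 1].",
                 class = "nascentfret_bad_param")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    rlang::abort("s must be non-negative.", class = "nascentfret_bad_param")
  }
  e_chain <- e_app * (1 + s)
  if (any(e_chain > 1 + 1e-12)) {
    bad <- which(e_chain > 1 + 1e-12)[1]
    s_max <- 1 / e_app[bad] - 1
    rlang::abort(
      sprintf(paste0("Infeasible inversion: e_app = %.4g with s = %.4g ",
                     "implies a per-chain FRET above 1; maximum feasible ",
                     "s is %.4g."),
              e_app[bad], s[bad], s_max),
      class = "nascentfret_infeasible_inversion"
    )
  }
  pmin(e_chain, 1)
}

# General inversion used by the simulator: allows s_d != s_da.
chain_fret_general <- function(e_app, s_d, s_da) {
  e_chain <- 1 + s_da - (1 - e_app) * (1 + s_d)
  if (any(e_chain < -1e-12) || any(e_chain > 1 + 1e-12)) {
    rlang::abort(
      "Target apparent FRET is infeasible under the given stall ratios.",
      class = "nascentfret_infeasible_inversion"
    )
  }
  pmin(pmax(e_chain, 0), 1)
}
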