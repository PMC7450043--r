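# Shared helpers: deterministic parameter sets and hand-built result rows.

quiet_params <- function(...) noise_free(generative_params(...))

# Build a results tibble (the compute_experiment_fret row shape) from bare
# replicate FRET values, for exercising the aggregation layer directly.
fake_results <- function(e, key = condition_key("WT", 487, 654),
                         qc_pass = TRUE) {
  n <- length(e)
  dplyr::bind_cols(
    tibble::tibble(experiment_id = paste0("exp", seq_len(n))),
    nascentFRET:::condition_fields(key)[rep(1, n), ],
    tibble::tibble(e_fret = e, f_d = 1, f_da = 1 - e, peak_d = 1,
                   peak_da = 1, conc_d = 1, conc_da = 1,
                   readthrough_ratio = 1,
                   qc_pass = rep_len(qc_pass, n), conc_flagged = FALSE)
  )
}

# Profile built directly from replicate values.
profile_of <- function(e, key = condition_key("WT", 487, 654), ...) {
  aggregate_profile(fake_results(e, key), ...)
}

# Noise-free pipeline estimate for a directly specified chain population.
pipeline_e <- function(e_chain, s_d, s_da) {
  p <- quiet_params(s_d = s_d, s_da = s_da)
  key <- condition_key("WT", 487, 654)
  rs <- simulate_reaction_set(key, params = p, e_chain = e_chain)
  compute_experiment_fret(rs)$e_fret
}
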