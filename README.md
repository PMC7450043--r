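# nascentFRET

Analysis of donor-quenching FRET measurements on stalled
ribosome-nascent-chain complexes — the assay used to watch the CFTR first
nucleotide-binding domain (NBD1) fold cotranslationally, one chain length
at a time, and to localise the folding defects of trafficking mutations
such as A455E and L558S to a specific window of synthesis.

The package is for anyone analysing (or simulating) this class of
experiment: matched four-reaction in vitro translations — donor-only (D),
donor+acceptor (DA), and their non-fluorescent blanks (BD, BDA) — read
out as CFP emission spectra plus ¹⁴C scintillation counts.

## The measurement

Each spectrum (450–600 nm, 1 nm steps) is summarised by the mean of its
five highest intensities (~475 nm for CFP). Counts give the nascent-chain
concentration,

    [RNC] = (cpm_S − cpm_B) / (CE · SA · vol)    (nM)

and the blank-corrected fluorescence per nM in the D and DA samples gives
the FRET efficiency by donor quenching:

    E_FRET = 1 − F_DA / F_D

Because stalled (non-readthrough) chains fluoresce but carry no ¹⁴C
label, a D/DA readthrough mismatch biases the apparent efficiency; the
population model

    E_app = 1 − ((1 − E_chain) + s_DA) / (1 + s_D)

is implemented in closed form (`apparent_fret()`), drives the
readthrough-ratio QC bands (0.80–1.20 for the Arg487 acceptor site,
0.85–1.15 for Asp567), and anchors the synthetic generator so that the
entire pipeline can be verified end-to-end without laboratory data.

Downstream, replicate efficiencies aggregate into condition profiles
(mean ± SEM), wild-type/mutant length scans with pooled-variance
Student's t tests, folding-window detection, ribosome bound-vs-released
contrasts with an exit-tunnel exposure-equivalence check (30–40 residue
offset), thermal-denaturation difference curves, and immunoblot-based
maturation quantification (band B/band C).

## Worked example

Simulate four replicate experiments each for wild type and A455E at
truncation 654 (acceptor at Arg487), run the measurement, and compare:

```r
library(nascentFRET)

wt  <- condition_key("WT",    probe_site = 487, truncation = 654)
mut <- condition_key("A455E", probe_site = 487, truncation = 654)

profile_for <- function(key) {
  sets <- simulate_experiment_series(key, n = 4, seed = 1)
  aggregate_profile(dplyr::bind_rows(lapply(sets, compute_experiment_fret)))
}

p_wt  <- profile_for(wt)
p_mut <- profile_for(mut)
p_wt
#> <condition_profile> WT/probe487/trunc654/bound/25 degC: E = 0.3876 +/- 0.0019 (SEM), n = 4
p_mut
#> <condition_profile> A455E/probe487/trunc654/bound/25 degC: E = 0.3083 +/- 0.0040 (SEM), n = 4
compare_conditions(p_wt, p_mut)
#> <comparison_result> diff = 0.0794, t(6) = 17.8955, two-tailed p = 1.957e-06
```

The wild-type chain at this length is compact (E ≈ 0.39); the A455E
chain is significantly less so (ΔE ≈ 0.08, ~8 FRET points), the
late-window folding defect this assay design resolves. Each replicate
row also carries the intermediates — peak intensities, concentrations
(here ~400 nM from ~2000 cpm), the D/DA readthrough ratio and its QC
verdict:

```r
compute_experiment_fret(simulate_reaction_set(wt, seed = 1))[,
  c("e_fret", "conc_d", "conc_da", "readthrough_ratio", "qc_pass")]
#>   e_fret conc_d conc_da readthrough_ratio qc_pass
#> 1  0.386   405.    402.                 1 TRUE
```

`run_pipeline()` orchestrates whole scenarios (length scans, thermal
ladders, blot tables) from a JSON/YAML description into TSV outputs plus
a hash manifest; `write_bundle()`/`read_bundle()` serialise single
experiments losslessly.

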