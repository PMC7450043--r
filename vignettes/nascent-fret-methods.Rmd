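---
title: "Measuring cotranslational folding by donor-quenching FRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cotranslational folding by donor-quenching FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentFRET)
```

## The measurement problem

Cotranslational folding of the CFTR first nucleotide-binding domain (NBD1)
can be watched one chain length at a time: translating truncated mRNAs
without a stop codon leaves a uniform cohort of nascent chains attached to
ribosomes as peptidyl-tRNA, and a FRET pair — an N-terminal CFP donor and a
small NBD acceptor dye placed at an internal amber codon by a suppressor
tRNA — reports the compaction of the chain between the two probes. As the
truncation point moves C-terminally, the FRET efficiency traces how and
when each subdomain collapses, and wild-type/mutant comparisons at matched
lengths localise a folding defect to a specific window of synthesis.

The raw observables are humble: a CFP emission spectrum (excitation
430 nm, emission 450–600 nm at 1 nm steps) and a ¹⁴C scintillation count
for each of four reactions translated in parallel:

* **D** — donor only: suppression with [¹⁴C]Lys-tRNA^amb (no acceptor);
* **DA** — donor + acceptor: suppression with the NBD-dye-carrying tRNA;
* **BD**, **BDA** — matched blanks translated from a non-fluorescent CFP
  lacking the amber codon, used for background fluorescence and counts.

This package implements the complete path from these observables to FRET
efficiencies and the downstream condition-level analyses, plus a synthetic
generator of the whole experiment so that every stage can be verified
end-to-end against closed-form expectations.

## From spectra and counts to a FRET efficiency

Each spectrum is summarised by the mean of its **five highest
intensities** (for CFP these cluster near 475 nm). The nascent-chain
concentration of the D and DA samples comes from scintillation counting:

$$[\mathrm{RNC}] = \frac{cpm_S - cpm_B}{CE \cdot SA \cdot vol}$$

with counting efficiency $CE$ (0.95 for ¹⁴C), specific activity $SA$
(dpm/pmol) and counted volume $vol$ (ml); the result is in nM. The net,
blank-corrected fluorescence per nM nascent chain is
$F = (\text{peak} - \text{blank peak})/[\mathrm{RNC}]$ (D against BD, DA
against BDA), and the efficiency follows from donor quenching:

$$E_{\mathrm{FRET}} = 1 - F_{DA} / F_D.$$

Acceptor emission is negligible under these conditions, so only the donor
channel enters.

### Why the ¹⁴C correction matters: stalled chains

Not every ribosome reads through the amber codon. Chains that stall there
have a mature CFP but no acceptor and — because the ¹⁴C label rides on the
suppressor tRNA — no label either. They therefore inflate fluorescence
but not the measured concentration. With stall-to-readthrough ratios
$s_D$ and $s_{DA}$ in the two reactions and a per-chain quench
$E_{chain}$, the measured population value is

$$E_{app} = 1 - \frac{(1 - E_{chain}) + s_{DA}}{1 + s_D},$$

which for matched stalls reduces to $E_{chain}/(1+s)$ and for mismatched
stalls acquires a bias linear in $1 - r$ where
$r = (1+s_{DA})/(1+s_D)$ is the D/DA readthrough ratio. This is exactly
why the assay gates on that ratio: samples are accepted only with
$r \in [0.80, 1.20]$ for the Arg487 acceptor site ($[0.85, 1.15]$ for
Asp567; the Thr389 tether control reuses the 487 band, which the assay
does not specify separately). Bounds are read inclusively. QC failure
never deletes a measurement here — the result row carries a flag and the
aggregation layer excludes it from statistics, so the exclusion is
auditable.

`apparent_fret()` and `chain_fret()` expose this population model
directly; they are the closed-form oracle against which the simulated
pipeline is tested.

## The synthetic generator

`simulate_reaction_set()` emits a matched quadruple from the generative
model: spectrum = brightness(T) × population signal × CFP line shape +
background (+ noise), counts = $CE \cdot SA \cdot vol \cdot
[\mathrm{RNC}] + cpm_{bg}$ (Poisson over the counting window). The
per-chain quench is obtained by inverting the population model at the
condition's target apparent FRET, so the noise-free pipeline output
reproduces the target to machine precision — a round trip the test suite
asserts on a 1000-point grid.

Key default parameters (`generative_params()`):

| parameter | default | meaning |
|---|---|---|
| `s_d`, `s_da` | 0.1 | matched stalls, the accepted-sample regime |
| `rnc_conc` | 400 nM | readthrough-chain concentration |
| `sa`, `ce`, `vol` | 10, 0.95, 0.5 | counting constants (dpm/pmol, –, ml) |
| `cpm_background` | 100 | blank count rate |
| `count_minutes` | 30 | scintillation integration time |
| `noise_cv` | 0.02 | fractional Gaussian noise on spectra |
| `donor_brightness` | 100 /nM | arbitrary intensity scale |
| `brightness_temp_coeff` | 0.01 /°C | linear CFP dimming from 25 °C |
| `bg_level` | 2000 | flat spectral background |

With these settings a simulated n = 4 condition shows replicate SEMs of
roughly 0.2–0.5 FRET points, the scale reported for the laboratory assay.
The counting time matters: counts enter the efficiency through two
independent concentration estimates, so short counting windows would
dominate the replicate scatter.

The CFP line shape is a fixed two-Gaussian mixture (main peak 476 nm,
σ = 12 nm; shoulder at 503 nm, relative amplitude 0.85, σ = 18 nm),
normalised to unit peak on the measurement grid. It places the emission
maximum near 475 nm with a realistic five-point peak window (478–482 nm);
its exact shape cancels from the FRET ratio by construction, which the
brightness-invariance tests make explicit.

### What the ground-truth table is and is not

`ground_truth_table()` maps each supported condition to a target apparent
FRET. Values tagged `"printed"` are reported condition means (e.g. the
wild-type rise from 4.1% at truncation 500 to 39.6% at 624 with the
Arg487 acceptor, and the bound-state values 31.8/38.3/36.8% at
truncations 664/704). Wild-type truncations without a reported number are
filled by linear interpolation between printed anchors and tagged
`"interpolated"`; mutant values at contrast truncations are encoded as
wild type minus the reported decrease (4.1 points for A455E at 584, 6.3
for L558S at 604, 7.2/7.0 at 654). Everything else — the thermal anchor
curves, the released-state values, the probe-567 series — is tagged
`"fixture"`: invented, shaped only by qualitative constraints (mutants
lower at all temperatures, a transition above 35–40 °C, convergence at
50 °C, a flat Thr389 control), and relied on by no quantitative check.

Thermal curves are piecewise-linear in temperature between anchors at 4,
25, 35, 40, 45 and 50 °C; no functional form (nor melting-temperature
fit) is imposed, because the denaturation profile enters the analysis
only through per-temperature means and differences.

### What the generator does and does not emulate

It does emulate: matched four-reaction structure, stalled-chain
contamination and readthrough mismatch, Poisson counting, multiplicative
spectral noise, temperature-dependent donor dimming, and per-replicate
independence through hashed seed substreams (one master seed, one
substream per condition × replicate, bit-identical reruns).

It does not emulate: day-to-day lysate variability (real experiments are
paired wild-type/mutant for exactly that reason), drifts or wavelength
miscalibration of the spectrometer, acceptor bleed-through (negligible in
the real assay and omitted here), aggregation or degradation of nascent
chains, or any kinetic model of elongation. Passing tests therefore
demonstrate correctness of the measurement arithmetic and the statistical
machinery under the assay's idealised error model — not robustness to
systematic instrument error.

## Statistical conventions

* Replicates aggregate as mean ± SEM with the n − 1 variance; a
  single-replicate profile reports SEM 0 with an explicit low-n flag and
  is refused by the tests.
* Contrasts use the **pooled-variance Student's t test** (the assay's
  stated convention); Welch and paired variants exist behind flags. The
  implementation is the textbook formula — the test suite cross-checks it
  against `stats::t.test` to 1e−10 and additionally covers the degenerate
  zero-variance case (identical groups give t = 0, p = 1), which the
  reference implementation refuses.
* α = 0.05 with **no multiple-testing correction**, matching the
  per-truncation asterisk convention of the source assay. Users scanning
  many truncations should treat individual borderline p-values
  accordingly.
* The one-tailed direction is fixed as reference (wild type) minus mutant
  > 0, the construction used for the thermal difference curves; the
  difference-curve SEM propagates as
  $\sqrt{SEM_{WT}^2 + SEM_{mut}^2}$.
* Replicate pairing: experiments are generated (and in the laboratory,
  run) as wild-type/mutant pairs, but the tests are unpaired by default
  since the pairing structure of the original statistics is not stated;
  `paired = TRUE` is available.

## Geometry of bound/released comparisons

A ribosome-bound chain keeps its last ~30–40 residues inside the exit
tunnel, so a bound chain truncated at residue $L$ exposes the same
sequence as a released chain truncated at $L - \delta$ with
$\delta \in [30, 40]$. `release_comparison()` refuses pairings whose
implied offset falls outside that band (the default tolerance accepts the
568/604 and 664/704 pairings, offsets 36 and 40) because a FRET
difference between non-equivalent exposures confounds ribosome attachment
with chain length.

## Numerical and design choices

* Top-5 peak selection runs over the full 151-point grid rather than a
  fixed window around 475 nm; with a CFP-shaped spectrum the two
  coincide, and the full-grid rule is unambiguous. Ties break toward the
  lower wavelength.
* Blank correction happens at the peak-intensity level, not per
  wavelength; for a flat background the two are identical, and the
  peak-level rule matches how the net intensities are defined.
* Negative efficiencies and net intensities are reported as-is, never
  clipped, so replicate averages stay unbiased; non-positive
  concentrations raise a flagged, named error instead of propagating
  silently.
* Whether blank subtraction preceded or followed peak selection in the
  original protocol is not stated; peak-level subtraction is the
  documented choice here and is exactly equivalent for flat blanks.
* Serialisation writes floating-point values with 17 significant digits
  and parses them with correctly-rounded conversion, making bundle and
  result round trips bit-exact (the shortest-representation writers can
  be one ulp off).
* The folding window is the maximal contiguous run of truncations with
  p < α and a positive reference-minus-mutant difference; detection is
  idempotent and unaffected by non-significant flanking truncations.

## Problem sizes in the test suite

The packaged checks run at desk scale by choice: n = 4 replicates per
condition for recovery checks (matching the fixture protocol), a
10×10×10 (E, s_D, s_DA) grid for oracle equivalence, 1000 null
simulations for type-I calibration, and 200 Monte-Carlo repeats for the
SEM scaling law. These sizes put the stochastic assertions comfortably
inside their tolerances while keeping a full run in the low minutes.

## Known limitations

* Fixture values for unreported conditions are interpolations or
  inventions; analyses of those conditions exercise the machinery, not
  the biology.
* The generator's error model is stationary and uncorrelated across
  wavelengths; real spectrometer noise is not.
* No melting-temperature fitting, no sensitized-emission FRET, no
  chaperone or elongation kinetics — all outside the measurement model
  this package implements.

## A minimal session

```{r example, eval = FALSE}
wt  <- condition_key("WT", probe_site = 487, truncation = 654)
mut <- condition_key("A455E", probe_site = 487, truncation = 654)
profile_for <- function(key) {
  sets <- simulate_experiment_series(key, n = 4, seed = 1)
  aggregate_profile(dplyr::bind_rows(lapply(sets, compute_experiment_fret)))
}
compare_conditions(profile_for(wt), profile_for(mut))
```
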