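---
title: "Heavy-water flux proteomics with midaflux: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-water flux proteomics with midaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midaflux)
```

## The measurement and the model

In vivo heavy-water labeling raises the deuterium enrichment of body
water to a constant level *p* (typically ~5%) for a labeling window of a
few days. Any protein molecule synthesized during that window draws
hydrogen for a subset of its C–H positions from the enriched body-water
pool, while pre-existing molecules carry only natural deuterium
(~0.0115%). LC-MS resolves each tryptic peptide into its mass-isotopomer
envelope M0, M1, M2, ... — the relative abundances of molecules shifted
by 0, 1, 2, ... nominal mass units from the all-light species.

`midaflux` implements the combinatorial (MIDA) model connecting the two:

1. **Elemental composition.** A peptide's formula is the sum of its
   residue formulas plus one water (`composition_from_sequence()`).
2. **Incorporation sites.** Each residue contributes an empirically
   determined effective number of C–H positions that equilibrate with
   body water during synthesis; the peptide total *n* is their sum
   (`exchangeable_site_count()`). The shipped per-residue table is the
   field-standard one (e.g. alanine 4.00, glycine 2.06, leucine 0.60);
   because published values vary, the table is an explicit input and can
   be replaced by any file via `read_site_table()`.
3. **Theoretical envelopes.** `theoretical_envelope()` convolves the
   natural-abundance isotope distributions of C, H, N, O and S with a
   binomial distribution over the *n* labeled sites at enrichment
   `p_sites`. With `p_sites` at natural abundance this is the *baseline*
   (unlabeled) envelope; at body-water enrichment it is the *asymptote* —
   the envelope a 100% newly synthesized pool would show.
4. **Mixture inversion.** A partially renewed pool is the linear mixture
   `(1 - f) * baseline + f * asymptote`. Writing EM0 for the excess M0
   (measured minus baseline) and EM0max for its asymptotic value, the
   fractional synthesis over the window is exactly `f = EM0 / EM0max`
   (`fractional_synthesis()`). `f` is cumulative (fraction of the pool
   renewed); with first-order turnover the rate constant is
   `k = -log(1 - f) / t`.

Fitting uses M0 only. The M1–M3 channels enter through the truncation
convention: all envelopes (measured, baseline, asymptote) are truncated
to M0–M3 and renormalized identically before the EM0 arithmetic, so the
three M0 values live on the same scale. The all-light channel carries the
strongest and cleanest labeling signal; an M0-only estimator is unbiased
for the mixture model and keeps the estimate independent of how the
higher isotopomers are apportioned.

Numerical notes: envelope convolutions are exact on the leading four
terms (convolution is causal, so truncation introduces no error in
M0..M3); element powers use exponentiation by squaring; a non-integer
site count *n* is handled by linear interpolation between the envelopes
at `floor(n)` and `ceiling(n)`, which preserves the closed form
`M0_labeled / M0_baseline = ((1 - p) / (1 - p_nat))^n` at integers and
continuity in between. Charge is metadata only — label incorporation is
charge-independent, so envelopes are treated in neutral isotopomer space.

Estimates of `f` outside [0, 1] are *retained and flagged*, never
clipped: values in [-0.05, 1.2] are flagged `minor_excursion`, values
beyond that `out_of_bounds` (excluded from protein roll-up). Silent
clipping would bias group means toward the interior.

## From peptides to proteome statistics

`compute_peptide_fsr()` applies the model to a peptide table using each
sample's own body-water enrichment from the metadata. `protein_fsr()`
collapses peptides to one FSR per protein per sample; the default is a
spectral-count-weighted mean (more spectra, more weight), switchable to
an unweighted mean or median. `filter_min_spectra()` then applies the
inclusion rule that a protein measurement must rest on at least two
peptide spectra; the rule runs per sample by default, with a
`scope = "study"` switch.

Group comparisons mirror the analysis style of proteome-wide
calorie-restriction (CR) flux studies:

* `group_summary()` gives per-protein mean, sample SD and percent CV
  across replicate animals per arm and day. A CV is undefined (NA) with
  fewer than two animals or a non-positive mean.
* `paired_log2fc()` pairs proteins present in both arms and computes
  `log2(mean_treated / mean_control)`; Up/Down/Tie classification and
  the percent change `(2^log2fc - 1) * 100` follow.
* `average_cv_threshold()` pools all defined CVs of both arms into one
  unweighted mean; `classify_flux_change()` marks a protein "above the
  cutoff" when its absolute percent change exceeds that average CV. CVs
  are computed within each arm and pooled only at the threshold step.
* `flux_proportions()` tallies Down vs Up (ties reported separately,
  excluded from the test) and computes an exact two-tailed binomial
  p-value. The default two-tailed convention doubles the smaller tail
  and caps at 1 — the "coin toss" convention — with a `minlik` switch
  that reproduces `stats::binom.test()`.
* `arm_contrast()` compares Down proportions between two treated arms
  with an exact two-tailed Fisher test on the (Down, not-Down) × arm
  table, summing hypergeometric point probabilities no larger than the
  observed table's.
* `zscore_by_timepoint()` standardizes FSRs at one time point; pooling
  Con and treated values before standardization is the default, since
  positioning "relative to the mean of the group" admits either reading
  and pooled scores keep the two arms on one scale.
* `timecourse_summary()` expresses per-day Down percentages relative to
  a reference day on the log2 scale. Both `log2` and `-log2` columns are
  emitted because the orientation convention differs between
  publications. Transition timing is estimated by a 4-parameter logistic
  fit (Levenberg–Marquardt on raw residuals, which tolerates nearly
  step-like series) plus a simpler first-day-above-threshold crossing
  (default 70%). The logistic fit needs at least five time points.

No multiple-testing correction is applied across proteins in this layer;
the binomial and Fisher tests are proteome-level summaries, not
per-protein hypothesis tests.

`wpasr()` and `normalize_wpasr_matrix()` implement within-proteome
absolute synthesis rates: each protein's FSR times its normalized
label-free intensity quotient Q within the sample, then median
adjustment per sample, log10, and per-protein mean centering. Zero or
negative intensities are masked, not imputed.

`match_and_orient()` and `concordance_test()` reproduce the
flux-vs-transcription comparison: an inner join of protein FSR fold
changes with an externally computed gene-level differential-expression
table (directions from the sign of its log2FC; zero fold changes and
ambiguous many-to-many mappings excluded), followed by the same exact
binomial test on concordant vs discordant directions. No significance
filter is applied to the DE table by default.

`dnl_fraction()` applies the identical polymerization/mixture machinery
to palmitate (C16H32O2): the fractional contribution of de novo
lipogenesis over the label period. The effective site count defaults to
22, the field-standard effective value for palmitate synthesized from
acetyl-CoA at ~5% body-water enrichment; it is exposed because
protocols differ and the value is rarely printed. Precursor enrichment
is taken from measured body water, not re-estimated from isotopomer
ratios.

## What the synthetic generator emulates — and what it does not

`simulation_design()` + `effect_model()` + `simulate_study()` generate
complete studies with the statistical structure the analysis assumes:

* per-protein baseline FSRs log-normal(log 0.35, 0.5), clamped to
  (0.005, 0.95) — a realistic spread for 4-day cumulative fractional
  synthesis in liver, where most proteins renew a substantial fraction
  of their pool within days;
* a logistic CR slowdown in study day: multiplier 1 →
  `cr_multiplier_late` (default 0.7) with midpoint 27.5 d and time
  scale 1 d. The study the package models brackets a rapid transition
  between days 25 and 30 without stating a functional form or an effect
  size; the logistic midpoint at the bracket center and a 30% late
  slowdown are documented free choices that reproduce the *prevalence*
  pattern (roughly half of proteins down before day 25, the large
  majority down after day 30), which is what the downstream statistics
  consume;
* arm multipliers for iNOS-deficient animals: `no_multiplier` 1.3
  (faster turnover without NO) and `no_cr_multiplier` 0.95 (the CR
  slowing largely abolished when NO is absent);
* replicate animals (default 4 per arm per day, within the usual
  n = 3–5) with mean-one log-normal jitter (sd 0.1) as biological
  variation;
* measurement noise as multinomial sampling of each truncated envelope
  at an ion-count depth (default 10^4), plus geometric spectral counts
  and optional Bernoulli peptide dropout;
* tryptic-looking random peptides (8–18 residues, C-terminal K/R,
  residues drawn at natural frequencies).

All randomness flows from one master seed through named streams, so any
component regenerates identically in isolation, and the generators
restore the caller's RNG state.

The generator deliberately does **not** emulate chromatography, charge
states, co-elution, peptide misassignment, protein inference from
shared peptides, or structured missingness. Passing tests therefore
demonstrate that the *computational* pipeline is correct and calibrated
under the model's own assumptions — not that those assumptions hold for
any particular instrument or cohort.

## Problem sizes and calibration checks

The test suite exercises, among others:

* envelope correctness against an independent atom-by-atom enumeration
  oracle for short peptides, and the closed-form M0 ratio over a grid
  of enrichments and site counts;
* exact recovery of mixture fractions end-to-end at noise-free
  (analytic) envelopes;
* recovery of true protein FSRs under multinomial noise at 200
  proteins, 4 animals/arm and 10^4 ions per envelope — bias below
  0.005, RMSE below 0.02;
* agreement of the binomial test with exhaustive 2^n enumeration
  (n ≤ 12) and of the Fisher test with full hypergeometric enumeration
  (margins ≤ 15);
* type-I calibration of the proteome-wide binomial layer over 1,000
  null studies;
* reproduction of the CR time-course pattern (percent-down near 50%
  before day 25, above 70% from day 30, logistic midpoint inside
  [25, 30]).

One sizing choice deserves a note. Before the transition, each
protein's Down call is an exchangeable fair coin, so the per-day
percent-down carries an irreducible binomial floor of
`100 * sqrt(0.25 / n_proteins)` percentage points. At 200 proteins that
floor (±3.5 points) makes a 45–65% acceptance band unreliable as a
*joint* condition over several pre-transition days; the qualitative
pattern check therefore runs at 1,000 proteins, where the band is more
than three standard deviations wide on every day and the check reflects
the generator's structure rather than coin-flip luck. The bias/RMSE
recovery check keeps the 200-protein, 4-animal scale, which is the
realistic cohort size.

## Known limitations

* The exchangeable-site table and the palmitate site count are
  literature defaults, not study-calibrated values; absolute FSRs shift
  (roughly proportionally in EM0max) if they are changed, though
  paired comparisons between arms are insensitive to modest rescaling.
* The baseline envelope is theoretical by default; a measured
  unlabeled-animal envelope can be substituted per peptide where
  systematic instrument effects on M0 matter.
* The M0-only estimator discards some information in M1–M3; a full
  envelope fit would gain precision at high enrichment but needs an
  error model for the higher channels.
* Fixed carbamidomethyl-cysteine is supported as a composition offset;
  other modifications are out of scope.
* Group summaries assume one sample per animal per day; repeated
  measures within an animal are not modeled.
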