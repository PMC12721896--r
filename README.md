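# midaflux

Heavy-water flux proteomics in R: from peptide mass-isotopomer envelopes
to protein fractional synthesis rates (FSRs) and proteome-wide turnover
statistics.

## The problem

In vivo ²H₂O labeling holds body-water deuterium at an enrichment *p*
(~5%) for a few days. Proteins synthesized during the window incorporate
deuterium at *n* effective C–H positions per peptide, depleting the
monoisotopic (M0) peak of each tryptic peptide's isotope envelope in a
predictable way. Mass isotopomer distribution analysis (MIDA) turns that
depletion into the fraction *f* of the protein pool newly synthesized
over the window:

```
f = EM0 / EM0max
EM0    = M0(measured)  − M0(baseline)
EM0max = M0(asymptote) − M0(baseline)
M0(labeled) / M0(baseline) = ((1 − p) / (1 − p_nat))^n   (integer n)
```

where the baseline envelope is the peptide at natural abundance and the
asymptote is the envelope a 100% newly synthesized pool would show at
body-water enrichment *p*. Envelopes are assessed in the M0–M3 window;
the measured envelope is the linear mixture `(1 − f)·baseline +
f·asymptote`, so *f* is exact for noise-free data.

On top of the kinetic core, the package provides the comparison
machinery used in proteome-wide calorie-restriction (CR) studies:
protein-level roll-up with a minimum-spectra filter, per-arm CV
summaries, paired log₂ fold changes with an averaged-CV stringency
cutoff, exact two-tailed binomial and Fisher tests, time-course
transition detection (4-parameter logistic), within-proteome absolute
synthesis rates (WPASR), fractional de novo lipogenesis of palmitate,
protein-flux vs mRNA concordance — and a fully seeded synthetic-study
generator so every stage is testable without raw LC-MS data.

Audience: researchers analyzing stable-isotope protein-turnover
experiments, and methodologists who need a transparent, tested
implementation of the MIDA mixture model and its downstream statistics.

## Worked example

Simulate a small CR cohort (50 proteins, 4 animals/arm, days 0–31),
estimate protein FSRs, and test the day-31 CR-vs-control contrast:

```r
library(midaflux)

design <- simulation_design(n_proteins = 50, days = c(0, 20, 27, 31),
                            seed = 42)
study <- simulate_study(design)

pk   <- compute_peptide_fsr(study$peptides, study$metadata)
prot <- filter_min_spectra(protein_fsr(pk))
head(prot, 3)
#>   protein_id sample_id       fsr n_peptides n_spectra qc_flag
#> 1      P0001 Con_d0_a1 0.1754514          3         4      ok
#> 2      P0002 Con_d0_a1 0.4417350          4        17      ok
#> 3      P0003 Con_d0_a1 0.2375664          3         6      ok

gs  <- group_summary(prot, study$metadata)
con <- gs[gs$arm == "Con" & gs$day == 31, ]
cr  <- gs[gs$arm == "CR"  & gs$day == 31, ]
thr <- average_cv_threshold(con$cv, cr$cv)   # pooled mean CV: 10.4%
cmp <- classify_flux_change(paired_log2fc(con, cr), thr)
str(flux_proportions(cmp))
#> List of 11
#>  $ n_down           : int 50
#>  $ n_up             : int 0
#>  ...
#>  $ pct_down         : num 100
#>  $ p_binomial       : num 1.78e-15
#>  $ n_down_above_cv  : int 50
```

By day 31 every one of the 50 proteins runs slower under CR (binomial
p ≈ 2·10⁻¹⁵), and all of the changes exceed the averaged-CV cutoff
(10.4%). The same per-day tally shows the transition the generator
injects near day 27.5:

```r
#>   day pct_down
#> 1   0       46
#> 2  20       50
#> 3  27       88
#> 4  31      100
```

Percent-down hovers at chance (46–50%) before the transition and
saturates after it; `timecourse_summary()` fits the logistic midpoint.

The kinetic core is directly inspectable. For one myoglobin peptide at
5% body water (n = 24.09 effective sites):

```r
ctx <- labeling_context(p_body = 0.05, t_label = 4)
env <- peptide_envelopes("GLSDGEWQLVLNVWGK", ctx)
round(env$baseline, 4)   # M0 0.3636, M1 0.3629, M2 0.1972, M3 0.0763
round(env$asymptote, 4)  # M0 0.1283, M1 0.2904, M2 0.3300, M3 0.2512
```

A measured envelope between those two extremes maps linearly onto
`f ∈ [0, 1]`.

A thin command-line wrapper over the same functions lives at
`inst/scripts/midaflux.R` (subcommands `simulate`, `fsr`, `compare`,
`timecourse`, `concordance`, `dnl`).

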