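# nucleoclock

Nucleosome-level aging signatures from cell-free DNA (cfDNA)
fragmentomics.

Plasma cfDNA consists mostly of nucleosome-protected fragments, so the
positions and sizes of aligned cfDNA fragments carry a genome-wide
snapshot of a person's chromatin organisation. `nucleoclock` implements
the analysis chain that turns aligned cfDNA fragments (BED) into
nucleosome-level aging readouts:

- **Fragment-size distributions** and mono-/di-/tri-nucleosome fragment
  proportions (~167 bp chromatosome peak, ~330 bp di-, ~500 bp
  tri-nucleosome fragments).
- **Phasograms** — histograms of pairwise distances `d = c_j − c_i`
  between fragment centres on the same chromosome.  Nucleosome phasing
  makes the phasogram oscillate with period equal to the **nucleosome
  repeat length (NRL)**; the NRL is estimated as the OLS slope of
  phasogram peak position against peak order,
  `position_k = intercept + NRL · k`, after Savitzky–Golay smoothing,
  prominence-based peak detection and spectral peak-order assignment.
- **Differential occupancy and PCA stratification** — 100-bp binned,
  fragments-per-million-normalised occupancy tracks; per-bin Welch
  tests with Benjamini–Hochberg FDR control select regions that gain or
  lose occupancy between age groups; PCA over those regions separates
  age groups, and held-out samples are projected with frozen
  standardisation and loadings.
- **Aging clocks** — linear age predictors on either the fragment-size
  frequency vector (501 features over 100–600 bp) or the smoothed
  normalised phasogram (distances 120–2,000 bp).  The default model is
  principal-component regression (top-*k* training-set components, OLS
  on the scores — still linear in the original features); ridge on raw
  features is available.  The same clock scores an age-group classifier
  (age > 55 years) evaluated with a tie-corrected rank (Mann–Whitney)
  AUC.
- **A synthetic cohort simulator** that draws cfDNA fragments around a
  jittered nucleosome-dyad lattice whose spacing (NRL) and
  mono/di/tri-fragment mixture drift with subject age, with optional
  planted differential-occupancy bins.  Every downstream stage can
  therefore be validated against known ground truth.

Real cfDNA cohorts of the kind this pipeline targets are controlled-
access; the package is fully testable without them via the simulator.

## Worked example

```r
library(nucleoclock)

## a 12-person cohort, three age groups, age-linked NRL drift
spec   <- cohort_spec(n_subjects = 12, genome_length = 2.5e6,
                      n_fragments_per_subject = 5e4, seed = 42)
cohort <- generate_cohort(spec, ages = rep(c(25, 70, 100), each = 4))

fs <- cohort$samples[[1]]          # or read_fragments("sample.bed")
fs
#> fragment_set 'S001': 50000 fragments on 1 chromosome(s)

sample_nrl(fs)                     # phasogram -> peaks -> OLS slope
#> NRL estimate: 185.82 bp (SE 0.055, R^2 1.0000, 10 peaks)
attr(fs, "true_nrl")
#> [1] 185.7886

tab <- nrl_cohort_table(cohort$samples,
                        group = rep(c("25", "70", "100"), each = 4))
attr(tab, "group_stats")
#>  group n     mean   median        var
#>    100 4 187.2135 187.1554 0.04717830
#>     25 4 185.6246 185.6091 0.02082552
#>     70 4 186.3995 186.4500 0.05968084

st <- nrl_age_stats(tab$nrl, cohort$meta$age)
sprintf("Pearson r = %.2f, p = %.2g", st$pearson_r, st$p_value)
#> "Pearson r = 0.96, p = 1.2e-06"
```

The per-sample estimate tracks the generative truth to ~0.05 bp, the
group means reproduce the planted ~1.6 bp spread between 25-year-olds
and centenarians, and NRL correlates positively with age across the
cohort.

For clocks, build a feature matrix and train on an 80/20 age-stratified
split:

```r
f <- build_features(cohort$samples, "size_dist")
m <- train_clock(f, cohort$meta$age, k = 5, seed = 1)
predict(m, f)          # predicted ages, years
```

A command-line wrapper with `simulate | sizes | phasogram | nrl |
diffbins | train | classify` subcommands lives in
`inst/cli/nucleoclock.R`.

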