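---
title: "Methods: cfDNA nucleosomics and the aging clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA nucleosomics and the aging clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleoclock)
```

## Scope and data model

`nucleoclock` starts from aligned paired-end cfDNA fragments in BED
convention (0-based, half-open).  A fragment's size is `end − start`
and its centre is `floor((start + end) / 2)`; the floor makes centres
deterministic integers, and because every fragment is shifted the same
way the convention cancels out of all pairwise-distance statistics.
Alignment, duplicate marking and mappability filtering are upstream
concerns: the package consumes fragment coordinates, never reads.

The default fragment-size window is 100–600 bp.  The lower edge
excludes sub-nucleosomal degradation products; the upper edge retains
tri-nucleosome fragments (~500 bp), which carry part of the age signal.
The window is exposed as configuration everywhere because no single
window suits all library preparations.

## Phasograms and NRL estimation

The phasogram counts ordered pairs of fragment centres on the same
chromosome at each distance 0–`d_max` (default 2,000 bp), pooled over
chromosomes.  It is computed with a sorted sliding window
(`findInterval` on the sorted centres), so cost scales with the number
of pairs actually within `d_max` rather than all pairs; a brute-force
all-pairs oracle in the test suite confirms exact equality.

Nucleosome phasing makes the normalised phasogram oscillate with the
inter-nucleosome spacing.  The NRL estimator proceeds as:

1. **Smoothing.** Savitzky–Golay, window 51 bp, polynomial order 3,
   applied once to the normalised counts.  A local polynomial filter is
   used because, unlike a moving average, it preserves peak positions;
   window 51 suppresses counting noise while remaining well under the
   ~95 bp half-period of typical phasograms.
2. **Peak detection.** Local maxima at distances ≥ `d_min_fit`
   (default 120 bp — below that the zero-lag/self-overlap shoulder of
   the phasogram dominates) with prominence at least 2% of the
   smoothed-signal range.  Peak positions are refined to sub-bp
   precision by a parabola through the three samples around each
   maximum.
3. **Order assignment.** A coarse period is taken as the dominant
   spectral component of the smoothed signal on 120–260 bp (the
   plausible NRL band), and each peak gets `k = round(position /
   period)`.  Peaks more than a quarter period from an integer multiple
   are dropped: di-nucleosome fragment centres sit mid-way between two
   dyads and generate genuine half-period harmonics that would
   otherwise be mislabelled.  Missing harmonics simply leave gaps in
   `k`; duplicate `k` keeps the more prominent peak.  Orders above 10
   are not used.
4. **Regression.** OLS of position on `k`.  The slope is the NRL; the
   intercept absorbs any constant linker/footprint offset.  Estimates
   with R² < 0.95, slope SE > 2 bp or slope outside 120–260 bp are
   flagged unreliable rather than discarded, mirroring the
   coverage-based quality control used with real cohorts, and cohort
   tables isolate per-sample failures as flagged rows.

With the default simulator noise (dyad jitter 20 bp) and 2×10⁵
fragments on a 10-Mb chromosome, the estimator recovers true NRLs of
175/185/195 bp within ±0.2 bp with |mean bias| well under 0.3 bp.

## The synthetic cohort simulator

No public fragment-level aging cohort can ship with the package, so the
simulator provides ground truth.  For a subject of age `a`:

- True NRL = `beta0 + beta1·a + N(0, sigma_subject)`, defaults
  `beta0 = 185` bp, `beta1 = 0.02` bp/year, `sigma_subject = 0.3` bp.
  These magnitudes place adult NRLs at ~186–187 bp and give a ~1.5 bp
  spread between ages 25 and 100, consistent with chromatosome-scale
  biology and the small, positive age trends reported for cfDNA
  cohorts.
- A dyad lattice spans one synthetic chromosome `chrS` (default 20 Mb)
  at the subject's NRL with a uniform random phase.  **Jitter is drawn
  per fragment, not per subject**: plasma cfDNA pools millions of
  cells, each with its own realisation of nucleosome positions around
  the preferred lattice, so two fragments from the same dyad index are
  not positionally identical.  This choice leaves phasogram statistics
  unchanged (inter-dyad distances still have SD `√2 ·
  dyad_jitter_sd`) but makes binned coverage sampling-limited rather
  than dominated by a single frozen lattice — without it, per-bin
  occupancy variance across subjects is an artefact of one lattice
  draw per subject rather than a property of cfDNA-like data.
- Each fragment is mono- (centred on one dyad, length
  `N(167, 15)` bp), di- (spanning two adjacent dyads, ~NRL + 167 bp) or
  tri-nucleosomal, with age-linked weights: raw weights
  `(0.60, 0.28, 0.12)` at age 0 drift by `(0, −0.002, −0.001)` per
  year and are renormalised, so di+tri protection declines from ~35%
  at age 25 to ~10% at age 100 — a deliberately strong, clean encoding
  of the loss of multi-nucleosome protection with age.
- Optional planted differential bins: fragments touching a designated
  100-bp bin are over-sampled by a factor interpolating linearly from
  1 at the youngest age to `diff_factor_hi` at the oldest
  (rejection-sampled, so exactly `n_fragments_per_subject` fragments
  are emitted).
- Per-subject RNG substreams are derived from the cohort seed and the
  subject index, so cohorts are reproducible and order-independent.

What the simulator does **not** emulate: genome sequence (no GC or
mappability bias), chromatin-state heterogeneity of the NRL, fragment
end biases, between-individual occupancy landscapes beyond the planted
bins, or any disease signal.  Passing tests therefore demonstrate that
the estimators recover the quantities they claim to measure under
controlled conditions — not that real cohorts carry signals of these
effect sizes.

## Differential occupancy and PCA

Occupancy tracks count, per 100-bp bin anchored at coordinate 0, the
fragments overlapping the bin, scaled to fragments-per-million so
sequencing depth cancels (duplicating every fragment leaves the track
unchanged).  Between two groups, each non-empty bin is tested with a
two-sample Welch *t*-test on the normalised values and
Benjamini–Hochberg FDR control at `alpha = 0.05`, keeping bins with the
requested direction; a Wilcoxon option exists for ≥ 4 samples per
group, and groups with a single sample fall back to flagged fold-change
ranking with no significance claim.  The exact test and threshold are
declared configuration, not canonical choices.

PCA standardises each selected region to mean 0, SD 1 **across the
discovery samples only** and eigendecomposes; held-out samples are
projected using the frozen discovery means/SDs and loadings, never
refit — projecting a discovery sample reproduces its score exactly.
Fragments extending past a planted bin elevate neighbouring bins, so
discovery sets typically include a halo of adjacent bins around each
planted one; this is faithful spillover, not false discovery, and null
cohorts show BH-controlled discovery fractions.

Occupancy-focused simulations use dyad jitter ≈ NRL/2 (95 bp) and an
age-constant mixture: with the lattice blurred to effectively uniform
placement, per-bin variance is sampling-limited and the planted
sampling-rate effect is the only group difference.  Tight-jitter
lattices would instead make a bin's baseline coverage depend on where
the subject's lattice phase happens to fall — legitimate biology for
phasograms, but a confounder the 100-bp occupancy contrast is not
designed to remove.

## Aging clocks

Feature kinds: the 501-bin fragment-size frequency vector (rows sum to
1) or the smoothed normalised phasogram on 120–2,000 bp.  With
hundreds of features and tens of samples a plain multiple regression is
underdetermined, so the default clock is principal-component
regression: standardise features on the training split (per-feature
mean/SD; constant features are left centred), project onto the top-`k`
training-set components (default `k = 10`, requiring `k ≤ n_train − 2`),
and fit OLS on the scores — a linear model in the original features.
Ridge regression on raw standardised features (glmnet, deterministic
fold assignment) is the alternative mode.

The 80/20 train/test split is seeded and stratified by age tertile so
small test sets still span the age range.  Standardisation, loadings
and coefficients come from training rows only; removing a test sample
changes nothing fitted (verified as an invariant).  Metrics are
Pearson *r* between predicted and chronological age, MSE and median
absolute error, all on the untouched test rows.  The age-group
classifier (> 55 years) scores test samples with the clock's predicted
age (or an optional logistic model on the projected features) and
reports the tie-corrected rank AUC, which equals the ROC integral.

On the default 80-subject synthetic cohort both feature kinds reach
test *r* ≈ 0.99 with MedAE ≈ 1–2 years — far cleaner than any real
cohort, as expected given the simulator's strong drift and absence of
biological nuisance variation; permuting ages before training drives
test *r* to ~0 and AUC to ~0.5.

## Numerical choices and degenerate inputs

- Centre ties break downward (floor); bins are half-open
  `[i·100, (i+1)·100)` anchored at 0.
- Phasogram pair expansion is chunked (~5×10⁶ pairs per block) to
  bound memory; counts are exact integers.
- Fewer than 2 fragments gives a zero phasogram with a warning; fewer
  than 3 usable peaks is an error ("insufficient peaks"); a flat
  signal has no peaks by construction.
- Zero-variance NRL or age vectors make the Pearson test an error;
  zero-variance predictions flag the metric object as degenerate
  rather than returning NaN.
- Empty BED files warn and return empty sets; malformed lines are hard
  errors naming the line number.
- All-zero samples project to finite PCA scores (standardised zeros).

## Problem sizes used by the test and acceptance runs

Chosen once to keep the full suite within a desktop-scale run while
leaving comfortable statistical margins, and not revisited:
single-subject NRL recovery uses 2×10⁵ fragments on 10 Mb; the
60-subject trend cohorts use 5×10⁴ fragments on 2.5 Mb (estimator SD
≈ 0.15 bp, small against the ~0.5 bp cohort NRL spread); occupancy
runs use 5,000 bins of 100 bp with 2×10⁵ fragments per subject
(discovery) or 2×10⁴ (null calibration); clock cohorts use 80
subjects at 5×10⁴ fragments.  The acceptance script mirrors these
sizes and completes in well under a minute per stage.

## Known limitations

- The NRL is genome-wide; chromatin-state- or region-resolved NRLs are
  out of scope.
- The simulator's age links are linear by construction; the clocks are
  validated for recovery, not for functional form discovery.
- Sub-nucleosomal fragmentomics (< 100 bp) and the 10.4-bp helical
  periodicity are not modelled or analysed.
- Real-genome artefact masking (blacklists, mappability) must happen
  upstream.
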