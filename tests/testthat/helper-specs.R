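## Shared simulator configurations for the test suite.
##
## NRL-focused runs use the default tight dyad jitter (20 bp) so the
## phasogram carries strong periodicity; occupancy-focused runs blur the
## lattice (jitter ~ NRL/2) and freeze the fragment mixture so per-bin
## coverage noise is sampling-limited and the planted effect is the only
## group difference.

nrl_subject_spec <- function(nrl, seed, n_frag = 2e5, genome = 1e7) {
  cohort_spec(genome_length = genome, n_fragments_per_subject = n_frag,
              nrl_beta0 = nrl, nrl_beta1 = 0, nrl_sigma = 0, seed = seed)
}

trend_cohort_spec <- function(seed, n_subjects = 60, beta1 = 0.02,
                              sigma = 0.3) {
  cohort_spec(n_subjects = n_subjects, genome_length = 2.5e6,
              n_fragments_per_subject = 5e4, nrl_beta1 = beta1,
              nrl_sigma = sigma, seed = seed)
}

occupancy_spec <- function(seed, planted = NULL, factor_hi = 2,
                           n_frag = 2e5, genome = 5e5) {
  cohort_spec(n_subjects = 10, age_range = c(25, 100),
              genome_length = genome, n_fragments_per_subject = n_frag,
              dyad_jitter_sd = 95, mix_slope = c(0, 0, 0),
              diff_bins = planted, diff_factor_hi = factor_hi,
              seed = seed)
}

clock_cohort_spec <- function(seed, n_subjects = 80) {
  cohort_spec(n_subjects = n_subjects, genome_length = 2.5e6,
              n_fragments_per_subject = 5e4, seed = seed)
}

## A fragment_set with prescribed centres (unit-ish fragments).
fs_from_centres <- function(centres, chrom = "chr1", id = "toy") {
  fragment_set(rep(chrom, length(centres)), centres, centres + 1, id)
}

## O(n^2) all-pairs phasogram oracle.
brute_phasogram <- function(fs, d_max) {
  counts <- numeric(d_max + 1)
  for (ch in fs$chroms) {
    cc <- ch$centre
    n <- length(cc)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      dd <- cc[(i + 1):n] - cc[i]
      dd <- dd[dd <= d_max]
      for (d in dd) counts[d + 1] <- counts[d + 1] + 1
    }
  }
  counts
}

## Build a phasogram object directly from a signal (for peak-detection
## tests where the smoothed curve is prescribed exactly).
phasogram_from_signal <- function(smoothed, counts = NULL) {
  d <- seq_along(smoothed) - 1
  if (is.null(counts)) counts <- rep(1, length(d))
  structure(list(d = d, counts = counts, n_pairs = sum(counts),
                 norm = counts / sum(counts), smoothed = smoothed,
                 sample_id = "synthetic"),
            class = "phasogram")
}

## Run code under a temporary seed without disturbing the test RNG.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
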