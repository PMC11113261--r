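## Synthetic cfDNA cohort simulator.
##
## Fragments are drawn around a jittered nucleosome-dyad lattice on a
## single synthetic chromosome.  Each subject has a true nucleosome repeat
## length (NRL) linked linearly to age, and a mono/di/tri-nucleosome
## fragment mixture whose di- and tri-nucleosome weights decline linearly
## with age, mimicking the loss of multi-nucleosome protection observed in
## older subjects.  Optional "differential" 100-bp bins are over-sampled by
## an age-dependent factor to plant a recoverable occupancy signal.

#' Specify a synthetic cfDNA cohort
#'
#' @param n_subjects number of subjects.
#' @param age_range ages are drawn uniformly from `[age_range[1],
#'   age_range[2]]` years.
#' @param genome_length length of the single synthetic chromosome
#'   (`"chrS"`), bp.
#' @param nrl_beta0 subject NRL intercept at age 0, bp.
#' @param nrl_beta1 NRL change per year of age, bp/year.
#' @param nrl_sigma subject-level NRL noise SD, bp.
#' @param dyad_jitter_sd SD of the independent Gaussian jitter applied to
#'   each dyad around the ideal lattice, bp.
#' @param mu_mono,sd_len mean mono-nucleosome fragment length and the
#'   fragment-length SD, bp.  Di-/tri-nucleosome fragments span two/three
#'   adjacent dyads and so have mean length `true_nrl + mu_mono` /
#'   `2 * true_nrl + mu_mono`.
#' @param mix0 numeric length-3: mono/di/tri mixture weights at age 0
#'   (will be renormalised).
#' @param mix_slope numeric length-3: per-year additive drift of each raw
#'   weight before renormalisation.  Weights must stay non-negative over
#'   the whole age range.
#' @param n_fragments_per_subject fragments emitted per subject (exact).
#' @param diff_bins optional integer vector of 100-bp bin indices
#'   (0-based) whose sampling rate is scaled by an age-dependent factor.
#' @param diff_bin_size bin width for `diff_bins`, bp.
#' @param diff_factor_hi sampling-rate multiplier of `diff_bins` at
#'   `age_range[2]`; it interpolates linearly from 1 at `age_range[1]`.
#' @param seed integer master seed; per-subject substreams are derived
#'   from it so cohorts are reproducible and order-independent.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, age_range = c(25, 100),
                        genome_length = 2e7,
                        nrl_beta0 = 185, nrl_beta1 = 0.02, nrl_sigma = 0.3,
                        dyad_jitter_sd = 20, mu_mono = 167, sd_len = 15,
                        mix0 = c(0.60, 0.28, 0.12),
                        mix_slope = c(0, -0.002, -0.001),
                        n_fragments_per_subject = 2e5,
                        diff_bins = NULL, diff_bin_size = 100,
                        diff_factor_hi = 1, seed = 1L) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[2] >= age_range[1], age_range[1] >= 0,
            length(mix0) == 3, length(mix_slope) == 3,
            n_fragments_per_subject >= 1, diff_factor_hi > 0)
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    genome_length = genome_length, nrl_beta0 = nrl_beta0,
    nrl_beta1 = nrl_beta1, nrl_sigma = nrl_sigma,
    dyad_jitter_sd = dyad_jitter_sd, mu_mono = mu_mono, sd_len = sd_len,
    mix0 = mix0, mix_slope = mix_slope,
    n_fragments_per_subject = as.integer(n_fragments_per_subject),
    diff_bins = diff_bins, diff_bin_size = diff_bin_size,
    diff_factor_hi = diff_factor_hi, seed = as.integer(seed)),
    class = "cohort_spec")
  ## raw weights are linear in age, so endpoint checks cover the range
  for (a in age_range) {
    if (any(mix0 + mix_slope * a < -1e-12))
      stop("mixture weights negative at age ", a,
           "; adjust mix0/mix_slope")
  }
  nrl_hi <- nrl_beta0 + nrl_beta1 * age_range[2]
  if (nrl_hi < 140 || nrl_hi > 260)
    stop("NRL at the top of the age range (", round(nrl_hi, 1),
         " bp) is outside the plausible [140, 260] bp band")
  if (genome_length < 100 * nrl_hi)
    stop("genome_length must be at least 100 NRLs")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort_spec: %d subjects, ages U[%g, %g], genome %g bp\n",
    "  NRL = %g + %g * age + N(0, %g) bp; jitter %g bp\n",
    "  fragments/subject = %d; mono length N(%g, %g) bp\n"),
    x$n_subjects, x$age_range[1], x$age_range[2], x$genome_length,
    x$nrl_beta0, x$nrl_beta1, x$nrl_sigma, x$dyad_jitter_sd,
    x$n_fragments_per_subject, x$mu_mono, x$sd_len))
  invisible(x)
}

#' Mono/di/tri mixture weights at a given age
#' @param spec a `cohort_spec`.
#' @param age age in years.
#' @return length-3 non-negative numeric summing to 1.
#' @export
mixture_weights <- function(spec, age) {
  w <- spec$mix0 + spec$mix_slope * age
  w <- pmax(w, 0)
  s <- sum(w)
  if (s <= 0) stop("all mixture weights zero at age ", age)
  w / s
}

## Age-dependent sampling-rate factor for the planted differential bins.
diff_factor <- function(spec, age) {
  if (is.null(spec$diff_bins) || spec$diff_factor_hi == 1) return(1)
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  t <- if (hi > lo) (age - lo) / (hi - lo) else 1
  1 + (spec$diff_factor_hi - 1) * max(0, min(1, t))
}

#' Simulate one subject's fragments
#'
#' Dyads are placed at `k * true_nrl + N(0, dyad_jitter_sd)` along the
#' synthetic chromosome.  Each emitted fragment picks a dyad and, with the
#' age-dependent mixture probabilities, is centred on that dyad
#' (mono-nucleosome), or spans it and the next dyad (di-), or it and the
#' next two (tri-); fragment length adds `N(0, sd_len)` noise and
#' fragments are clipped to the genome.  Exactly
#' `spec$n_fragments_per_subject` fragments are emitted.
#'
#' @param spec a `cohort_spec`.
#' @param age subject age, years.
#' @param subject_index 1-based index used to derive the subject's RNG
#'   substream from `spec$seed`.
#' @param sample_id sample identifier.
#' @return A `fragment_set` with attributes `true_nrl` (bp) and `age`.
#' @export
generate_subject <- function(spec, age, subject_index = 1L,
                             sample_id = sprintf("S%03d", subject_index)) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, subject_index), {
    true_nrl <- spec$nrl_beta0 + spec$nrl_beta1 * age +
      stats::rnorm(1, 0, spec$nrl_sigma)
    n_dyads <- floor(spec$genome_length / true_nrl)
    ## random lattice phase: the dyad grid origin is arbitrary per subject
    phase <- stats::runif(1, 0, true_nrl)
    n <- spec$n_fragments_per_subject
    w <- mixture_weights(spec, age)
    ## dyad jitter is drawn per fragment: cfDNA pools many cells, each
    ## with its own realisation of nucleosome positions around the
    ## preferred lattice, so fragments sharing a dyad index are not
    ## positionally identical
    draw <- function(m) {
      i0 <- sample.int(n_dyads, m, replace = TRUE)
      kind <- sample.int(3L, m, replace = TRUE, prob = w)
      ## spanning fragments need kind-1 dyads downstream; clamp at the end
      i0 <- pmin(i0, n_dyads - (kind - 1L))
      left <- phase + (i0 - 1L) * true_nrl +
        stats::rnorm(m, 0, spec$dyad_jitter_sd)
      right <- ifelse(kind == 1L, left,
                      phase + (i0 + kind - 2L) * true_nrl +
                        stats::rnorm(m, 0, spec$dyad_jitter_sd))
      centre <- (left + right) / 2
      len <- (kind - 1L) * true_nrl + spec$mu_mono +
        stats::rnorm(m, 0, spec$sd_len)
      len <- round(pmax(len, 30))
      start <- pmax(floor(centre - len / 2), 0)
      end <- pmax(pmin(start + len, spec$genome_length), start + 1)
      cbind(start, end)
    }
    f <- diff_factor(spec, age)
    if (!is.null(spec$diff_bins) && f != 1) {
      ## planted signal: a fragment touching a planted bin is sampled at
      ## rate f(age); rejection sampling keeps exactly n fragments
      is_hot <- function(se) {
        b0 <- se[, 1] %/% spec$diff_bin_size
        b1 <- (se[, 2] - 1) %/% spec$diff_bin_size
        hot <- logical(nrow(se))
        for (off in 0:max(b1 - b0))
          hot <- hot | (pmin(b0 + off, b1) %in% spec$diff_bins)
        hot
      }
      acc <- matrix(numeric(0), 0, 2)
      while (nrow(acc) < n) {
        se <- draw(ceiling((n - nrow(acc)) * 1.3) + 100L)
        p_acc <- ifelse(is_hot(se), f, 1) / max(f, 1)
        keep <- stats::runif(nrow(se)) < p_acc
        acc <- rbind(acc, se[keep, , drop = FALSE])
      }
      se <- acc[seq_len(n), , drop = FALSE]
    } else {
      se <- draw(n)
    }
    fs <- fragment_set(rep("chrS", n), se[, 1], se[, 2], sample_id)
    attr(fs, "true_nrl") <- true_nrl
    attr(fs, "age") <- age
    fs
  })
}

#' Simulate a cohort
#'
#' Ages are drawn uniformly from the spec's age range; each subject is
#' generated on its own RNG substream, so the cohort is reproducible and
#' independent of generation order.
#'
#' @param spec a `cohort_spec`.
#' @param ages optional numeric vector overriding the uniform age draw
#'   (length `n_subjects`).
#' @return A list of class `cohort` with elements `samples` (list of
#'   `fragment_set`), `meta` (data.frame: sample_id, age, group) and
#'   `true_nrl` (numeric vector).
#' @export
generate_cohort <- function(spec, ages = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(ages)) {
    ages <- with_seed(derive_seed(spec$seed, 0L),
                      stats::runif(spec$n_subjects, spec$age_range[1],
                                   spec$age_range[2]))
  }
  stopifnot(length(ages) == spec$n_subjects)
  samples <- vector("list", spec$n_subjects)
  true_nrl <- numeric(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    samples[[i]] <- generate_subject(spec, ages[i], i)
    true_nrl[i] <- attr(samples[[i]], "true_nrl")
  }
  meta <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    age = ages, group = NA_character_, stringsAsFactors = FALSE)
  structure(list(samples = samples, meta = meta, true_nrl = true_nrl,
                 spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, ages %.0f-%.0f, true NRL %.1f-%.1f bp\n",
              nrow(x$meta), min(x$meta$age), max(x$meta$age),
              min(x$true_nrl), max(x$true_nrl)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one BED file per subject, a metadata TSV, and a JSON truth file
#' (true NRLs, ages, spec echo) for test harnesses.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param gzip write gzip-compressed BED files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".bed.gz" else ".bed"
  for (fs in cohort$samples)
    write_fragments(fs, file.path(dir, paste0(fs$sample_id, ext)))
  meta <- cohort$meta
  utils::write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(sample_id = meta$sample_id, age = meta$age,
                true_nrl = cohort$true_nrl,
                spec = unclass(cohort$spec))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
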