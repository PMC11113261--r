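## Phasograms: histograms of pairwise distances between cfDNA fragment
## centres, and nucleosome repeat length (NRL) estimation.
##
## The phasogram of a nucleosome-protected sample oscillates with the
## inter-nucleosome spacing; the NRL is recovered as the slope of an OLS
## fit of phasogram peak position against peak order.

#' Compute a phasogram
#'
#' Counts ordered centre pairs (i < j, same chromosome) at each distance
#' `d = c_j - c_i`, `0 <= d <= d_max`, pooled over chromosomes.  Uses a
#' sorted sliding window, never an all-pairs scan, so runtime scales with
#' the number of pairs actually within `d_max`.
#'
#' @param fs a `fragment_set` (centres are already sorted per
#'   chromosome).
#' @param d_max maximum distance, bp (>= 500).
#' @return An object of class `phasogram`: list with `d` (0..d_max),
#'   `counts`, `n_pairs`, `norm` (= counts / n_pairs) and `smoothed`
#'   (NULL until [smooth_phasogram()]).
#' @export
compute_phasogram <- function(fs, d_max = 2000) {
  stopifnot(inherits(fs, "fragment_set"), d_max >= 500)
  d_max <- as.integer(d_max)
  counts <- numeric(d_max + 1L)  # index 1 <-> d = 0
  if (fs$n_fragments < 2L)
    warning("fewer than 2 fragments; phasogram is all zero")
  for (ch in fs$chroms) {
    cc <- ch$centre
    n <- length(cc)
    if (n < 2L) next
    ## last index whose centre is within d_max of each centre
    hi <- findInterval(cc + d_max, cc)
    ni <- hi - seq_len(n)
    ## chunk the pair expansion to bound memory
    csum <- cumsum(as.numeric(ni))
    starts <- 1L
    while (starts <= n) {
      stop_i <- findInterval(csum[starts] + 5e6, csum) + 1L
      stop_i <- min(max(stop_i, starts), n)
      idx <- starts:stop_i
      nii <- ni[idx]
      if (sum(nii) > 0) {
        js <- sequence(nii, from = idx + 1L)
        dd <- cc[js] - rep(cc[idx], nii)
        counts <- counts + tabulate(dd + 1L, nbins = d_max + 1L)
      }
      starts <- stop_i + 1L
    }
  }
  structure(list(d = 0:d_max, counts = counts, n_pairs = sum(counts),
                 norm = if (sum(counts) > 0) counts / sum(counts)
                 else counts,
                 smoothed = NULL, sample_id = fs$sample_id),
            class = "phasogram")
}

#' @export
print.phasogram <- function(x, ...) {
  cat(sprintf("phasogram '%s': %g pairs up to d = %d bp%s\n",
              x$sample_id, x$n_pairs, max(x$d),
              if (is.null(x$smoothed)) "" else " (smoothed)"))
  invisible(x)
}

#' Savitzky-Golay smoothing of a phasogram
#'
#' Smooths the normalised phasogram; raw counts are untouched.  A
#' polynomial of order `polyorder` is fit in a centred window, which
#' preserves peak positions far better than a moving average.
#'
#' @param p a `phasogram`.
#' @param window odd window length, bp.
#' @param polyorder polynomial order, < `window`.
#' @return the `phasogram` with `smoothed` filled in.
#' @export
smooth_phasogram <- function(p, window = 51, polyorder = 3) {
  stopifnot(inherits(p, "phasogram"), window %% 2 == 1,
            window > polyorder)
  if (window > length(p$norm))
    stop("smoothing window (", window, ") exceeds signal length (",
         length(p$norm), ")")
  p$smoothed <- as.numeric(signal::sgolayfilt(p$norm, p = polyorder,
                                              n = window))
  p$smooth_window <- window
  p$smooth_polyorder <- polyorder
  p
}

## Prominence of a local maximum: height minus the higher of the two
## minima separating it from the nearest higher point (or signal end).
peak_prominences <- function(s, peaks) {
  vapply(peaks, function(i) {
    h <- s[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && s[j] <= h) { lmin <- min(lmin, s[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(lmin, min(s[1:i]))
    rmin <- h
    j <- i + 1L
    n <- length(s)
    while (j <= n && s[j] <= h) { rmin <- min(rmin, s[j]); j <- j + 1L }
    if (j > n) rmin <- min(rmin, min(s[i:n]))
    h - max(lmin, rmin)
  }, 0)
}

## Dominant period of a (centred) signal on the candidate band, by direct
## evaluation of the discrete spectrum at a fine period grid.
dominant_period <- function(s, d, band = c(120, 260), step = 0.25) {
  s0 <- s - mean(s)
  periods <- seq(band[1], band[2], by = step)
  power <- vapply(periods, function(P) {
    w <- 2 * pi * d / P
    sum(s0 * cos(w))^2 + sum(s0 * sin(w))^2
  }, 0)
  periods[which.max(power)]
}

#' Detect phasogram peaks and assign nucleosome orders
#'
#' Local maxima of the smoothed phasogram at `d >= d_min_fit` with
#' prominence above a threshold are assigned order indices
#' `k = round(position / period)`, where the period is the dominant
#' spectral component of the smoothed signal on the 120-260 bp band.
#' Peaks falling more than a quarter period from an integer multiple are
#' discarded (this suppresses half-period harmonics contributed by
#' di-nucleosome fragment centres, which sit mid-way between dyads); when
#' two peaks map to the same order the more prominent one wins.  Skipped
#' orders are allowed.  Peak positions are refined to sub-bp precision by
#' parabolic interpolation around each maximum.
#'
#' @param p a smoothed `phasogram`.
#' @param d_min_fit smallest distance considered, bp (excludes the
#'   zero-lag/self-overlap shoulder).
#' @param min_prominence prominence threshold; default 2% of the
#'   smoothed-signal range over the fit region.
#' @param k_max largest order used.
#' @return An object of class `peak_set`: data.frame with columns `k`,
#'   `position`, `prominence`; attribute `period` holds the coarse
#'   period estimate.
#' @export
detect_peaks <- function(p, d_min_fit = 120, min_prominence = NULL,
                         k_max = 10) {
  stopifnot(inherits(p, "phasogram"))
  if (is.null(p$smoothed))
    stop("smooth_phasogram() must be applied first")
  sel <- p$d >= d_min_fit
  s <- p$smoothed[sel]
  d <- p$d[sel]
  n <- length(s)
  cand <- which(s[-c(1L, n)] > s[1:(n - 2L)] &
                  s[-c(1L, n)] >= s[3:n]) + 1L
  if (is.null(min_prominence))
    min_prominence <- 0.02 * diff(range(s))
  if (length(cand)) {
    prom <- peak_prominences(s, cand)
    keep <- prom >= min_prominence & prom > 0
    cand <- cand[keep]
    prom <- prom[keep]
  } else prom <- numeric(0)
  if (length(cand) < 3L)
    stop("insufficient peaks for NRL (", length(cand), " found)")
  period <- dominant_period(s, d)
  ## sub-bp refinement: parabola through the three points at the maximum
  pos <- vapply(seq_along(cand), function(ii) {
    i <- cand[ii]
    if (i <= 1L || i >= n) return(d[i])
    denom <- s[i - 1L] - 2 * s[i] + s[i + 1L]
    delta <- if (denom < 0) 0.5 * (s[i - 1L] - s[i + 1L]) / denom else 0
    d[i] + max(-0.5, min(0.5, delta))
  }, 0)
  k <- round(pos / period)
  resid <- pos / period - k
  ok <- abs(resid) <= 0.25 & k >= 1 & k <= k_max
  k <- k[ok]; pos <- pos[ok]; prom <- prom[ok]
  if (length(k)) {
    o <- order(k, -prom)
    first <- !duplicated(k[o])
    o <- o[first]
    o <- o[order(k[o])]
    k <- k[o]; pos <- pos[o]; prom <- prom[o]
  }
  if (length(k) < 3L)
    stop("insufficient peaks for NRL (", length(k),
         " after order assignment)")
  structure(data.frame(k = k, position = pos, prominence = prom),
            class = c("peak_set", "data.frame"), period = period)
}

#' Estimate the nucleosome repeat length from a peak set
#'
#' OLS fit `position = intercept + nrl * k`; the slope is the NRL and the
#' intercept absorbs any constant linker/footprint offset.  The estimate
#' is flagged unreliable (never a hard failure) when R-squared < 0.95,
#' the slope standard error exceeds 2 bp, or the slope falls outside the
#' plausible 120-260 bp band.
#'
#' @param peaks a `peak_set` with at least 3 peaks.
#' @return An object of class `nrl_estimate` with fields `nrl`,
#'   `intercept`, `r_squared`, `slope_se`, `n_peaks_used`, `reliable`,
#'   and the underlying `peaks`.
#' @export
estimate_nrl <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(peaks) < 3L) stop("need at least 3 peaks")
  fit <- stats::lm(position ~ k, data = peaks)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  nrl <- unname(stats::coef(fit)[2])
  se <- sm$coefficients["k", "Std. Error"]
  r2 <- sm$r.squared
  structure(list(nrl = nrl,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, slope_se = se,
                 n_peaks_used = nrow(peaks),
                 reliable = r2 >= 0.95 && se <= 2 &&
                   nrl >= 120 && nrl <= 260,
                 peaks = peaks),
            class = "nrl_estimate")
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat(sprintf("NRL estimate: %.2f bp (SE %.3f, R^2 %.4f, %d peaks)%s\n",
              x$nrl, x$slope_se, x$r_squared, x$n_peaks_used,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' @export
coef.nrl_estimate <- function(object, ...) {
  c(intercept = object$intercept, nrl = object$nrl)
}

#' @export
summary.nrl_estimate <- function(object, ...) {
  print(object)
  cat("peaks used:\n")
  print(object$peaks, row.names = FALSE)
  invisible(object)
}

#' One-call NRL estimation for a sample
#'
#' Convenience pipeline: phasogram, Savitzky-Golay smoothing, peak
#' detection, OLS peak-order fit.
#'
#' @param fs a `fragment_set`.
#' @param d_max,d_min_fit phasogram range and fit region, bp.
#' @param window,polyorder smoothing parameters.
#' @param k_max largest peak order used in the fit.
#' @return An `nrl_estimate`.
#' @export
sample_nrl <- function(fs, d_max = 2000, d_min_fit = 120, window = 51,
                       polyorder = 3, k_max = 10) {
  p <- compute_phasogram(fs, d_max = d_max)
  p <- smooth_phasogram(p, window = window, polyorder = polyorder)
  estimate_nrl(detect_peaks(p, d_min_fit = d_min_fit, k_max = k_max))
}

#' Per-sample NRL table with group summaries
#'
#' Estimates the NRL for every sample; a failing sample is reported as a
#' flagged row, never an abort.
#'
#' @param samples list of `fragment_set` objects.
#' @param group optional character/factor vector of group labels.
#' @param ... passed to [sample_nrl()].
#' @return data.frame with columns `sample_id`, `nrl`, `se`, `r2`,
#'   `n_peaks`, `flag` (`"ok"`, `"unreliable"` or `"failed"`); when
#'   groups are given, attribute `group_stats` holds per-group mean,
#'   median and variance of the NRL.
#' @export
nrl_cohort_table <- function(samples, group = NULL, ...) {
  rows <- lapply(seq_along(samples), function(i) {
    fs <- samples[[i]]
    est <- tryCatch(sample_nrl(fs, ...), error = function(e) e)
    if (inherits(est, "error"))
      data.frame(sample_id = fs$sample_id, nrl = NA_real_, se = NA_real_,
                 r2 = NA_real_, n_peaks = NA_integer_, flag = "failed",
                 stringsAsFactors = FALSE)
    else
      data.frame(sample_id = fs$sample_id, nrl = est$nrl,
                 se = est$slope_se, r2 = est$r_squared,
                 n_peaks = est$n_peaks_used,
                 flag = if (est$reliable) "ok" else "unreliable",
                 stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(group)) {
    stopifnot(length(group) == length(samples))
    tab$group <- as.character(group)
    ok <- !is.na(tab$nrl)
    gs <- do.call(rbind, lapply(split(tab$nrl[ok], tab$group[ok]),
                                function(v)
                                  data.frame(n = length(v), mean = mean(v),
                                             median = stats::median(v),
                                             var = stats::var(v))))
    gs$group <- rownames(gs)
    attr(tab, "group_stats") <- gs[, c("group", "n", "mean", "median",
                                       "var")]
  }
  tab
}

#' NRL-age association statistics
#'
#' Pearson correlation between NRL and age with the two-sided
#' t-distributed p-value; optionally a paired-sample t-test between two
#' groups (e.g. centenarians vs young subjects matched by position).
#'
#' @param nrls,ages equal-length numeric vectors, n >= 3.
#' @param pairing optional two-level factor; the paired t-test compares
#'   `nrls` between the two levels in order of appearance (equal sizes
#'   required).
#' @return list with `pearson_r`, `p_value`, `n`, and when pairing is
#'   given `paired_t` (statistic, p_value, mean_difference).
#' @export
nrl_age_stats <- function(nrls, ages, pairing = NULL) {
  stopifnot(length(nrls) == length(ages), length(nrls) >= 3)
  if (stats::sd(nrls) == 0 || stats::sd(ages) == 0)
    stop("zero variance in NRL or age")
  ct <- stats::cor.test(nrls, ages, method = "pearson")
  out <- list(pearson_r = unname(ct$estimate),
              p_value = ct$p.value, n = length(nrls))
  if (!is.null(pairing)) {
    lv <- unique(as.character(pairing))
    if (length(lv) != 2) stop("pairing must have exactly 2 levels")
    a <- nrls[pairing == lv[1]]
    b <- nrls[pairing == lv[2]]
    if (length(a) != length(b))
      stop("paired groups must have equal sizes")
    d <- b - a
    if (stats::sd(d) == 0) {
      ## degenerate pairing: identical groups give t = 0, p = 1
      out$paired_t <- list(
        statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
        p_value = if (mean(d) == 0) 1 else 0,
        mean_difference = mean(d))
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)
      out$paired_t <- list(statistic = unname(tt$statistic),
                           p_value = tt$p.value,
                           mean_difference = unname(tt$estimate))
    }
  }
  out
}

#' Write a phasogram as TSV
#' @param p a `phasogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phasogram <- function(p, path) {
  df <- data.frame(distance = p$d, count = p$counts, norm = p$norm)
  if (!is.null(p$smoothed)) df$smoothed <- p$smoothed
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
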