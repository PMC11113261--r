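## Binned cfDNA occupancy, differential-region discovery between age
## groups, and PCA stratification with held-out projection.

#' Binned occupancy track of a sample
#'
#' Counts, for each fixed-width bin anchored at coordinate 0 (half-open
#' `[i*bin, (i+1)*bin)`), the fragments overlapping the bin; a fragment
#' overlapping m bins increments each of the m bins by 1.  Raw counts are
#' scaled to fragments-per-million (FPM): `raw / n_fragments * 1e6`, so
#' tracks are comparable across sequencing depths.
#'
#' @param fs a `fragment_set`.
#' @param bin_size bin width, bp (>= 10).
#' @return An object of class `occupancy_track`: list with per-chromosome
#'   `raw` and `value` (FPM) vectors (bin i of chromosome `ch` is
#'   `track$values[[ch]][i + 1]` for 0-based bin index i), `bin_size` and
#'   `n_fragments`.
#' @export
bin_occupancy <- function(fs, bin_size = 100) {
  stopifnot(inherits(fs, "fragment_set"), bin_size >= 10)
  values <- list(); raw <- list()
  for (ch in names(fs$chroms)) {
    d <- fs$chroms[[ch]]
    if (length(d$start) == 0L) { raw[[ch]] <- numeric(0); next }
    b0 <- d$start %/% bin_size
    b1 <- (d$end - 1) %/% bin_size
    nb <- b1 - b0 + 1
    bins <- sequence(nb, from = b0 + 1)  # 1-based bin ids
    raw[[ch]] <- tabulate(bins, nbins = max(b1) + 1L)
  }
  scale <- if (fs$n_fragments > 0) 1e6 / fs$n_fragments else 0
  values <- lapply(raw, function(v) v * scale)
  structure(list(raw = raw, values = values, bin_size = bin_size,
                 n_fragments = fs$n_fragments, sample_id = fs$sample_id),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("occupancy_track '%s': %d-bp bins, %d fragments, %d chrom\n",
              x$sample_id, x$bin_size, x$n_fragments, length(x$raw)))
  invisible(x)
}

## Stack tracks into a bins x samples FPM matrix on a common grid.
occupancy_matrix <- function(tracks) {
  bs <- unique(vapply(tracks, `[[`, 0, "bin_size"))
  if (length(bs) != 1) stop("tracks use different bin sizes")
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$raw))))
  rows <- list()
  for (ch in sort(chroms)) {
    nmax <- max(vapply(tracks, function(t)
      length(t$values[[ch]]) %||% 0L, 0L))
    if (nmax == 0L) next
    m <- vapply(tracks, function(t) {
      v <- t$values[[ch]] %||% numeric(0)
      c(v, numeric(nmax - length(v)))
    }, numeric(nmax))
    rownames(m) <- sprintf("%s:%d-%d", ch,
                           (seq_len(nmax) - 1L) * bs,
                           seq_len(nmax) * bs)
    rows[[ch]] <- m
  }
  out <- do.call(rbind, rows)
  colnames(out) <- vapply(tracks, `[[`, "", "sample_id")
  attr(out, "bin_size") <- bs
  out
}

## Vectorised per-row Welch t-test (B vs A); returns t, df, p.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, delta = mb - ma)
}

#' Differential occupancy bins between two groups
#'
#' Per-bin two-sample test on FPM-normalised occupancy with
#' Benjamini-Hochberg FDR control.  Bins with zero occupancy in every
#' sample of both groups are excluded before testing.  With fewer than 2
#' samples in a group the function falls back to fold-change ranking and
#' flags the result.
#'
#' @param groupA,groupB lists of `occupancy_track` on the same grid.
#' @param alpha FDR level.
#' @param direction `"B>A"` (default), `"A>B"` or `"both"`.
#' @param test `"welch"` (default) or `"wilcoxon"` (needs >= 4 per
#'   group).
#' @param min_fc absolute log2 fold-change cut used only in the
#'   fold-change fallback.
#' @return An object of class `region_set`: data.frame with `chrom`,
#'   `bin_start`, `bin_end`, `statistic`, `p_adj`, `direction`;
#'   attributes `n_tested` and `method`.
#' @export
differential_bins <- function(groupA, groupB, alpha = 0.05,
                              direction = c("B>A", "A>B", "both"),
                              test = c("welch", "wilcoxon"),
                              min_fc = 1) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  a <- occupancy_matrix(groupA)
  b <- occupancy_matrix(groupB)
  if (attr(a, "bin_size") != attr(b, "bin_size"))
    stop("bin grids differ between groups")
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0L) stop("no common bins between groups")
  ## grids must agree where they overlap; pad-length differences at
  ## chromosome ends are tolerated by restricting to the common bins
  a <- a[common, , drop = FALSE]
  b <- b[common, , drop = FALSE]
  nz <- rowSums(a) + rowSums(b) > 0
  a <- a[nz, , drop = FALSE]
  b <- b[nz, , drop = FALSE]
  method <- test
  if (ncol(a) < 2 || ncol(b) < 2) {
    method <- "fold_change"
    lfc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
    stat <- lfc; p <- rep(NA_real_, length(lfc))
    keep <- switch(direction,
                   "B>A" = lfc >= min_fc,
                   "A>B" = lfc <= -min_fc,
                   both = abs(lfc) >= min_fc)
    warning("fewer than 2 samples per group: fold-change ranking, ",
            "no significance control")
  } else if (test == "welch") {
    w <- welch_rows(a, b)
    stat <- w$t
    p <- w$p
    p[!is.finite(stat)] <- 1
    stat[!is.finite(stat)] <- 0
  } else {
    if (ncol(a) < 4 || ncol(b) < 4)
      stop("wilcoxon test needs >= 4 samples per group")
    res <- apply(cbind(a, b), 1L, function(v) {
      wt <- suppressWarnings(
        stats::wilcox.test(v[seq_len(ncol(a))],
                           v[ncol(a) + seq_len(ncol(b))]))
      c(wt$statistic, wt$p.value)
    })
    stat <- -res[1L, ]
    p <- res[2L, ]
  }
  if (method != "fold_change") {
    p_adj <- stats::p.adjust(p, method = "BH")
    delta <- rowMeans(b) - rowMeans(a)
    keep <- p_adj < alpha & switch(direction,
                                   "B>A" = delta > 0,
                                   "A>B" = delta < 0,
                                   both = TRUE)
  } else p_adj <- p
  ids <- rownames(a)[keep]
  parts <- regmatches(ids, regexec("^(.*):(\\d+)-(\\d+)$", ids))
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 2L),
    bin_start = as.numeric(vapply(parts, `[[`, "", 3L)),
    bin_end = as.numeric(vapply(parts, `[[`, "", 4L)),
    statistic = stat[keep],
    p_adj = p_adj[keep],
    direction = if (length(ids))
      ifelse((rowMeans(b) - rowMeans(a))[keep] > 0, "up", "down")
    else character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- ids
  structure(out, class = c("region_set", "data.frame"),
            n_tested = nrow(a), method = method)
}

#' Write a region set as BED6
#'
#' Name column carries the test statistic, score column
#' `-log10(p_adj)` (capped at 1000).
#'
#' @param rs a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(rs, path) {
  score <- ifelse(is.na(rs$p_adj), 0,
                  pmin(1000, round(-log10(pmax(rs$p_adj, 1e-300)), 2)))
  df <- data.frame(rs$chrom, as.integer(rs$bin_start),
                   as.integer(rs$bin_end),
                   sprintf("stat=%.3f", rs$statistic), score,
                   ifelse(rs$direction == "up", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' PCA stratification over differential regions
#'
#' Restricts occupancy tracks to a region set, standardises each region
#' (mean 0, SD 1 across the discovery samples), and performs PCA.
#' Constant regions are dropped with a warning.  The standardisation and
#' loadings are frozen: held-out samples are projected with the
#' discovery means/SDs (see [project_samples()]), never re-fit.
#'
#' @param tracks list of discovery `occupancy_track` objects.
#' @param regions a `region_set` (or data.frame with `chrom`,
#'   `bin_start`, `bin_end`).
#' @return An object of class `occupancy_pca`: list with `scores`
#'   (samples x PCs), `loadings`, `explained_variance_ratio`, `center`,
#'   `scale`, `region_ids`, `bin_size`, `discovery_samples`.
#' @export
fit_pca <- function(tracks, regions) {
  stopifnot(length(tracks) >= 3)
  m <- occupancy_matrix(tracks)
  ids <- sprintf("%s:%d-%d", regions$chrom,
                 as.integer(regions$bin_start),
                 as.integer(regions$bin_end))
  if (length(ids) < 2) stop("need at least 2 regions")
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("regions missing from tracks: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- t(m[ids, , drop = FALSE])  # samples x regions
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning(sum(const), " constant region(s) dropped")
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]; sd <- sd[!const]
    ids <- ids[!const]
  }
  if (ncol(x) < 2) stop("fewer than 2 non-constant regions")
  z <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_ratio = evr,
                 center = mu, scale = sd, region_ids = ids,
                 bin_size = attr(m, "bin_size"),
                 discovery_samples = rownames(x)),
            class = "occupancy_pca")
}

#' @export
print.occupancy_pca <- function(x, ...) {
  cat(sprintf(
    "occupancy_pca: %d discovery samples, %d regions; PC1 %.0f%% var\n",
    length(x$discovery_samples), length(x$region_ids),
    100 * x$explained_variance_ratio[1]))
  invisible(x)
}

#' Project samples onto a fitted occupancy PCA
#'
#' Standardises with the stored discovery means/SDs and projects onto the
#' stored loadings; projecting a discovery sample reproduces its original
#' score.
#'
#' @param model an `occupancy_pca`.
#' @param tracks list of `occupancy_track` objects binned on the same
#'   grid.
#' @return matrix of PC scores (samples x components).
#' @export
project_samples <- function(model, tracks) {
  stopifnot(inherits(model, "occupancy_pca"))
  m <- occupancy_matrix(tracks)
  missing <- setdiff(model$region_ids, rownames(m))
  if (length(missing))
    stop("samples lack model regions: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- t(m[model$region_ids, , drop = FALSE])
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  z %*% model$loadings
}

#' Serialise an occupancy PCA model to JSON
#' @param model an `occupancy_pca`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(region_ids = model$region_ids, center = model$center,
         scale = model$scale,
         loadings = apply(model$loadings, 2L, identity,
                          simplify = FALSE),
         explained_variance_ratio = model$explained_variance_ratio,
         bin_size = model$bin_size,
         discovery_samples = model$discovery_samples),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
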