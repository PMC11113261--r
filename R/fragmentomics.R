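## Fragment-size distributions and derived mixture features.

#' Fragment-size distribution of a sample
#'
#' Counts fragment sizes in 1-bp bins over `[size_min, size_max]` and
#' normalises to frequencies.
#'
#' @param fs a `fragment_set`.
#' @param size_min,size_max inclusive size range, bp.
#' @return An object of class `size_dist`: list with `size` (integer
#'   grid), `counts`, `freq` (sums to 1 when non-empty), `n_total`, and
#'   `empty` flag.
#' @export
size_distribution <- function(fs, size_min = 100, size_max = 600) {
  stopifnot(inherits(fs, "fragment_set"), size_max > size_min)
  sizes <- fragment_sizes(fs)
  sizes <- sizes[sizes >= size_min & sizes <= size_max]
  grid <- size_min:size_max
  counts <- if (length(sizes))
    tabulate(sizes - size_min + 1L, nbins = length(grid))
  else
    integer(length(grid))
  n <- sum(counts)
  structure(list(size = grid, counts = counts,
                 freq = if (n > 0) counts / n else rep(NA_real_,
                                                       length(grid)),
                 n_total = n, empty = n == 0,
                 sample_id = fs$sample_id),
            class = "size_dist")
}

#' @export
print.size_dist <- function(x, ...) {
  cat(sprintf("size_dist '%s': %d fragments over [%d, %d] bp%s\n",
              x$sample_id, x$n_total, min(x$size), max(x$size),
              if (x$empty) " (empty)" else
                sprintf(", mode at %d bp", x$size[which.max(x$counts)])))
  invisible(x)
}

#' Average size distributions across samples
#'
#' Unweighted mean of the per-sample frequency vectors, renormalised to
#' sum to 1 (so every sample contributes equally, regardless of depth).
#'
#' @param dists list of `size_dist` objects on identical size grids.
#' @return A `size_dist` (counts are summed raw counts; `freq` is the
#'   renormalised mean frequency).
#' @export
group_average_distribution <- function(dists) {
  stopifnot(length(dists) >= 1)
  grid <- dists[[1]]$size
  for (d in dists) {
    stopifnot(inherits(d, "size_dist"))
    if (!identical(d$size, grid)) stop("mismatched size-bin edges")
    if (d$empty) stop("cannot average an empty distribution: ",
                      d$sample_id)
  }
  fmat <- vapply(dists, `[[`, numeric(length(grid)), "freq")
  freq <- rowMeans(fmat)
  freq <- freq / sum(freq)
  counts <- rowSums(vapply(dists, function(d) as.numeric(d$counts),
                           numeric(length(grid))))
  structure(list(size = grid, counts = counts, freq = freq,
                 n_total = sum(counts), empty = FALSE,
                 sample_id = sprintf("average(%d)", length(dists))),
            class = "size_dist")
}

#' Mono/di/tri-nucleosome fragment proportions
#'
#' Frequency mass inside three disjoint size windows, corresponding to
#' fragments protected by one, two or three nucleosomes.
#'
#' @param dist a `size_dist`.
#' @param mono,di,tri inclusive size windows, bp, `c(lo, hi)`.  Defaults
#'   bracket the chromatosome (~167 bp), di- (~330 bp) and tri-
#'   (~500 bp) nucleosome peaks.
#' @return named numeric: `mono`, `di`, `tri` proportions in `[0, 1]`.
#' @export
multinucleosome_proportions <- function(dist, mono = c(120, 200),
                                        di = c(275, 420),
                                        tri = c(440, 600)) {
  stopifnot(inherits(dist, "size_dist"))
  if (dist$empty) stop("empty distribution")
  wins <- list(mono = mono, di = di, tri = tri)
  iv <- t(vapply(wins, identity, numeric(2)))
  o <- order(iv[, 1])
  if (any(iv[o, 2][-3] >= iv[o, 1][-1]))
    stop("mono/di/tri windows must be disjoint")
  vapply(wins, function(w)
    sum(dist$freq[dist$size >= w[1] & dist$size <= w[2]]), 0)
}

#' Write a size distribution as TSV
#' @param dist a `size_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(dist, path) {
  utils::write.table(
    data.frame(size = dist$size, count = dist$counts, freq = dist$freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
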