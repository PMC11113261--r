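## Fragment-level I/O.
##
## cfDNA fragments are handled in BED convention: 0-based, half-open
## [start, end).  A fragment's size is end - start and its centre is
## floor((start + end) / 2) -- ties broken downward so centres are
## deterministic integers.

#' Construct a FragmentSet
#'
#' A `fragment_set` holds one sample's cfDNA fragments with, per
#' chromosome, the sorted fragment centres and the matching sizes.
#'
#' @param chrom character vector of chromosome names (one per fragment).
#' @param start,end integer vectors, BED convention (0-based, half-open).
#'   Every `end` must exceed its `start`.
#' @param sample_id sample identifier.
#' @return An object of class `fragment_set`: a list with `sample_id`,
#'   `chroms` (a named list, one entry per chromosome, each with sorted
#'   integer `centre` and the corresponding `size` and `start`/`end`),
#'   and `n_fragments`.
#' @export
fragment_set <- function(chrom, start, end, sample_id = "sample") {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0L && any(end <= start))
    stop("all fragments must satisfy end > start")
  start <- as.numeric(start)
  end <- as.numeric(end)
  centre <- floor((start + end) / 2)
  size <- end - start
  chroms <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(centre[i])]
    chroms[[ch]] <- list(centre = centre[o], size = size[o],
                         start = start[o], end = end[o])
  }
  structure(list(sample_id = sample_id, chroms = chroms, n_fragments = n),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s': %d fragments on %d chromosome(s)\n",
              x$sample_id, x$n_fragments, length(x$chroms)))
  invisible(x)
}

#' All fragment sizes of a sample
#' @param fs a `fragment_set`.
#' @return numeric vector of fragment sizes (bp), in no particular order.
#' @export
fragment_sizes <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  unlist(lapply(fs$chroms, `[[`, "size"), use.names = FALSE) %||% numeric(0)
}

#' Sorted fragment centres on one chromosome
#'
#' @param fs a `fragment_set`.
#' @param chrom chromosome name; an unknown chromosome yields an empty
#'   vector.
#' @return sorted integer vector of fragment centres (bp).
#' @export
fragment_centres <- function(fs, chrom) {
  stopifnot(inherits(fs, "fragment_set"))
  ch <- fs$chroms[[chrom]]
  if (is.null(ch)) return(numeric(0))
  ch$centre
}

#' Read cfDNA fragments from a BED file
#'
#' Reads a 3+ column BED file (extra columns ignored; gzip accepted) and
#' applies a fragment-size filter.  Malformed lines (non-integer
#' coordinates, `end <= start`) are a hard error naming the line number.
#'
#' @param path BED file path (`.gz` accepted).
#' @param size_min,size_max retained fragment-size window in bp
#'   (inclusive).  Defaults keep mono- through tri-nucleosome fragments.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return A `fragment_set` with an attribute `n_dropped` giving the
#'   number of size-filtered fragments.
#' @export
read_fragments <- function(path, size_min = 100, size_max = 600,
                           sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(size_min >= 1, size_max > size_min)
  if (is.null(sample_id))
    sample_id <- sub("\\.bed(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keepers <- nzchar(trimws(lines))
  lines <- lines[keepers]
  if (length(lines) == 0L) {
    warning("empty BED file: ", path)
    fs <- fragment_set(character(0), integer(0), integer(0), sample_id)
    attr(fs, "n_dropped") <- 0L
    return(fs)
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": end <= start")
  size <- end - start
  keep <- size >= size_min & size <= size_max
  fs <- fragment_set(chrom[keep], start[keep], end[keep], sample_id)
  attr(fs, "n_dropped") <- sum(!keep)
  fs
}

#' Write a FragmentSet as BED
#' @param fs a `fragment_set`.
#' @param path output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (ch in names(fs$chroms)) {
    d <- fs$chroms[[ch]]
    writeLines(sprintf("%s\t%d\t%d", ch, as.integer(d$start),
                       as.integer(d$end)), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a header containing at least `sample_id` and `age`
#' columns; an optional `group` column carries a label.
#'
#' @param path TSV path (`.gz` accepted).
#' @return data.frame with columns `sample_id` (character), `age`
#'   (numeric) and `group` (character or NA).
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "age") %in% names(df)))
    stop("metadata must have 'sample_id' and 'age' columns")
  if (nrow(df) == 0L)
    return(data.frame(sample_id = character(0), age = numeric(0),
                      group = character(0), stringsAsFactors = FALSE))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age))
  bad <- which(is.na(age) | !is.finite(age))
  if (length(bad))
    stop("missing or non-numeric age in rows: ",
         paste(bad, collapse = ", "))
  if (any(age < 0)) stop("ages must be non-negative")
  data.frame(sample_id = df$sample_id, age = age,
             group = if ("group" %in% names(df)) df$group else
               NA_character_,
             stringsAsFactors = FALSE)
}

#' Keep only fragments within a size window
#' @param fs a `fragment_set`.
#' @param size_min,size_max inclusive size window (bp).
#' @return filtered `fragment_set`.
#' @export
filter_fragments <- function(fs, size_min = 100, size_max = 600) {
  stopifnot(inherits(fs, "fragment_set"))
  chrom <- rep(names(fs$chroms),
               vapply(fs$chroms, function(d) length(d$size), 0L))
  start <- unlist(lapply(fs$chroms, `[[`, "start"), use.names = FALSE) %||%
    numeric(0)
  end <- unlist(lapply(fs$chroms, `[[`, "end"), use.names = FALSE) %||%
    numeric(0)
  size <- end - start
  keep <- size >= size_min & size <= size_max
  fragment_set(chrom[keep], start[keep], end[keep], fs$sample_id)
}
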