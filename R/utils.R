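# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round coordinates to the nearest multiple of a resolution
#'
#' Half-up tie rule: a coordinate exactly half-way between two grid points
#' rounds to the larger one.
#'
#' @param x Numeric vector of coordinates (base pairs).
#' @param resolution Grid size in base pairs.
#' @return Numeric vector of grid-aligned coordinates.
#' @export
round_to_grid <- function(x, resolution) {
  stopifnot(is.numeric(x), resolution > 0)
  floor(x / resolution + 0.5) * resolution
}

.assert_on_grid <- function(x, resolution, what = "coordinate") {
  if (any(x %% resolution != 0)) {
    stop(sprintf("%s not aligned to the %d bp grid", what, as.integer(resolution)),
         call. = FALSE)
  }
  invisible(x)
}

# row-wise variance of a numeric matrix, n-1 denominator
.row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# pairwise overlap hits between two interval sets split by chromosome.
# a, b: data.frames with chrom, start, end (0-based half-open).
# Returns data.frame(qi, si) of row indices with gap <= maxgap
# (maxgap = -1, the default, means intersection length >= 1 bp; adjacent
# half-open intervals do not overlap).
.chrom_overlaps <- function(a, b, maxgap = -1L) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, maxgap = maxgap)
    if (length(hits)) {
      out[[ch]] <- data.frame(qi = ia[S4Vectors::queryHits(hits)],
                              si = ib[S4Vectors::subjectHits(hits)])
    }
  }
  if (!length(out)) return(data.frame(qi = integer(), si = integer()))
  do.call(rbind, out)
}
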