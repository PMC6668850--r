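#' Describe a genome assembly as a set of binned chromosomes
#'
#' A minimal genome description used throughout the package: chromosome
#' names, lengths, and the fixed bin resolution at which contact matrices
#' are tiled. All coordinates in the package are 0-based, half-open, and
#' aligned to the resolution grid.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in base pairs; each
#'   must be a positive multiple of \code{resolution}.
#' @param resolution Bin size in base pairs (default 10000).
#' @return An object of class \code{genome_spec}.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(5e6, 4e6))
#' @export
genome_spec <- function(chroms, lengths, resolution = 10000) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(chroms) != length(lengths)) stop("chroms and lengths differ in length")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(lengths %% resolution != 0)) {
    stop("chromosome lengths must be multiples of the resolution")
  }
  structure(list(chroms = chroms,
                 lengths = stats::setNames(lengths, chroms),
                 resolution = resolution),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosome(s), %.3g bp total, %d bp bins\n",
              length(x$chroms), sum(x$lengths), as.integer(x$resolution)))
  invisible(x)
}

#' Tile a genome into fixed-size windows
#'
#' Tiles each chromosome end-to-end; a final partial window is kept.
#'
#' @param genome A \code{\link{genome_spec}}.
#' @param window Window size in base pairs (defaults to the genome
#'   resolution).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
tile_genome <- function(genome, window = genome$resolution) {
  if (window <= 0) stop("window size must be positive")
  out <- lapply(genome$chroms, function(ch) {
    len <- genome$lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len))
  })
  do.call(rbind, out)
}

#' Number of bins per chromosome at the genome resolution
#' @param genome A \code{\link{genome_spec}}.
#' @return Named integer vector.
#' @export
n_bins <- function(genome) {
  stats::setNames(as.integer(genome$lengths / genome$resolution), genome$chroms)
}
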