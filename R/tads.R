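#' Derive fixed-width boundaries from TAD intervals
#'
#' Each domain edge is extended by \code{flank} base pairs in both
#' directions, giving two boundaries of width \code{2 * flank} per domain
#' (15 kb by default), clamped to chromosome bounds when a genome is given.
#'
#' @param domains data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{sample}.
#' @param flank Extension in base pairs on each side of the edge
#'   (default 7500).
#' @param genome Optional \code{\link{genome_spec}} used to clamp the
#'   boundaries to chromosome ends; boundaries are always clamped at 0.
#' @return data.frame of boundaries with a \code{side} column
#'   ("left"/"right").
#' @export
boundaries_from_domains <- function(domains, flank = 7500, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(domains)))
  if (any(domains$end <= domains$start)) stop("domains must have end > start")
  edge <- c(domains$start, domains$end)
  out <- data.frame(chrom = rep(domains$chrom, 2),
                    start = edge - flank, end = edge + flank,
                    side = rep(c("left", "right"), each = nrow(domains)))
  if (!is.null(domains$sample)) out$sample <- rep(domains$sample, 2)
  out$start <- pmax(0, out$start)
  if (!is.null(genome)) {
    out$end <- pmin(out$end, genome$lengths[out$chrom])
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Reciprocal-overlap domain conservation criterion
#'
#' Two domains are conserved partners when each shares at least a fraction
#' \code{f} of its own length with the other (and they lie on the same
#' chromosome). Symmetric in its arguments.
#'
#' @param a,b data.frames (same number of rows, compared row-wise) with
#'   \code{chrom}, \code{start}, \code{end}.
#' @param f Required reciprocal overlap fraction (default 0.9).
#' @return Logical vector.
#' @export
reciprocal_overlap_conserved <- function(a, b, f = 0.9) {
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  a$chrom == b$chrom & ov >= f * (a$end - a$start) & ov >= f * (b$end - b$start)
}

#' Endpoint-distance domain conservation criterion
#'
#' Domain \code{a} is conserved against \code{b} when the Euclidean distance
#' between their (start, end) coordinate pairs is less than the smaller of
#' 50 kb or half of \code{a}'s size. Not symmetric when lengths differ: the
#' threshold always uses the size of the domain under consideration.
#'
#' @param a,b data.frames compared row-wise, with \code{chrom},
#'   \code{start}, \code{end}.
#' @return Logical vector.
#' @export
rao_conserved <- function(a, b) {
  dist <- sqrt((a$start - b$start)^2 + (a$end - b$end)^2)
  a$chrom == b$chrom & dist < pmin(50000, (a$end - a$start) / 2)
}

# which rows of x have at least one conserved partner in y
.has_partner <- function(x, y, criterion = c("reciprocal90", "rao"), f = 0.9) {
  criterion <- match.arg(criterion)
  if (!nrow(x) || !nrow(y)) return(rep(FALSE, nrow(x)))
  hits <- .chrom_overlaps(x, y, maxgap = if (criterion == "rao") 50000L else -1L)
  out <- rep(FALSE, nrow(x))
  if (!nrow(hits)) return(out)
  xa <- x[hits$qi, c("chrom", "start", "end")]
  yb <- y[hits$si, c("chrom", "start", "end")]
  ok <- if (criterion == "reciprocal90") {
    reciprocal_overlap_conserved(xa, yb, f)
  } else {
    rao_conserved(xa, yb)
  }
  out[unique(hits$qi[ok])] <- TRUE
  out
}

#' Cross-species domain conservation summary
#'
#' Counts, in each direction, the domains of one species with a conserved
#' partner in the other (each domain counted once however many partners it
#' has). The conserved domain count is the larger of the two directional
#' estimates, and the conservation proportion divides it by the sum of the
#' conserved count and the species-specific domains from both sets. Both
#' domain sets must be given in a common coordinate system (e.g. species B
#' domains transferred to assembly A with
#' \code{\link{transfer_intervals}}).
#'
#' @param a,b data.frames of domains with \code{chrom}, \code{start},
#'   \code{end}.
#' @param criterion \code{"reciprocal90"} or \code{"rao"}.
#' @param f Overlap fraction for the reciprocal criterion.
#' @return One-row data.frame with directional shared counts, totals, the
#'   conserved count, and the conservation \code{proportion} (NA when either
#'   set is empty).
#' @export
conservation_summary <- function(a, b, criterion = c("reciprocal90", "rao"),
                                 f = 0.9) {
  criterion <- match.arg(criterion)
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(criterion = criterion, n_a = nrow(a), n_b = nrow(b),
                      shared_a = NA_integer_, shared_b = NA_integer_,
                      conserved = NA_integer_, specific = NA_integer_,
                      proportion = NA_real_))
  }
  sa <- sum(.has_partner(a, b, criterion, f))
  sb <- sum(.has_partner(b, a, criterion, f))
  conserved <- max(sa, sb)
  specific <- (nrow(a) - sa) + (nrow(b) - sb)
  data.frame(criterion = criterion, n_a = nrow(a), n_b = nrow(b),
             shared_a = sa, shared_b = sb, conserved = conserved,
             specific = specific,
             proportion = conserved / (conserved + specific))
}

#' Merge boundaries across samples and score cross-species conservation
#'
#' Overlapping boundary intervals (any overlap of at least 1 bp; touching
#' half-open intervals do not overlap) from all samples are merged into
#' unique boundary elements. An element is conserved when its contributing
#' samples include both species.
#'
#' @param boundaries data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{sample}.
#' @param species Named vector mapping sample ids to species labels.
#' @return list with \code{elements} (merged intervals, contributing sample
#'   lists, \code{conserved} flag) and the conservation \code{proportion}.
#' @export
boundary_conservation <- function(boundaries, species) {
  stopifnot(all(c("chrom", "start", "end", "sample") %in% names(boundaries)))
  stopifnot(all(boundaries$sample %in% names(species)))
  elements <- list()
  for (ch in unique(boundaries$chrom)) {
    bb <- boundaries[boundaries$chrom == ch, , drop = FALSE]
    r <- IRanges::IRanges(start = bb$start + 1L, end = bb$end)
    red <- IRanges::reduce(r, with.revmap = TRUE, min.gapwidth = 0L)
    rv <- S4Vectors::mcols(red)$revmap
    contrib <- lapply(seq_along(red), function(i) unique(bb$sample[rv[[i]]]))
    elements[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      samples = vapply(contrib, paste, "", collapse = ","),
      conserved = vapply(contrib, function(s) {
        length(unique(species[s])) >= 2
      }, TRUE))
  }
  el <- do.call(rbind, elements)
  rownames(el) <- NULL
  list(elements = el, proportion = mean(el$conserved))
}

#' Pairwise feature-sharing matrix across individuals
#'
#' Entry (i, j) is the fraction of individual i's features (domains or
#' boundaries) with a conserved partner in individual j's set, so rows are
#' normalized by individual i's total and the matrix need not be symmetric.
#' Individuals are ordered by average-linkage hierarchical clustering of
#' 1 - the symmetrized sharing proportion.
#'
#' @param sets Named list of data.frames (one per individual) with
#'   \code{chrom}, \code{start}, \code{end}.
#' @param criterion \code{"reciprocal90"}, \code{"rao"}, or \code{"any"}
#'   (single-bp overlap, used for boundaries).
#' @param f Overlap fraction for the reciprocal criterion.
#' @return list with \code{matrix}, \code{hclust}, and \code{order}.
#' @export
sharing_matrix <- function(sets, criterion = c("reciprocal90", "rao", "any"),
                           f = 0.9) {
  criterion <- match.arg(criterion)
  n <- length(sets)
  stopifnot(n >= 2)
  ids <- names(sets) %||% as.character(seq_len(n))
  P <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- if (criterion == "any") {
        hits <- .chrom_overlaps(sets[[i]], sets[[j]], maxgap = -1L)
        seq_len(nrow(sets[[i]])) %in% hits$qi
      } else {
        .has_partner(sets[[i]], sets[[j]], criterion, f)
      }
      P[i, j] <- mean(shared)
    }
  }
  d <- stats::as.dist(1 - (P + t(P)) / 2)
  hc <- stats::hclust(d, method = "average")
  list(matrix = P, hclust = hc, order = ids[hc$order])
}
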