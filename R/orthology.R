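#' Interval-level orthology map between two assemblies
#'
#' The map is a set of alignment blocks, each pairing an interval of
#' assembly A with an equal-length interval of assembly B on strand
#' \code{"+"} (co-linear) or \code{"-"} (inverted). Blocks must be
#' non-overlapping within each assembly. Regions of A not covered by any
#' block have no ortholog in B (e.g. lineage-specific deletions), and
#' vice versa.
#'
#' @param blocks data.frame with columns \code{chrom_a}, \code{start_a},
#'   \code{end_a}, \code{chrom_b}, \code{start_b}, \code{end_b},
#'   \code{strand} ("+" or "-") and optionally \code{block_id}.
#' @return An object of class \code{orthology_map}.
#' @export
orthology_map <- function(blocks) {
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b", "strand")
  if (!all(need %in% names(blocks))) {
    stop("blocks must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(blocks$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  la <- blocks$end_a - blocks$start_a
  lb <- blocks$end_b - blocks$start_b
  if (any(la <= 0) || any(la != lb)) {
    stop("source and target block lengths must be equal and positive")
  }
  .check_disjoint <- function(ch, s, e, side) {
    for (c1 in unique(ch)) {
      i <- ch == c1
      o <- order(s[i])
      if (any(s[i][o][-1] < e[i][o][-sum(i)])) {
        stop("blocks overlap within assembly ", side)
      }
    }
  }
  .check_disjoint(blocks$chrom_a, blocks$start_a, blocks$end_a, "A")
  .check_disjoint(blocks$chrom_b, blocks$start_b, blocks$end_b, "B")
  if (is.null(blocks$block_id)) blocks$block_id <- seq_len(nrow(blocks))
  blocks <- blocks[order(blocks$chrom_a, blocks$start_a), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks), class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  b <- x$blocks
  cat(sprintf("<orthology_map> %d block(s), %.3g bp aligned, %d inverted\n",
              nrow(b), sum(b$end_a - b$start_a), sum(b$strand == "-")))
  invisible(x)
}

# map intervals through the block set in one direction.
# intervals: data.frame(chrom, start, end). Returns data.frame with target
# chrom/start/end/strand and status in {ok, no_target, split_block}.
.map_intervals <- function(map, intervals, direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  b <- map$blocks
  if (direction == "AtoB") {
    src <- data.frame(chrom = b$chrom_a, start = b$start_a, end = b$end_a)
    tgt <- data.frame(chrom = b$chrom_b, start = b$start_b, end = b$end_b)
  } else {
    src <- data.frame(chrom = b$chrom_b, start = b$start_b, end = b$end_b)
    tgt <- data.frame(chrom = b$chrom_a, start = b$start_a, end = b$end_a)
  }
  n <- nrow(intervals)
  out <- data.frame(chrom = rep(NA_character_, n), start = rep(NA_real_, n),
                    end = rep(NA_real_, n), strand = rep(NA_character_, n),
                    status = rep("no_target", n), stringsAsFactors = FALSE)
  hits <- .chrom_overlaps(intervals, src, maxgap = -1L)
  if (!nrow(hits)) return(out)
  nhit <- tabulate(hits$qi, nbins = n)
  multi <- which(nhit > 1)
  out$status[multi] <- "split_block"
  single <- hits[nhit[hits$qi] == 1L, , drop = FALSE]
  if (nrow(single)) {
    q <- single$qi; s <- single$si
    contained <- intervals$start[q] >= src$start[s] & intervals$end[q] <= src$end[s]
    # partial overlap with a single block: image spans the block edge
    out$status[q[!contained]] <- "split_block"
    q <- q[contained]; s <- s[contained]
    plus <- b$strand[s] == "+"
    ts <- ifelse(plus,
                 tgt$start[s] + (intervals$start[q] - src$start[s]),
                 tgt$start[s] + (src$end[s] - intervals$end[q]))
    te <- ts + (intervals$end[q] - intervals$start[q])
    out$chrom[q] <- tgt$chrom[s]
    out$start[q] <- ts
    out$end[q] <- te
    out$strand[q] <- b$strand[s]
    out$status[q] <- "ok"
  }
  out
}

#' Map resolution bins across assemblies with a reciprocal-best-hits rule
#'
#' Each bin is forward-mapped through the orthology map, the image's start
#' and end are independently rounded to the nearest multiple of
#' \code{resolution} (half-up ties), and the rounded target bin is mapped
#' back. The bin is accepted only if the back-mapped, rounded bin equals
#' the input bin. Rejections carry a reason: \code{no_target} (bin falls in
#' unaligned sequence), \code{split_block} (image spans a block edge or
#' rounds to a degenerate interval), or \code{non_reciprocal} (round trip
#' lands in a different bin).
#'
#' @param map An \code{\link{orthology_map}}.
#' @param chrom,start Vectors giving the bin locations (grid-aligned starts).
#' @param resolution Bin size in base pairs.
#' @param direction \code{"AtoB"} (default) or \code{"BtoA"}.
#' @return data.frame with the target bin (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}) and columns \code{accepted}, \code{reason}.
#' @export
map_bin_rbh <- function(map, chrom, start, resolution = 10000,
                        direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  .assert_on_grid(start, resolution, "bin start")
  bins <- data.frame(chrom = as.character(chrom), start = start,
                     end = start + resolution)
  fwd <- .map_intervals(map, bins, direction)
  res <- data.frame(chrom = NA_character_, start = NA_real_, end = NA_real_,
                    strand = NA_character_, accepted = FALSE,
                    reason = fwd$status, stringsAsFactors = FALSE)[rep(1, nrow(bins)), ]
  res$reason <- fwd$status
  rownames(res) <- NULL
  ok <- fwd$status == "ok"
  if (any(ok)) {
    rs <- round_to_grid(fwd$start[ok], resolution)
    re <- round_to_grid(fwd$end[ok], resolution)
    degen <- rs >= re
    res$reason[ok][degen] <- "split_block"
    ok2 <- which(ok)[!degen]
    if (length(ok2)) {
      tchrom <- fwd$chrom[ok2]
      tstart <- round_to_grid(fwd$start[ok2], resolution)
      tend <- tstart + resolution
      back <- .map_intervals(map, data.frame(chrom = tchrom, start = tstart,
                                             end = tend),
                             if (direction == "AtoB") "BtoA" else "AtoB")
      recip <- back$status == "ok" &
        back$chrom == bins$chrom[ok2] &
        round_to_grid(back$start, resolution) == bins$start[ok2]
      recip[is.na(recip)] <- FALSE
      acc <- ok2[recip]
      res$chrom[acc] <- tchrom[recip]
      res$start[acc] <- tstart[recip]
      res$end[acc] <- tend[recip]
      res$strand[acc] <- fwd$strand[ok2][recip]
      res$accepted[acc] <- TRUE
      res$reason[acc] <- "accepted"
      res$reason[ok2[!recip]] <- "non_reciprocal"
    }
  }
  res
}

#' Fraction of genome windows with a reciprocal ortholog
#'
#' Tiles the genome into windows (last partial window kept), maps each
#' window across the assemblies and back, and reports the fraction whose
#' round trip returns the original window exactly.
#'
#' @param genome A \code{\link{genome_spec}} for the source assembly.
#' @param map An \code{\link{orthology_map}}.
#' @param window Window size in base pairs.
#' @param direction Mapping direction for the forward pass.
#' @return Single numeric fraction in [0, 1].
#' @export
synteny_fraction <- function(genome, map, window,
                             direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  if (window <= 0) stop("window size must be positive")
  w <- tile_genome(genome, window)
  fwd <- .map_intervals(map, w, direction)
  mapped <- rep(FALSE, nrow(w))
  ok <- which(fwd$status == "ok")
  if (length(ok)) {
    back <- .map_intervals(map, fwd[ok, c("chrom", "start", "end")],
                           if (direction == "AtoB") "BtoA" else "AtoB")
    mapped[ok] <- back$status == "ok" & back$chrom == w$chrom[ok] &
      back$start == w$start[ok] & back$end == w$end[ok]
  }
  mean(mapped)
}

#' Transfer genomic intervals (e.g. TADs) across assemblies
#'
#' Interval-level reciprocal-best-hits transfer: the parts of an interval
#' covered by alignment blocks are mapped, and the transferred interval is
#' the coordinate range of the mapped pieces. An interval is accepted when
#' at least \code{min_cover} of its length is aligned, the pieces land on a
#' single target chromosome, and the reciprocal transfer overlaps the
#' original by at least \code{min_cover} of the longer of the two.
#'
#' @param map An \code{\link{orthology_map}}.
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param direction \code{"AtoB"} or \code{"BtoA"}.
#' @param min_cover Minimum aligned/overlap fraction (default 0.9).
#' @return \code{intervals} with added target columns \code{chrom_o},
#'   \code{start_o}, \code{end_o} and logical \code{mapped}.
#' @export
transfer_intervals <- function(map, intervals, direction = c("AtoB", "BtoA"),
                               min_cover = 0.9) {
  direction <- match.arg(direction)
  fwd <- .transfer_once(map, intervals, direction, min_cover)
  out <- intervals
  out$chrom_o <- fwd$chrom
  out$start_o <- fwd$start
  out$end_o <- fwd$end
  out$mapped <- fwd$ok
  idx <- which(fwd$ok)
  if (length(idx)) {
    back <- .transfer_once(map, data.frame(chrom = fwd$chrom[idx],
                                           start = fwd$start[idx],
                                           end = fwd$end[idx]),
                           if (direction == "AtoB") "BtoA" else "AtoB",
                           min_cover)
    same <- back$ok & back$chrom == intervals$chrom[idx]
    ov <- pmax(0, pmin(back$end, intervals$end[idx]) -
                 pmax(back$start, intervals$start[idx]))
    longer <- pmax(back$end - back$start,
                   intervals$end[idx] - intervals$start[idx])
    same <- same & !is.na(ov) & ov >= min_cover * longer
    same[is.na(same)] <- FALSE
    out$mapped[idx] <- same
    out$chrom_o[idx][!same] <- NA
    out$start_o[idx][!same] <- NA
    out$end_o[idx][!same] <- NA
  }
  out
}

# one-directional piecewise transfer; returns range of mapped pieces
.transfer_once <- function(map, intervals, direction, min_cover) {
  b <- map$blocks
  if (direction == "AtoB") {
    src <- data.frame(chrom = b$chrom_a, start = b$start_a, end = b$end_a)
  } else {
    src <- data.frame(chrom = b$chrom_b, start = b$start_b, end = b$end_b)
  }
  n <- nrow(intervals)
  res <- data.frame(chrom = rep(NA_character_, n), start = rep(NA_real_, n),
                    end = rep(NA_real_, n), ok = rep(FALSE, n))
  hits <- .chrom_overlaps(intervals, src, maxgap = -1L)
  if (!nrow(hits)) return(res)
  ps <- pmax(intervals$start[hits$qi], src$start[hits$si])
  pe <- pmin(intervals$end[hits$qi], src$end[hits$si])
  mp <- .map_intervals(map, data.frame(chrom = intervals$chrom[hits$qi],
                                       start = ps, end = pe), direction)
  keep <- mp$status == "ok"
  if (!any(keep)) return(res)
  q <- hits$qi[keep]
  cov <- stats::aggregate(pe[keep] - ps[keep], list(qi = q), sum)
  agg_s <- stats::aggregate(mp$start[keep], list(qi = q), min)
  agg_e <- stats::aggregate(mp$end[keep], list(qi = q), max)
  nchrom <- stats::aggregate(mp$chrom[keep], list(qi = q),
                             function(z) length(unique(z)))
  i <- cov$qi
  len <- intervals$end[i] - intervals$start[i]
  good <- cov$x >= min_cover * len & nchrom$x == 1
  i <- i[good]
  res$chrom[i] <- vapply(split(mp$chrom[keep], q), `[`, "", 1)[as.character(i)]
  res$start[i] <- agg_s$x[good]
  res$end[i] <- agg_e$x[good]
  res$ok[i] <- TRUE
  res
}

#' Invert an orthology map (swap the roles of the two assemblies)
#' @param map An \code{\link{orthology_map}}.
#' @return An \code{\link{orthology_map}} from B to A.
#' @export
invert_map <- function(map) {
  b <- map$blocks
  orthology_map(data.frame(chrom_a = b$chrom_b, start_a = b$start_b,
                           end_a = b$end_b, chrom_b = b$chrom_a,
                           start_b = b$start_a, end_b = b$end_a,
                           strand = b$strand, block_id = b$block_id))
}

#' Build the union list of orthologous contacts across individuals
#'
#' Collects every bin pair called significant in at least one individual
#' into a single deduplicated table keyed on assembly-A coordinates (anchors
#' sorted so that bin1 < bin2). Each individual's anchors are mapped into
#' the other assembly with the reciprocal-best-hits rule; pairs with any
#' non-orthologous anchor are excluded and tallied. The discovery count of
#' a union pair is the number of individuals (across both species) in which
#' it was independently significant.
#'
#' @param calls Named list, one element per individual:
#'   \code{list(assembly = "A"|"B", pairs = data.frame(chrom, start1, start2))}
#'   with grid-aligned anchor bin starts in that individual's assembly.
#' @param map An \code{\link{orthology_map}} (A to B).
#' @param resolution Bin size in base pairs.
#' @return list with \code{contacts} (union table with both assemblies'
#'   coordinates, mate-pair distances and \code{discovery_count}),
#'   \code{excluded} (per-individual tally), and \code{exclusion_fraction}.
#' @export
build_union_contacts <- function(calls, map, resolution = 10000) {
  stopifnot(length(calls) >= 1)
  per <- vector("list", length(calls))
  tally <- data.frame(individual = names(calls) %||% seq_along(calls),
                      n_input = 0L, n_excluded = 0L)
  for (k in seq_along(calls)) {
    ind <- calls[[k]]
    p <- ind$pairs
    tally$n_input[k] <- nrow(p)
    if (!nrow(p)) next
    dir <- if (identical(ind$assembly, "A")) "AtoB" else "BtoA"
    m1 <- map_bin_rbh(map, p$chrom, p$start1, resolution, dir)
    m2 <- map_bin_rbh(map, p$chrom, p$start2, resolution, dir)
    keep <- m1$accepted & m2$accepted
    tally$n_excluded[k] <- sum(!keep)
    if (!any(keep)) next
    if (identical(ind$assembly, "A")) {
      ca <- p$chrom[keep]; a1 <- p$start1[keep]; a2 <- p$start2[keep]
      cb <- m1$chrom[keep]; b1 <- m1$start[keep]; b2 <- m2$start[keep]
    } else {
      ca <- m1$chrom[keep]; a1 <- m1$start[keep]; a2 <- m2$start[keep]
      cb <- p$chrom[keep]; b1 <- p$start1[keep]; b2 <- p$start2[keep]
    }
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
    per[[k]] <- data.frame(chrom_a = ca, start1_a = a1, start2_a = a2,
                           chrom_b = cb, start1_b = b1, start2_b = b2,
                           individual = tally$individual[k])
  }
  all <- do.call(rbind, per)
  if (is.null(all) || !nrow(all)) {
    return(list(contacts = data.frame(), excluded = tally,
                exclusion_fraction = if (sum(tally$n_input) > 0)
                  sum(tally$n_excluded) / sum(tally$n_input) else NA_real_))
  }
  key <- paste(all$chrom_a, all$start1_a, all$start2_a, sep = ":")
  first <- !duplicated(key)
  contacts <- all[first, c("chrom_a", "start1_a", "start2_a",
                           "chrom_b", "start1_b", "start2_b")]
  contacts$discovery_count <- as.integer(table(key)[key[first]])
  contacts$dist_a <- contacts$start2_a - contacts$start1_a
  contacts$dist_b <- abs(contacts$start2_b - contacts$start1_b)
  contacts <- contacts[order(contacts$chrom_a, contacts$start1_a,
                             contacts$start2_a), ]
  rownames(contacts) <- NULL
  list(contacts = contacts, excluded = tally,
       exclusion_fraction = sum(tally$n_excluded) / sum(tally$n_input))
}

#' Attach per-individual normalized frequencies to a union contact table
#'
#' For every pair in the union table, looks up each individual's normalized
#' contact frequency in that individual's own assembly coordinates
#' (regardless of whether the pair was called significant there).
#'
#' @param union_contacts The \code{contacts} table from
#'   \code{\link{build_union_contacts}}.
#' @param freq_tables Named list per individual:
#'   \code{list(assembly, freq = data.frame(chrom, start1, start2, freq))}.
#' @return Numeric matrix (contacts x individuals) of log2 frequencies.
#' @export
attach_frequencies <- function(union_contacts, freq_tables) {
  n <- nrow(union_contacts)
  out <- matrix(NA_real_, n, length(freq_tables),
                dimnames = list(NULL, names(freq_tables)))
  for (k in seq_along(freq_tables)) {
    ft <- freq_tables[[k]]
    if (identical(ft$assembly, "A")) {
      key <- paste(union_contacts$chrom_a, union_contacts$start1_a,
                   union_contacts$start2_a, sep = ":")
    } else {
      key <- paste(union_contacts$chrom_b,
                   pmin(union_contacts$start1_b, union_contacts$start2_b),
                   pmax(union_contacts$start1_b, union_contacts$start2_b),
                   sep = ":")
    }
    fkey <- paste(ft$freq$chrom, pmin(ft$freq$start1, ft$freq$start2),
                  pmax(ft$freq$start1, ft$freq$start2), sep = ":")
    out[, k] <- ft$freq$freq[match(key, fkey)]
  }
  out
}
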