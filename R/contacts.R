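#' Sparse intrachromosomal contact count matrix for one individual
#'
#' @param pairs data.frame with columns \code{chrom}, \code{start1},
#'   \code{start2} (grid-aligned bin starts, \code{start1 <= start2}) and
#'   \code{count} (non-negative integer read pairs).
#' @param genome The \code{\link{genome_spec}} the bins live on.
#' @param max_distance Maximum bin-pair distance represented (base pairs);
#'   defines the pair universe used for expectation estimation.
#' @return Object of class \code{count_matrix}.
#' @export
count_matrix <- function(pairs, genome, max_distance = 2e6) {
  stopifnot(all(c("chrom", "start1", "start2", "count") %in% names(pairs)))
  if (any(pairs$count < 0)) stop("counts must be non-negative")
  res <- genome$resolution
  .assert_on_grid(pairs$start1, res, "bin start")
  .assert_on_grid(pairs$start2, res, "bin start")
  if (any(pairs$start2 < pairs$start1)) stop("start1 must be <= start2")
  structure(list(pairs = pairs, genome = genome,
                 total = sum(pairs$count), resolution = res,
                 max_distance = max_distance),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d nonzero pair(s), %.3g read pairs, %d bp bins\n",
              nrow(x$pairs), x$total, as.integer(x$resolution)))
  invisible(x)
}

# number of possible intrachromosomal pairs at each distance (multiples of
# the resolution, 1..max) across all chromosomes
.pairs_per_distance <- function(genome, max_distance) {
  res <- genome$resolution
  nb <- n_bins(genome)
  dmax <- min(max_distance %/% res, max(nb) - 1)
  if (dmax < 1) return(stats::setNames(numeric(0), character(0)))
  k <- seq_len(dmax)
  counts <- vapply(k, function(d) sum(pmax(0, nb - d)), 0)
  stats::setNames(counts, as.character(k * res))
}

#' Estimate the distance-decay expected count profile
#'
#' The expected count for a bin pair at genomic distance d is the mean
#' observed count over every possible intrachromosomal pair at that
#' distance (zero pairs included). With \code{smooth = TRUE}, distances are
#' grouped into log-spaced bands holding at least \code{min_pairs_per_band}
#' possible pairs, band means are interpolated linearly in log-distance, and
#' the profile is rescaled so that the implied total read-pair count equals
#' the observed total (the expectation preserves the matrix total exactly).
#'
#' @param cm A \code{\link{count_matrix}} with a positive total.
#' @param smooth Smooth across log-spaced distance bands (default TRUE).
#' @param min_pairs_per_band Minimum possible pairs per band (default 100).
#' @return Object of class \code{decay_profile}: expected count per distance.
#' @export
estimate_expected <- function(cm, smooth = TRUE, min_pairs_per_band = 100) {
  if (cm$total <= 0) stop("count matrix is empty")
  res <- cm$resolution
  npairs <- .pairs_per_distance(cm$genome, cm$max_distance)
  if (!length(npairs)) stop("no valid bin-pair distances in the genome")
  d <- as.numeric(names(npairs))
  obs_d <- cm$pairs$start2 - cm$pairs$start1
  keep <- obs_d >= res & obs_d <= max(d)
  sums <- rep(0, length(d))
  if (any(keep)) {
    agg <- rowsum(cm$pairs$count[keep], group = obs_d[keep])
    sums[match(as.numeric(rownames(agg)), d)] <- agg[, 1]
  }
  raw <- sums / npairs
  if (!smooth || length(d) < 3) {
    expected <- raw
  } else {
    band <- integer(length(d))
    bi <- 1L
    acc <- 0
    for (i in seq_along(d)) {
      band[i] <- bi
      acc <- acc + npairs[i]
      if (acc >= min_pairs_per_band) {
        bi <- bi + 1L
        acc <- 0
      }
    }
    # fold a trailing underfull band into its predecessor
    if (acc > 0 && bi > 1L) band[band == bi] <- bi - 1L
    bsum <- rowsum(sums, band)[, 1]
    bn <- rowsum(as.numeric(npairs), band)[, 1]
    bmean <- bsum / bn
    # band centers: mean log-distance weighted by possible pairs
    blog <- rowsum(log(d) * as.numeric(npairs), band)[, 1] / bn
    if (length(bmean) == 1) {
      expected <- rep(bmean, length(d))
    } else {
      expected <- stats::approx(blog, bmean, xout = log(d), rule = 2)$y
    }
    tot <- sum(expected * npairs)
    if (tot > 0) expected <- expected * sum(sums) / tot
  }
  structure(list(distance = d, expected = expected, npairs = npairs,
                 resolution = res, total = cm$total),
            class = "decay_profile")
}

#' Expected count at given genomic distances
#'
#' Distances beyond the profile's range are clamped to the nearest covered
#' distance (orthologous pairs can sit farther apart in one assembly than
#' the other when they straddle a rearrangement).
#'
#' @param profile A \code{decay_profile} from \code{\link{estimate_expected}}.
#' @param distance Vector of distances (multiples of the resolution).
#' @return Numeric vector of expected counts.
#' @export
expected_at <- function(profile, distance) {
  .assert_on_grid(distance, profile$resolution, "distance")
  distance <- pmin(pmax(distance, min(profile$distance)),
                   max(profile$distance))
  profile$expected[match(distance, profile$distance)]
}

#' Call significant contacts with a cumulative binomial test
#'
#' For each observed bin pair, the null is that its count is binomially
#' distributed with the library's total read pairs N and success probability
#' expected/N taken from the distance-decay profile. The p-value is the
#' upper tail P(X >= observed); pairs with p <= alpha are retained
#' (inclusive threshold, no multiple-testing correction).
#'
#' @param cm A \code{\link{count_matrix}}.
#' @param profile Matching \code{decay_profile}.
#' @param alpha Significance threshold (default 0.01).
#' @param pseudocount Pseudocount for the log2 observed:expected frequency.
#' @return data.frame of retained pairs with columns \code{chrom},
#'   \code{start1}, \code{start2}, \code{obs}, \code{expected}, \code{p},
#'   \code{freq}.
#' @export
call_contacts <- function(cm, profile, alpha = 0.01, pseudocount = 0.5) {
  p <- cm$pairs
  d <- p$start2 - p$start1
  keep <- d >= cm$resolution & d <= max(profile$distance)
  p <- p[keep, , drop = FALSE]
  d <- d[keep]
  expd <- expected_at(profile, d)
  if (any(expd > cm$total)) stop("expected count exceeds library total")
  pv <- stats::pbinom(p$count - 1, size = cm$total, prob = expd / cm$total,
                      lower.tail = FALSE)
  out <- data.frame(chrom = p$chrom, start1 = p$start1, start2 = p$start2,
                    obs = p$count, expected = expd, p = pv,
                    freq = normalized_frequency(p$count, expd, pseudocount))
  out[out$p <= alpha, , drop = FALSE]
}

#' Log2 observed:expected contact frequency
#'
#' @param obs Observed counts.
#' @param expected Expected counts (same length or scalar).
#' @param pseudocount Added to both numerator and denominator; must be
#'   positive when any expected value is 0.
#' @return log2((obs + pseudocount) / (expected + pseudocount)).
#' @export
normalized_frequency <- function(obs, expected, pseudocount = 0.5) {
  if (any(expected < 0)) stop("expected must be non-negative")
  if (pseudocount == 0 && any(expected == 0)) {
    stop("pseudocount must be positive when expected is 0")
  }
  log2((obs + pseudocount) / (expected + pseudocount))
}

#' Normalized frequencies for an arbitrary set of bin pairs
#'
#' Looks up the observed count for each requested pair (0 when absent from
#' the sparse matrix) and returns the log2 observed:expected frequency.
#'
#' @param cm A \code{\link{count_matrix}}.
#' @param profile Matching \code{decay_profile}.
#' @param pairs data.frame with \code{chrom}, \code{start1}, \code{start2}.
#' @param pseudocount Pseudocount for the log ratio.
#' @return data.frame \code{pairs} plus \code{obs}, \code{expected},
#'   \code{freq}.
#' @export
pair_frequencies <- function(cm, profile, pairs, pseudocount = 0.5) {
  key <- paste(pairs$chrom, pmin(pairs$start1, pairs$start2),
               pmax(pairs$start1, pairs$start2), sep = ":")
  mkey <- paste(cm$pairs$chrom, cm$pairs$start1, cm$pairs$start2, sep = ":")
  obs <- cm$pairs$count[match(key, mkey)]
  obs[is.na(obs)] <- 0
  d <- abs(pairs$start2 - pairs$start1)
  expd <- expected_at(profile, d)
  data.frame(pairs, obs = obs, expected = expd,
             freq = normalized_frequency(obs, expd, pseudocount))
}

#' Filter a contact table by discovery count
#'
#' Keeps pairs independently called significant in at least
#' \code{min_individuals} individuals (inclusive).
#'
#' @param table data.frame with a \code{discovery_count} column.
#' @param min_individuals Minimum discovery count (default 4).
#' @return Filtered data.frame.
#' @export
filter_by_discovery <- function(table, min_individuals = 4) {
  if (!nrow(table)) return(table)
  stopifnot("discovery_count" %in% names(table))
  out <- table[table$discovery_count >= min_individuals, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Across-individual frequency variance, summarized by discovery count
#'
#' Computes, for each contact, the sample variance of its normalized
#' frequency across individuals, then summarizes the variances per
#' discovery-count bin with boxplot statistics.
#'
#' @param table data.frame with a \code{discovery_count} column.
#' @param freq Numeric matrix (contacts x individuals) of frequencies.
#' @return data.frame with one row per discovery count: \code{n},
#'   \code{mean_var}, and boxplot stats \code{lo}, \code{q1}, \code{median},
#'   \code{q3}, \code{hi}.
#' @export
variance_by_discovery <- function(table, freq) {
  stopifnot(nrow(table) == nrow(freq), ncol(freq) >= 2)
  v <- .row_vars(freq)
  out <- lapply(split(v, table$discovery_count), function(z) {
    bs <- grDevices::boxplot.stats(z)$stats
    data.frame(n = length(z), mean_var = mean(z), lo = bs[1], q1 = bs[2],
               median = bs[3], q3 = bs[4], hi = bs[5])
  })
  res <- do.call(rbind, out)
  res <- cbind(discovery_count = as.integer(names(out)), res)
  rownames(res) <- NULL
  res[order(res$discovery_count), ]
}

#' Cyclic loess normalization across individuals
#'
#' Removes smooth intensity-dependent differences between samples by
#' iterating pairwise MA-curve (loess) normalization over all sample pairs
#' until the largest per-contact adjustment falls below \code{tol} or
#' \code{max_iter} cycles are reached. The smoothing itself is delegated to
#' \code{limma::normalizeCyclicLoess} with \code{method = "pairs"}.
#'
#' @param x Numeric matrix (contacts x individuals) of log2 frequencies
#'   with at least 2 columns and 50 rows.
#' @param span Loess span (default 0.3).
#' @param tol Convergence tolerance on the max per-contact adjustment.
#' @param max_iter Maximum number of cycles (default 10).
#' @return Normalized matrix of the same dimensions.
#' @export
cyclic_loess_normalize <- function(x, span = 0.3, tol = 1e-3, max_iter = 10) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (nrow(x) < 50) stop("need at least 50 contacts for loess normalization")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    warning("constant column(s); returning input unchanged")
    return(x)
  }
  cur <- x
  for (i in seq_len(max_iter)) {
    nxt <- limma::normalizeCyclicLoess(cur, span = span, iterations = 1,
                                       method = "pairs")
    delta <- max(abs(nxt - cur))
    cur <- nxt
    if (delta < tol) break
  }
  dimnames(cur) <- dimnames(x)
  cur
}
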