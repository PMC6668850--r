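#' Base-pair overlap of loci with a chromatin-state annotation track
#'
#' @param loci data.frame of bins with \code{chrom}, \code{start},
#'   \code{end}.
#' @param states data.frame of annotation segments with \code{chrom},
#'   \code{start}, \code{end}, \code{state}.
#' @return Numeric matrix (loci x states) of overlap in base pairs.
#' @export
state_overlaps <- function(loci, states) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(states)))
  vocab <- sort(unique(states$state))
  out <- matrix(0, nrow(loci), length(vocab),
                dimnames = list(NULL, vocab))
  hits <- .chrom_overlaps(loci, states, maxgap = -1L)
  if (nrow(hits)) {
    ov <- pmin(loci$end[hits$qi], states$end[hits$si]) -
      pmax(loci$start[hits$qi], states$start[hits$si])
    for (k in seq_len(nrow(hits))) {
      s <- states$state[hits$si[k]]
      out[hits$qi[k], s] <- out[hits$qi[k], s] + ov[k]
    }
  }
  out
}

#' Per-state weights from mean overlaps
#'
#' The weight of a state is the reciprocal of its mean base-pair overlap
#' across all loci where it overlaps at all, correcting for states whose
#' segments are systematically long (e.g. quiescent chromatin) dominating
#' raw-overlap assignment. States with zero mean overlap are excluded with
#' a warning.
#'
#' @param overlaps Matrix from \code{\link{state_overlaps}} computed over
#'   the full locus set (compute weights before any subsetting).
#' @return Named numeric vector of weights (NA for excluded states).
#' @export
state_weights <- function(overlaps) {
  means <- apply(overlaps, 2, function(z) {
    z <- z[z > 0]
    if (!length(z)) return(0)
    mean(z)
  })
  w <- 1 / means
  if (any(means == 0)) {
    warning("state(s) with zero mean overlap excluded: ",
            paste(names(means)[means == 0], collapse = ", "))
    w[means == 0] <- NA_real_
  }
  w
}

#' Assign each locus a single chromatin state
#'
#' In raw mode the state with the largest base-pair overlap wins; in
#' weighted mode overlaps are first multiplied by the per-state weights from
#' \code{\link{state_weights}}. Ties are broken by larger raw overlap, then
#' lexicographically by state name. Loci with no overlapping annotation are
#' assigned \code{"."}.
#'
#' @param overlaps Matrix from \code{\link{state_overlaps}}.
#' @param mode \code{"weighted"} (default) or \code{"raw"}.
#' @param weights Per-state weights; computed from \code{overlaps} when
#'   omitted. Pass weights computed on the full locus set when assigning a
#'   subset.
#' @return Character vector of state assignments.
#' @export
assign_states <- function(overlaps, mode = c("weighted", "raw"),
                          weights = NULL) {
  mode <- match.arg(mode)
  score <- overlaps
  if (mode == "weighted") {
    w <- weights %||% state_weights(overlaps)
    stopifnot(identical(names(w), colnames(overlaps)))
    score <- sweep(overlaps, 2, ifelse(is.na(w), 0, w), "*")
  }
  vocab <- colnames(overlaps)
  apply_one <- function(i) {
    s <- score[i, ]
    if (all(s <= 0)) return(".")
    best <- which(s == max(s))
    if (length(best) > 1) {
      raw <- overlaps[i, best]
      best <- best[raw == max(raw)]
    }
    vocab[min(best)]   # lexicographic: vocab is sorted
  }
  vapply(seq_len(nrow(overlaps)), apply_one, "")
}

#' Cumulative state proportions over ranked loci
#'
#' Orders loci by ascending differential-contact FDR, starts with the top
#' \code{start} loci, and repeatedly adds the next \code{step} loci,
#' recomputing per-state proportions (including \code{"."}) at each step.
#' When a stratum holds fewer than \code{start} loci a single step over all
#' of them is emitted.
#'
#' @param assignment State assignment per locus.
#' @param q Differential-contact q-value per locus (ranking key).
#' @param start Size of the initial set (default 10).
#' @param step Loci added per step (default 2).
#' @param strata Optional factor of locus strata (e.g. promoter classes);
#'   curves are computed within each stratum.
#' @return data.frame with \code{stratum}, \code{n} (set size),
#'   \code{state}, \code{proportion}.
#' @export
cumulative_state_proportions <- function(assignment, q, start = 10, step = 2,
                                         strata = NULL) {
  stopifnot(length(assignment) == length(q))
  strata <- strata %||% rep("all", length(q))
  vocab <- sort(unique(assignment))
  out <- list()
  for (st in unique(strata)) {
    sel <- strata == st
    a <- assignment[sel][order(q[sel])]
    n <- length(a)
    sizes <- if (n <= start) n else unique(c(seq(start, n, by = step), n))
    for (sz in sizes) {
      tab <- table(factor(a[seq_len(sz)], levels = vocab)) / sz
      out[[length(out) + 1]] <- data.frame(stratum = st, n = sz,
                                           state = names(tab),
                                           proportion = as.numeric(tab))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify loci by differential-contact and differential-expression status
#'
#' @param dc Logical: locus is differentially contacting.
#' @param de Logical: locus is linked to a differentially expressed gene.
#' @return Factor with levels \code{"DC&DE"}, \code{"DC only"},
#'   \code{"DE only"}, \code{"neither"}.
#' @export
classify_loci <- function(dc, de) {
  stopifnot(length(dc) == length(de))
  lab <- ifelse(dc & de, "DC&DE",
                ifelse(dc, "DC only", ifelse(de, "DE only", "neither")))
  factor(lab, levels = c("DC&DE", "DC only", "DE only", "neither"))
}

#' Pairwise comparisons of histone-mark overlap between locus classes
#'
#' Welch two-sample t-tests of per-locus base-pair overlap with a mark for
#' every pair of locus classes. Pairs involving a class with fewer than two
#' loci, or with no variance on either side, are reported as NA. No
#' multiple-testing correction is applied across pairs.
#'
#' @param overlap_bp Numeric vector of per-locus overlap (deduplicate loci
#'   first).
#' @param class Factor of locus classes.
#' @return data.frame with one row per class pair: group sizes, means,
#'   \code{t}, \code{p}.
#' @export
overlap_class_tests <- function(overlap_bp, class) {
  stopifnot(length(overlap_bp) == length(class))
  cls <- levels(factor(class))
  pairs <- utils::combn(cls, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- overlap_bp[class == pairs[1, k]]
    b <- overlap_bp[class == pairs[2, k]]
    tt <- if (length(a) >= 2 && length(b) >= 2) {
      tryCatch(stats::t.test(a, b), error = function(e) NULL)
    } else NULL
    data.frame(class1 = pairs[1, k], class2 = pairs[2, k],
               n1 = length(a), n2 = length(b),
               mean1 = if (length(a)) mean(a) else NA_real_,
               mean2 = if (length(b)) mean(b) else NA_real_,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  do.call(rbind, rows)
}
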