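#' Reads per kilobase per million mapped reads
#'
#' @param counts Read counts (vector or matrix of genes x individuals).
#' @param length Gene lengths in base pairs (recycled along rows).
#' @param library_size Mapped reads per individual (scalar, or vector
#'   recycled along columns for a matrix).
#' @return RPKM values with the shape of \code{counts}.
#' @export
rpkm <- function(counts, length, library_size) {
  if (any(length <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  if (is.matrix(counts)) {
    sweep(counts / (length / 1e3), 2, library_size / 1e6, "/")
  } else {
    counts / (length / 1e3) / (library_size / 1e6)
  }
}

#' log2 RPKM with a pseudocount
#'
#' @inheritParams rpkm
#' @param pseudocount Added to the RPKM inside the log (default 0.5).
#' @return log2(RPKM + pseudocount).
#' @export
log2_rpkm <- function(counts, length, library_size, pseudocount = 0.5) {
  log2(rpkm(counts, length, library_size) + pseudocount)
}

#' Filter genes by expression level in both species
#'
#' A gene is retained when at least \code{min_per_species} individuals in
#' each species have log2 RPKM at or above \code{threshold} (inclusive).
#'
#' @param x Numeric matrix of log2 RPKM (genes x individuals).
#' @param species Species label (two levels) per individual.
#' @param threshold Expression threshold (default 0.4 log2 RPKM).
#' @param min_per_species Minimum passing individuals per species
#'   (default 2).
#' @return Logical vector: gene retained.
#' @export
expression_filter <- function(x, species, threshold = 0.4,
                              min_per_species = 2) {
  stopifnot(ncol(x) == length(species))
  sp <- unique(species)
  stopifnot(length(sp) == 2)
  pass <- x >= threshold
  n1 <- rowSums(pass[, species == sp[1], drop = FALSE])
  n2 <- rowSums(pass[, species == sp[2], drop = FALSE])
  n1 >= min_per_species & n2 >= min_per_species
}

#' Differential expression test across species
#'
#' Per-gene ordinary least squares fit of log2 RPKM on species and sex, with
#' a two-sided t-test on the species effect and Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param x Numeric matrix of log2 RPKM (genes x individuals).
#' @param design A \code{\link{study_design}} with at least a species
#'   column (sex used when present; batch columns are also honoured).
#' @return data.frame with \code{beta_sp}, \code{t}, \code{p}, \code{q}.
#' @export
de_test <- function(x, design) {
  stopifnot(ncol(x) == nrow(design))
  fit <- .ols_fit(x, design, coef = "species")
  data.frame(gene = rownames(x) %||% seq_len(nrow(x)),
             beta_sp = fit$coefficients[, "species"],
             t = fit$t, p = fit$p, q = bh_adjust(fit$p))
}

#' Link genes to contacts through their TSS bin
#'
#' Each gene is assigned to the resolution bin containing its transcription
#' start site proxy (a single base pair at the start of the first exon).
#' Among union contacts anchored at that bin, the contact with the smallest
#' species-term FDR represents the gene; ties are broken by larger absolute
#' species effect, then smaller genomic distance. Genes whose TSS bin
#' anchors no contact are excluded.
#'
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{tss}
#'   (assembly-A coordinates).
#' @param contacts Union contact table (assembly-A coordinates) with
#'   columns \code{chrom_a}, \code{start1_a}, \code{start2_a}, \code{q},
#'   \code{beta_sp}, \code{dist_a}.
#' @param resolution Bin size in base pairs.
#' @return list with \code{linked} (genes plus \code{contact_idx},
#'   \code{dc_q}, \code{dc_beta}) and \code{n_unlinked}.
#' @export
link_genes_to_contacts <- function(genes, contacts, resolution = 10000) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(genes)))
  bin <- floor(genes$tss / resolution) * resolution
  key1 <- paste(contacts$chrom_a, contacts$start1_a, sep = ":")
  key2 <- paste(contacts$chrom_a, contacts$start2_a, sep = ":")
  gkey <- paste(genes$chrom, bin, sep = ":")
  anchor_idx <- split(rep(seq_len(nrow(contacts)), 2), c(key1, key2))
  hits <- anchor_idx[gkey]
  pick <- vapply(hits, function(ix) {
    if (is.null(ix)) return(NA_integer_)
    ix <- unique(ix)
    o <- order(contacts$q[ix], -abs(contacts$beta_sp[ix]), contacts$dist_a[ix])
    ix[o[1]]
  }, 1L)
  out <- genes
  out$tss_bin <- bin
  out$contact_idx <- pick
  out$dc_q <- contacts$q[pick]
  out$dc_beta <- contacts$beta_sp[pick]
  list(linked = out[!is.na(pick), , drop = FALSE],
       n_unlinked = sum(is.na(pick)))
}

#' Weighted combination of p-values (Stouffer's method)
#'
#' Combines the p-values of all contacts anchored at a locus into a single
#' p-value for the null that none of them differs between species:
#' Z = sum(w * qnorm(1 - p)) / sqrt(sum(w^2)), combined p = 1 - pnorm(Z).
#' Equal weights by default.
#'
#' @param p Vector of p-values in (0, 1]; zeros are clipped to the machine
#'   minimum with a warning.
#' @param weights Positive weights (default equal).
#' @return Combined p-value.
#' @export
combine_pvalues_weighted <- function(p, weights = NULL) {
  if (!length(p)) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clipped to machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  w <- weights %||% rep(1, length(p))
  if (any(w <= 0)) stop("weights must be positive")
  z <- sum(w * stats::qnorm(1 - p)) / sqrt(sum(w^2))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Chi-squared enrichment sweep of differential expression in differential
#' contacts
#'
#' For every combination of a differential-contact (DC) FDR cutoff and a
#' differential-expression (DE) FDR cutoff, cross-tabulates linked genes by
#' DC and DE status and computes Pearson's chi-squared statistic (1 df, no
#' continuity correction), together with the proportion DE among DC genes
#' and the baseline proportion DE among all linked genes ("expected by
#' chance"). Swap the two q-value arguments for the reciprocal sweep (DC
#' enrichment among DE genes).
#'
#' @param dc_q DC q-value per linked gene.
#' @param de_q DE q-value per linked gene.
#' @param dc_grid DC FDR cutoffs; by default the sorted unique dc_q values
#'   within [0.01, 0.25].
#' @param de_cuts DE FDR cutoffs (default 0.01, 0.025, 0.05, 0.075, 0.10).
#' @return data.frame with one row per (dc_fdr, de_fdr) cell: counts,
#'   \code{prop_de_in_dc}, \code{baseline}, \code{chisq}, \code{p} (NA when
#'   a table margin is zero).
#' @export
enrichment_sweep <- function(dc_q, de_q, dc_grid = NULL,
                             de_cuts = c(0.01, 0.025, 0.05, 0.075, 0.10)) {
  stopifnot(length(dc_q) == length(de_q))
  if (is.null(dc_grid)) {
    dc_grid <- sort(unique(dc_q[dc_q >= 0.01 & dc_q <= 0.25]))
    if (!length(dc_grid)) dc_grid <- 0.05
  }
  rows <- list()
  for (dc in dc_grid) {
    is_dc <- dc_q <= dc
    for (de in de_cuts) {
      is_de <- de_q <= de
      n11 <- sum(is_dc & is_de); n10 <- sum(is_dc & !is_de)
      n01 <- sum(!is_dc & is_de); n00 <- sum(!is_dc & !is_de)
      tab <- matrix(c(n11, n01, n10, n00), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        chisq <- NA_real_; pv <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chisq <- unname(ct$statistic); pv <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        dc_fdr = dc, de_fdr = de, n_dc = n11 + n10, n_de = n11 + n01,
        n_dc_de = n11, n = length(dc_q),
        prop_de_in_dc = if (n11 + n10 > 0) n11 / (n11 + n10) else NA_real_,
        baseline = mean(is_de), chisq = chisq, p = pv)
    }
  }
  do.call(rbind, rows)
}

#' Per-gene correlation between expression and linked contact frequency
#'
#' Pearson correlation across individuals between each gene's log2 RPKM and
#' the normalized frequency of its linked contact, with a permutation null
#' built by shuffling individual labels.
#'
#' @param expr Numeric matrix (genes x individuals) of log2 RPKM.
#' @param freq Numeric matrix (genes x individuals) of contact frequencies,
#'   rows matched to \code{expr}.
#' @param n_perm Number of permutations for the null (default 10).
#' @param mode \code{"global"} permutes the same individual relabelling for
#'   all genes; \code{"within_gene"} permutes each gene independently.
#' @param seed Optional RNG seed.
#' @return list with \code{r} (per-gene correlation, NA for zero-variance
#'   series) and \code{perm} (genes x n_perm matrix of null correlations).
#' @export
contact_expression_correlation <- function(expr, freq, n_perm = 10,
                                           mode = c("global", "within_gene"),
                                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(expr), dim(freq)), ncol(expr) >= 3)
  if (!is.null(seed)) set.seed(seed)
  row_cor <- function(a, b) {
    va <- .row_vars(a); vb <- .row_vars(b)
    vapply(seq_len(nrow(a)), function(i) {
      if (va[i] == 0 || vb[i] == 0) NA_real_ else stats::cor(a[i, ], b[i, ])
    }, 0)
  }
  r <- row_cor(expr, freq)
  perm <- matrix(NA_real_, nrow(expr), n_perm)
  n <- ncol(expr)
  for (k in seq_len(n_perm)) {
    if (mode == "global") {
      perm[, k] <- row_cor(expr, freq[, sample.int(n), drop = FALSE])
    } else {
      shuffled <- t(apply(freq, 1, function(z) z[sample.int(n)]))
      perm[, k] <- row_cor(expr, shuffled)
    }
  }
  list(r = r, perm = perm)
}
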