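#' Run the full comparative analysis on a simulated (or assembled) study
#'
#' End-to-end driver mirroring the intended analysis of a two-species Hi-C +
#' expression study: per-individual contact calling against a distance-decay
#' binomial null, reciprocal-best-hits union of orthologous contacts,
#' frequency extraction and cyclic loess normalization, discovery-count and
#' mate-pair-distance filtering, per-contact linear modeling of the species
#' effect with BH FDR, per-chromosome asymmetry tests, TAD/boundary
#' conservation, differential expression, gene-contact linking with the
#' chi-squared enrichment sweep, contact-expression correlation, and the
#' mediation screen over differentially expressed genes.
#'
#' @param sim A study as returned by \code{\link{simulate_study}}.
#' @param alpha Per-individual contact-calling p-value threshold
#'   (default 0.01).
#' @param min_individuals Discovery-count filter (default 4).
#' @param fdr FDR threshold for differential contacts (default 0.05).
#' @param de_fdr FDR threshold for differential expression (default 0.05).
#' @param max_dist_diff Mate-pair-distance difference filter in base pairs
#'   (default 20000).
#' @param expr_threshold log2 RPKM expression filter threshold (default 0.4).
#' @param mc_draws Monte Carlo draws per gene in the mediation screen.
#' @param pseudocount Pseudocount for log2 observed:expected frequencies.
#' @param stages Character vector of optional stages to run in addition to
#'   the core contact analysis: any of \code{"tads"}, \code{"expression"},
#'   \code{"mediation"}, \code{"correlation"} (all by default).
#'   \code{"mediation"} and \code{"correlation"} imply \code{"expression"}.
#' @return list with the intermediate and final tables of every stage (see
#'   the package vignette for a walk-through).
#' @export
analyze_study <- function(sim, alpha = 0.01, min_individuals = 4,
                          fdr = 0.05, de_fdr = 0.05, max_dist_diff = 20000,
                          expr_threshold = 0.4, mc_draws = 5000,
                          pseudocount = 0.5,
                          stages = c("tads", "expression", "mediation",
                                     "correlation")) {
  if (any(c("mediation", "correlation") %in% stages)) {
    stages <- union(stages, "expression")
  }
  inds <- sim$hic$individuals
  design <- sim$hic$design
  res <- sim$config$resolution

  # 1. per-individual expectation + significant-contact calls
  profiles <- lapply(inds, function(x) estimate_expected(x$counts))
  calls <- lapply(seq_along(inds), function(i) {
    cc <- call_contacts(inds[[i]]$counts, profiles[[i]], alpha = alpha,
                        pseudocount = pseudocount)
    list(assembly = inds[[i]]$assembly,
         pairs = cc[, c("chrom", "start1", "start2")])
  })
  names(calls) <- names(inds)

  # 2. orthologous union across individuals
  union <- build_union_contacts(calls, sim$map, res)
  contacts <- union$contacts

  # 3. per-individual normalized frequencies for every union pair
  freq_tables <- lapply(seq_along(inds), function(i) {
    if (inds[[i]]$assembly == "A") {
      pairs <- data.frame(chrom = contacts$chrom_a,
                          start1 = contacts$start1_a,
                          start2 = contacts$start2_a)
    } else {
      pairs <- data.frame(chrom = contacts$chrom_b,
                          start1 = pmin(contacts$start1_b, contacts$start2_b),
                          start2 = pmax(contacts$start1_b, contacts$start2_b))
    }
    pf <- pair_frequencies(inds[[i]]$counts, profiles[[i]], pairs,
                           pseudocount)
    list(assembly = inds[[i]]$assembly,
         freq = pf[, c("chrom", "start1", "start2", "freq")])
  })
  names(freq_tables) <- names(inds)
  freq <- attach_frequencies(contacts, freq_tables)

  # 4. cross-sample normalization
  freq_norm <- cyclic_loess_normalize(freq)

  # 5. discovery-count filter, then mate-pair-distance filter
  keep1 <- contacts$discovery_count >= min_individuals
  contacts <- contacts[keep1, , drop = FALSE]
  freq_norm <- freq_norm[keep1, , drop = FALSE]
  mf <- matepair_distance_filter(contacts, max_dist_diff)
  keep2 <- abs(contacts$dist_a - contacts$dist_b) <= max_dist_diff
  contacts <- mf$kept
  freq_norm <- freq_norm[keep2, , drop = FALSE]

  # 6. per-contact linear model + FDR
  fit <- fit_contact_model(freq_norm, design)
  dc <- cbind(contacts, fit[, c("beta_sp", "p")])
  dc$q <- bh_adjust(dc$p)
  sig <- dc[dc$q <= fdr, , drop = FALSE]
  asym <- if (nrow(sig)) {
    chromosome_asymmetry_test(sig$chrom_a, sig$beta_sp)
  } else NULL

  # 7. TAD and boundary conservation (consensus + individuals)
  tad_cons <- NULL; bound_cons <- NULL; sharing <- NULL
  if ("tads" %in% stages) {
  cons_b_in_a <- transfer_intervals(sim$map, sim$tads$consensus_b, "BtoA")
  cons_b_in_a <- data.frame(chrom = cons_b_in_a$chrom_o[cons_b_in_a$mapped],
                            start = cons_b_in_a$start_o[cons_b_in_a$mapped],
                            end = cons_b_in_a$end_o[cons_b_in_a$mapped])
  tad_cons <- rbind(
    conservation_summary(sim$tads$consensus_a, cons_b_in_a, "reciprocal90"),
    conservation_summary(sim$tads$consensus_a, cons_b_in_a, "rao"))
  ind_bounds <- do.call(rbind, lapply(names(sim$tads$individual), function(id) {
    b <- boundaries_from_domains(sim$tads$individual[[id]],
                                 genome = sim$genomes$genome_a)
    b$sample <- id
    b
  }))
  species_of <- stats::setNames(ifelse(design$species == 1, "B", "A"),
                                rownames(design))
  bound_cons <- boundary_conservation(ind_bounds, species_of)
  sharing <- sharing_matrix(sim$tads$individual, "reciprocal90")
  }

  # 8. expression processing + DE
  l2r <- NULL; de <- NULL; linked <- NULL; enrich <- NULL; corr <- NULL
  mediation <- list(results = data.frame(), fraction_significant = NA_real_)
  if ("expression" %in% stages) {
  expr <- sim$expression
  l2r <- log2_rpkm(expr$counts, expr$lengths, expr$lib_size)
  keep_g <- expression_filter(l2r, design$species, threshold = expr_threshold)
  l2r <- l2r[keep_g, , drop = FALSE]
  de <- de_test(l2r, design)

  # 9. gene-contact linking, enrichment sweep, correlation
  genes <- sim$genes[match(rownames(l2r), sim$genes$gene), ]
  link <- link_genes_to_contacts(genes, dc, res)
  linked <- link$linked
  linked$de_q <- de$q[match(linked$gene, de$gene)]
  enrich <- enrichment_sweep(linked$dc_q, linked$de_q)
  if ("correlation" %in% stages) {
    corr <- contact_expression_correlation(
      l2r[linked$gene, , drop = FALSE],
      freq_norm[linked$contact_idx, , drop = FALSE])
  }

  # 10. mediation screen over linked DE genes
  if ("mediation" %in% stages) {
    med_genes <- linked[!is.na(linked$de_q) & linked$de_q <= de_fdr, ,
                        drop = FALSE]
    if (nrow(med_genes)) {
      mediation <- mediation_screen(
        l2r[med_genes$gene, , drop = FALSE],
        freq_norm[med_genes$contact_idx, , drop = FALSE],
        design$species, n_draws = mc_draws)
    }
  }
  }

  list(calls = calls, union = union, freq = freq_norm, dc = dc, sig = sig,
       asymmetry = asym, tad_conservation = tad_cons,
       boundary_conservation = bound_cons, sharing = sharing,
       log2rpkm = l2r, de = de, linked = linked, enrichment = enrich,
       correlation = corr, mediation = mediation,
       n_union = nrow(union$contacts), n_tested = nrow(dc),
       n_dc = nrow(sig),
       exclusion_fraction = union$exclusion_fraction)
}

#' Estimate species effects for planted contacts of a simulated study
#'
#' Validation utility for planted-effect recovery: extracts per-individual
#' normalized frequencies for every planted differential pair plus a set of
#' random null pairs, cyclic-loess normalizes across individuals, fits the
#' per-contact species model, and returns the estimates alongside the
#' planted truth.
#'
#' Cross-sample loess normalization is off by default here: it corrects
#' technical trends, but when a large fraction of the evaluated pairs carry
#' true signal its MA curve absorbs part of that signal, biasing recovery
#' estimates of the generator's planted effects.
#'
#' @param sim A study from \code{\link{simulate_study}} with planted
#'   differential contacts.
#' @param n_null Number of random unplanted pairs added to the evaluation
#'   set (default: 4x the planted count).
#' @param pseudocount Pseudocount for the log2 frequencies.
#' @param normalize Apply \code{\link{cyclic_loess_normalize}} before the
#'   model fit (default FALSE).
#' @return data.frame with \code{effect} (true planted log2 effect; 0 for
#'   null pairs) and \code{beta_sp} (estimated species effect).
#' @export
planted_effect_estimates <- function(sim, n_null = NULL, pseudocount = 0.5,
                                     normalize = FALSE) {
  planted <- sim$truth$planted_dc
  if (!nrow(planted)) stop("study has no planted differential contacts")
  uni <- .pair_universe(sim$genomes$genome_a, sim$config$max_distance)
  ukey <- paste(uni$chrom, uni$start1, uni$start2, sep = ":")
  res <- sim$config$resolution
  # null pairs: mappable, unplanted
  bm <- map_bin_rbh(sim$map, uni$chrom, uni$start1, res, "AtoB")
  bm2 <- map_bin_rbh(sim$map, uni$chrom, uni$start2, res, "AtoB")
  mappable <- bm$accepted & bm2$accepted
  pool <- which(mappable & !(ukey %in% planted$contact_id))
  n_null <- n_null %||% (4 * nrow(planted))
  nulls <- sample(pool, min(n_null, length(pool)))
  idx <- c(match(planted$contact_id, ukey), nulls)
  pairs_a <- uni[idx, , drop = FALSE]
  b1 <- map_bin_rbh(sim$map, pairs_a$chrom, pairs_a$start1, res, "AtoB")
  b2 <- map_bin_rbh(sim$map, pairs_a$chrom, pairs_a$start2, res, "AtoB")
  inds <- sim$hic$individuals
  freq <- sapply(inds, function(ind) {
    prof <- estimate_expected(ind$counts)
    if (ind$assembly == "A") {
      p <- pairs_a
    } else {
      p <- data.frame(chrom = b1$chrom, start1 = pmin(b1$start, b2$start),
                      start2 = pmax(b1$start, b2$start))
    }
    pair_frequencies(ind$counts, prof, p, pseudocount)$freq
  })
  if (normalize) freq <- cyclic_loess_normalize(freq)
  fit <- fit_contact_model(freq, sim$hic$design)
  data.frame(effect = c(planted$effect, rep(0, length(nulls))),
             beta_sp = fit$beta_sp)
}
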