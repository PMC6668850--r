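#' Configuration of a synthetic two-species study
#'
#' Defines the study conditions emulated by the generator: a balanced
#' design of \code{n_per_species} individuals per species with alternating
#' sex and two processing batches, distance-decay Hi-C counts at a fixed
#' resolution, planted species effects on a fraction of contacts, TAD block
#' structure with a configurable cross-species shared fraction, genome
#' rearrangements (inversions and deletions) in the orthology map,
#' expression optionally driven by contact frequency (mediation), and a
#' multi-state annotation track.
#'
#' @param n_per_species Individuals per species (default 4).
#' @param chrom_lengths Named vector of assembly-A chromosome lengths.
#' @param resolution Bin size in base pairs (default 10000).
#' @param rearrangements List of rearrangements, each
#'   \code{list(type = "inversion"|"deletion", chrom, start, end)} with
#'   grid-aligned, non-overlapping intervals.
#' @param depth Read pairs per individual (default 1e6).
#' @param decay Distance-decay exponent: expected count proportional to
#'   d^(-decay) (default 1).
#' @param max_distance Maximum simulated bin-pair distance (default 2 Mb).
#' @param loop_frac Fraction of orthologous pairs that are elevated
#'   "loop" contacts, enriched by \code{loop_boost} in both species
#'   (default 0.05). These emulate the called-contact layer of real maps.
#' @param loop_boost Multiplicative enrichment of loop pairs (default 4).
#' @param frac_dc Fraction of loop contacts carrying a planted species
#'   effect on top of the shared enrichment (default 0.1).
#' @param dc_effect Magnitude of planted effects in log2 units; the sign is
#'   drawn at random per contact (default 2).
#' @param count_model \code{"multinomial"} (library total fixed at
#'   \code{depth}) or \code{"poisson"}.
#' @param tad_boost Multiplicative within-domain contact enrichment
#'   (default 2).
#' @param tad_shared Fraction of domains present in both species
#'   (default 0.5).
#' @param tad_size_range,tad_gap_range Domain size and inter-domain gap
#'   ranges in base pairs.
#' @param tad_detect Per-individual probability of detecting a consensus
#'   domain (default 0.9).
#' @param tad_jitter Per-edge probability of a one-bin placement jitter in
#'   an individual's domain call (default 0.2).
#' @param sex_effect_sd,batch_effect_sd SD of per-contact log2 sex and
#'   batch nuisance effects (default 0.1 each, so the model covariates are
#'   non-degenerate).
#' @param n_genes Number of genes (default 300).
#' @param n_mediation Genes whose expression is driven by a planted
#'   differential contact (default 50).
#' @param med_beta Contact-to-expression effect for mediation genes
#'   (default 1).
#' @param de_frac Fraction of non-mediation genes with a planted direct
#'   species effect on expression (default 0.1).
#' @param de_effect Magnitude of planted expression effects, log2 units.
#' @param expr_noise_sd SD of expression noise, log2 units (default 0.3).
#' @param expr_base_mean,expr_base_sd Baseline log2 RPKM distribution.
#' @param lib_size RNA library size per individual (default 1e6).
#' @param state_freqs Named vector of annotation state frequencies (must
#'   sum to 1).
#' @param state_mean_len Mean annotation segment length in base pairs.
#' @param seed Integer RNG seed recorded in every output header.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_per_species = 4,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       resolution = 10000,
                       rearrangements = list(
                         list(type = "inversion", chrom = "chr1",
                              start = 2e6, end = 3e6),
                         list(type = "deletion", chrom = "chr2",
                              start = 3e6, end = 3.5e6)),
                       depth = 1e6, decay = 1, max_distance = 2e6,
                       loop_frac = 0.05, loop_boost = 4,
                       frac_dc = 0.1, dc_effect = 2,
                       count_model = c("multinomial", "poisson"),
                       tad_boost = 2, tad_shared = 0.5,
                       tad_size_range = c(2e5, 8e5),
                       tad_gap_range = c(0, 1e5),
                       tad_detect = 0.9, tad_jitter = 0.2,
                       sex_effect_sd = 0.1, batch_effect_sd = 0.1,
                       n_genes = 300, n_mediation = 50, med_beta = 1,
                       de_frac = 0.1, de_effect = 2, expr_noise_sd = 0.3,
                       expr_base_mean = 3, expr_base_sd = 1, lib_size = 1e6,
                       state_freqs = c(TssA = 0.05, Enh = 0.15, Tx = 0.2,
                                       Quies = 0.6),
                       state_mean_len = 5000, seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- as.list(environment())
  if (cfg$depth <= 0) stop("library depth must be positive")
  for (p in c("frac_dc", "loop_frac", "tad_shared", "tad_detect",
              "tad_jitter", "de_frac")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (any(state_freqs < 0)) stop("state frequencies must be non-negative")
  structure(cfg, class = "sim_config")
}

.config_digest <- function(config) {
  s <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
            .Machine$integer.max)
}

#' Simulate a pair of assemblies related by rearrangements
#'
#' Starts from an identity mapping of assembly A onto assembly B and applies
#' the configured rearrangements: deleted intervals are absent from B (all
#' downstream B coordinates shift), and inverted intervals map on the minus
#' strand with reversed offsets. The resulting orthology map covers all of A
#' except deleted intervals and is invertible outside them.
#'
#' @param spec A \code{\link{genome_spec}} for assembly A.
#' @param rearrangements List of \code{list(type, chrom, start, end)} with
#'   grid-aligned, in-bounds, non-overlapping intervals; \code{type} is
#'   \code{"inversion"} or \code{"deletion"}.
#' @return list with \code{genome_a}, \code{genome_b} and \code{map} (an
#'   \code{\link{orthology_map}}).
#' @export
simulate_genome_pair <- function(spec, rearrangements = list()) {
  res <- spec$resolution
  for (r in rearrangements) {
    if (!r$type %in% c("inversion", "deletion")) {
      stop("unknown rearrangement type: ", r$type)
    }
    if (!r$chrom %in% spec$chroms) stop("rearrangement on unknown chromosome")
    if (r$start < 0 || r$end > spec$lengths[[r$chrom]] || r$start >= r$end) {
      stop("rearrangement interval out of chromosome bounds")
    }
    .assert_on_grid(c(r$start, r$end), res, "rearrangement interval")
  }
  # overlapping rearrangements are a configuration error
  rdf <- if (length(rearrangements)) {
    data.frame(chrom = vapply(rearrangements, `[[`, "", "chrom"),
               start = vapply(rearrangements, function(r) r$start, 0),
               end = vapply(rearrangements, function(r) r$end, 0),
               type = vapply(rearrangements, `[[`, "", "type"))
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               type = character())
  }
  for (ch in unique(rdf$chrom)) {
    s <- rdf[rdf$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("rearrangements overlap on ", ch)
    }
  }
  blocks <- list()
  b_len <- stats::setNames(numeric(length(spec$chroms)), spec$chroms)
  for (ch in spec$chroms) {
    s <- rdf[rdf$chrom == ch, ]
    s <- s[order(s$start), ]
    cur_a <- 0
    cur_b <- 0
    emit <- function(sa, ea, strand) {
      len <- ea - sa
      blocks[[length(blocks) + 1]] <<- data.frame(
        chrom_a = ch, start_a = sa, end_a = ea,
        chrom_b = ch, start_b = cur_b, end_b = cur_b + len, strand = strand)
      cur_b <<- cur_b + len
    }
    for (i in seq_len(nrow(s))) {
      if (s$start[i] > cur_a) emit(cur_a, s$start[i], "+")
      if (s$type[i] == "inversion") emit(s$start[i], s$end[i], "-")
      cur_a <- s$end[i]
    }
    if (cur_a < spec$lengths[[ch]]) emit(cur_a, spec$lengths[[ch]], "+")
    b_len[ch] <- cur_b
  }
  keep <- b_len > 0
  genome_b <- genome_spec(names(b_len)[keep], b_len[keep], res)
  list(genome_a = spec, genome_b = genome_b,
       map = orthology_map(do.call(rbind, blocks)))
}

# sequential domain layout on assembly A with a planted shared fraction:
# each domain exists in both species (shared) or in exactly one.
.simulate_tad_truth <- function(genome, config) {
  res <- genome$resolution
  doms <- list()
  for (ch in genome$chroms) {
    len <- genome$lengths[[ch]]
    pos <- 0
    repeat {
      gap <- round_to_grid(stats::runif(1, config$tad_gap_range[1],
                                        config$tad_gap_range[2]), res)
      size <- round_to_grid(stats::runif(1, config$tad_size_range[1],
                                         config$tad_size_range[2]), res)
      if (pos + gap + size > len) break
      doms[[length(doms) + 1]] <- data.frame(chrom = ch, start = pos + gap,
                                             end = pos + gap + size)
      pos <- pos + gap + size
    }
  }
  d <- do.call(rbind, doms)
  u <- stats::runif(nrow(d))
  d$category <- ifelse(u < config$tad_shared, "shared",
                       ifelse(stats::runif(nrow(d)) < 0.5, "a_only", "b_only"))
  d$domain_id <- sprintf("tad%04d", seq_len(nrow(d)))
  d
}

# per-individual domain calls: consensus domains detected with probability
# tad_detect, edges jittered by one bin with probability tad_jitter
.individual_domains <- function(consensus, config, resolution) {
  keep <- stats::runif(nrow(consensus)) < config$tad_detect
  d <- consensus[keep, c("chrom", "start", "end"), drop = FALSE]
  jit <- function(x) {
    j <- stats::runif(length(x)) < config$tad_jitter
    x + ifelse(j, sample(c(-1, 1), length(x), replace = TRUE) * resolution, 0)
  }
  d$start <- pmax(0, jit(d$start))
  d$end <- pmax(d$start + resolution, jit(d$end))
  rownames(d) <- NULL
  d
}

#' Simulate TAD structure for both species
#'
#' Lays sequential domains along assembly A and plants each as shared by
#' both species or specific to one, per the configured shared fraction.
#' Species B domains are transferred to assembly-B coordinates through the
#' orthology map. Per-individual domain calls miss each consensus domain
#' with probability \code{1 - tad_detect} and jitter edges by one bin.
#'
#' @param genome_pair Output of \code{\link{simulate_genome_pair}}.
#' @param config A \code{\link{sim_config}}.
#' @param individuals Optional character vector of individual ids paired
#'   with a logical \code{species_b} vector of the same length, for
#'   per-individual calls.
#' @param species_b Logical per individual: belongs to species B.
#' @return list with \code{truth} (domains with category), \code{consensus_a},
#'   \code{consensus_b} (assembly-B coordinates), \code{consensus_b_in_a},
#'   and \code{individual} (named list of per-individual domain sets in
#'   assembly-A coordinates).
#' @export
simulate_tads <- function(genome_pair, config, individuals = NULL,
                          species_b = NULL) {
  truth <- .simulate_tad_truth(genome_pair$genome_a, config)
  res <- config$resolution
  cons_a <- truth[truth$category %in% c("shared", "a_only"),
                  c("chrom", "start", "end"), drop = FALSE]
  b_in_a <- truth[truth$category %in% c("shared", "b_only"),
                  c("chrom", "start", "end"), drop = FALSE]
  tr <- transfer_intervals(genome_pair$map, b_in_a, "AtoB", min_cover = 0.9)
  cons_b <- data.frame(chrom = tr$chrom_o[tr$mapped],
                       start = tr$start_o[tr$mapped],
                       end = tr$end_o[tr$mapped])
  b_in_a <- b_in_a[tr$mapped, , drop = FALSE]
  indiv <- NULL
  if (!is.null(individuals)) {
    stopifnot(length(individuals) == length(species_b))
    indiv <- stats::setNames(lapply(seq_along(individuals), function(i) {
      cons <- if (species_b[i]) b_in_a else cons_a
      .individual_domains(cons, config, res)
    }), individuals)
  }
  list(truth = truth, consensus_a = cons_a, consensus_b = cons_b,
       consensus_b_in_a = b_in_a, individual = indiv)
}

# enumerate the intrachromosomal pair universe of a genome up to max_distance
.pair_universe <- function(genome, max_distance) {
  res <- genome$resolution
  nb <- n_bins(genome)
  out <- list()
  for (ch in genome$chroms) {
    n <- nb[[ch]]
    dmax <- min(max_distance %/% res, n - 1)
    if (dmax < 1) next
    d <- unlist(lapply(seq_len(dmax), function(k) rep(k, n - k)))
    i <- unlist(lapply(seq_len(dmax), function(k) seq_len(n - k) - 1))
    out[[ch]] <- data.frame(chrom = ch, start1 = i * res,
                            start2 = (i + d) * res)
  }
  do.call(rbind, out)
}

# logical: both anchors of each pair inside a single domain
.within_domain <- function(pairs, domains) {
  if (is.null(domains) || !nrow(domains)) return(rep(FALSE, nrow(pairs)))
  out <- rep(FALSE, nrow(pairs))
  p1 <- data.frame(chrom = pairs$chrom, start = pairs$start1,
                   end = pairs$start2 + 1)
  hits <- .chrom_overlaps(p1, domains, maxgap = -1L)
  if (!nrow(hits)) return(out)
  inside <- pairs$start1[hits$qi] >= domains$start[hits$si] &
    pairs$start2[hits$qi] < domains$end[hits$si]
  out[unique(hits$qi[inside])] <- TRUE
  out
}

#' Simulate per-individual Hi-C contact count matrices
#'
#' Draws sparse intrachromosomal counts for every individual of the study.
#' Expected counts decay with genomic distance as d^(-decay); pairs within a
#' TAD of the individual's species receive a multiplicative enrichment; a
#' fraction of orthologous pairs are elevated "loop" contacts in both
#' species, and planted differential pairs -- drawn from the loops --
#' additionally receive a multiplicative 2^effect in species B; small
#' per-contact sex and batch effects are added multiplicatively.
#' With the multinomial count model the per-individual total equals the
#' configured depth exactly.
#'
#' @param genome_pair Output of \code{\link{simulate_genome_pair}}.
#' @param config A \code{\link{sim_config}}; its seed drives all draws.
#' @param tads Optional output of \code{\link{simulate_tads}} (consensus
#'   sets used for the within-domain enrichment).
#' @return list with \code{individuals} (per individual: id, assembly,
#'   species/sex/batch, \code{counts} as a \code{\link{count_matrix}} in the
#'   individual's own assembly), \code{design} (a
#'   \code{\link{study_design}}), \code{truth} (planted pairs with log2
#'   effects, plus the generator's per-individual true normalized
#'   frequencies of the planted pairs), and \code{universe} bookkeeping.
#' @export
simulate_hic <- function(genome_pair, config, tads = NULL) {
  if (config$depth <= 0) stop("library depth must be positive")
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- config$resolution
  ga <- genome_pair$genome_a
  map <- genome_pair$map
  uni <- .pair_universe(ga, config$max_distance)
  d <- uni$start2 - uni$start1
  w_decay <- (d / res)^(-config$decay)

  # orthologous-bin map for translating species-B matrices
  bins <- unique(data.frame(chrom = c(uni$chrom, uni$chrom),
                            start = c(uni$start1, uni$start2)))
  bm <- map_bin_rbh(map, bins$chrom, bins$start, res, "AtoB")
  bkey <- paste(bins$chrom, bins$start, sep = ":")
  b_start <- stats::setNames(bm$start, bkey)
  b_chrom <- stats::setNames(bm$chrom, bkey)
  ok_bin <- stats::setNames(bm$accepted, bkey)
  k1 <- paste(uni$chrom, uni$start1, sep = ":")
  k2 <- paste(uni$chrom, uni$start2, sep = ":")
  mappable <- ok_bin[k1] & ok_bin[k2]

  # loop layer: elevated contacts shared by both species
  is_loop <- rep(FALSE, nrow(uni))
  n_loops <- round(config$loop_frac * sum(mappable))
  if (n_loops > 0) is_loop[sample(which(mappable), n_loops)] <- TRUE
  # planted species effects on a fraction of the loop contacts
  n_dc <- round(config$frac_dc * n_loops)
  planted_idx <- sort(sample(which(is_loop), n_dc))
  effect <- rep(0, nrow(uni))
  if (n_dc > 0) {
    effect[planted_idx] <- config$dc_effect *
      sample(c(-1, 1), n_dc, replace = TRUE)
  }

  in_tad_a <- .within_domain(uni, tads$consensus_a)
  in_tad_b <- .within_domain(uni, tads$consensus_b_in_a)
  sex_mod <- stats::rnorm(nrow(uni), 0, config$sex_effect_sd)
  batch_mod <- stats::rnorm(nrow(uni), 0, config$batch_effect_sd)

  n <- config$n_per_species
  ids <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  species <- rep(c(0, 1), each = n)
  sex <- rep(rep_len(c(0, 1), n), 2)
  batch <- rep(rep(c(0, 1), each = ceiling(n / 2))[seq_len(n)], 2)
  design <- study_design(species, sex, batch)
  rownames(design) <- ids

  individuals <- vector("list", length(ids))
  names(individuals) <- ids
  planted_freq <- matrix(NA_real_, n_dc, length(ids),
                         dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    is_b <- species[j] == 1
    keep <- if (is_b) mappable else rep(TRUE, nrow(uni))
    lg2 <- (if (is_b) effect else 0) +
      log2(config$loop_boost) * is_loop +
      log2(config$tad_boost) * (if (is_b) in_tad_b else in_tad_a) +
      sex[j] * sex_mod + batch[j] * batch_mod
    w <- w_decay * 2^lg2
    w[!keep] <- 0
    if (config$count_model == "multinomial") {
      cnt <- as.vector(stats::rmultinom(1, config$depth, prob = w))
    } else {
      cnt <- stats::rpois(length(w), config$depth * w / sum(w))
    }
    lambda0 <- config$depth * w_decay / sum(w_decay)
    if (n_dc > 0) {
      planted_freq[, j] <- log2((cnt[planted_idx] + 0.5) /
                                  (lambda0[planted_idx] + 0.5))
    }
    nz <- cnt > 0
    if (is_b) {
      s1 <- unname(b_start[k1[nz]])
      s2 <- unname(b_start[k2[nz]])
      pr <- data.frame(chrom = unname(b_chrom[k1[nz]]),
                       start1 = pmin(s1, s2), start2 = pmax(s1, s2),
                       count = cnt[nz])
      cm <- count_matrix(pr[order(pr$chrom, pr$start1, pr$start2), ],
                         genome_pair$genome_b, config$max_distance)
    } else {
      pr <- data.frame(chrom = uni$chrom[nz], start1 = uni$start1[nz],
                       start2 = uni$start2[nz], count = cnt[nz])
      cm <- count_matrix(pr, ga, config$max_distance)
    }
    individuals[[j]] <- list(id = ids[j], assembly = if (is_b) "B" else "A",
                             species = species[j], sex = sex[j],
                             batch = batch[j], counts = cm)
  }
  truth_dc <- if (n_dc > 0) {
    data.frame(contact_id = paste(uni$chrom[planted_idx],
                                  uni$start1[planted_idx],
                                  uni$start2[planted_idx], sep = ":"),
               chrom = uni$chrom[planted_idx],
               start1 = uni$start1[planted_idx],
               start2 = uni$start2[planted_idx],
               effect = effect[planted_idx])
  } else {
    data.frame(contact_id = character(), chrom = character(),
               start1 = numeric(), start2 = numeric(), effect = numeric())
  }
  list(individuals = individuals, design = design,
       truth = list(planted = truth_dc, planted_freq = planted_freq,
                    n_loops = n_loops, mappable_fraction = mean(mappable)),
       universe = list(n_pairs = nrow(uni), n_mappable = sum(mappable)))
}

#' Simulate a gene expression count table
#'
#' Baseline log2 RPKM is drawn per gene; a fraction of genes receives a
#' direct species effect; mediation genes additionally receive
#' \code{beta} times the per-individual frequency of their linked contact
#' (which itself carries the planted species effect alpha), so the indirect
#' species effect on their expression is alpha * beta. Gaussian noise is
#' added on the log2 scale and counts are derived from RPKM using the gene
#' length and library size.
#'
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{tss},
#'   \code{length}.
#' @param species 0/1 species indicator per individual (named by id).
#' @param mediation Optional data.frame with \code{gene}, \code{contact_id},
#'   \code{beta}; every row must reference an existing gene and a row of
#'   \code{freq}.
#' @param freq Optional matrix (contacts x individuals, rownames contact
#'   ids) of contact frequencies used as mediators.
#' @param de_frac,de_effect Planted direct differential expression.
#' @param noise_sd Expression noise SD in log2 units.
#' @param base_mean,base_sd Baseline log2 RPKM distribution.
#' @param lib_size Library size per individual.
#' @param seed Optional RNG seed.
#' @return list with \code{counts} (genes x individuals), \code{lengths},
#'   \code{lib_size}, \code{log2rpkm} (latent, noise included), and
#'   \code{truth} (planted DE effects and mediation assignments).
#' @export
simulate_expression <- function(genes, species, mediation = NULL,
                                freq = NULL, de_frac = 0.1, de_effect = 2,
                                noise_sd = 0.3, base_mean = 3, base_sd = 1,
                                lib_size = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ind <- length(species)
  ng <- nrow(genes)
  med_genes <- character()
  if (!is.null(mediation) && nrow(mediation)) {
    if (!all(mediation$gene %in% genes$gene)) {
      stop("mediation references unknown gene(s)")
    }
    if (is.null(freq) || !all(mediation$contact_id %in% rownames(freq))) {
      stop("mediation references unknown contact(s)")
    }
    med_genes <- mediation$gene
  }
  base <- stats::rnorm(ng, base_mean, base_sd)
  x <- as.numeric(species)
  eligible <- setdiff(genes$gene, med_genes)
  n_de <- round(de_frac * length(eligible))
  de_genes <- sample(eligible, n_de)
  de_eff <- stats::setNames(rep(0, ng), genes$gene)
  de_eff[de_genes] <- de_effect * sample(c(-1, 1), n_de, replace = TRUE)
  lg <- matrix(base, ng, n_ind) +
    outer(de_eff[genes$gene], x) +
    matrix(stats::rnorm(ng * n_ind, 0, noise_sd), ng, n_ind)
  if (length(med_genes)) {
    gi <- match(mediation$gene, genes$gene)
    lg[gi, ] <- lg[gi, ] + mediation$beta *
      freq[mediation$contact_id, , drop = FALSE]
  }
  dimnames(lg) <- list(genes$gene, names(species) %||% seq_len(n_ind))
  rpkm_val <- 2^lg
  counts <- round(sweep(rpkm_val * (genes$length / 1e3), 2,
                        rep_len(lib_size, n_ind) / 1e6, "*"))
  truth <- list(de = data.frame(gene = genes$gene,
                                effect = unname(de_eff[genes$gene])),
                mediation = mediation)
  list(counts = counts, lengths = stats::setNames(genes$length, genes$gene),
       lib_size = rep_len(lib_size, n_ind), log2rpkm = lg, truth = truth)
}

#' Simulate a chromatin-state annotation track
#'
#' Tiles each chromosome with non-overlapping segments whose states are
#' drawn from the configured frequencies and whose lengths are exponential
#' with the given mean, so long-run base-pair state proportions converge to
#' the frequencies.
#'
#' @param genome A \code{\link{genome_spec}} (may have zero chromosomes).
#' @param state_freqs Named non-negative frequencies summing to 1.
#' @param mean_len Mean segment length in base pairs.
#' @param seed Optional RNG seed.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{state}.
#' @export
simulate_annotations <- function(genome, state_freqs, mean_len = 5000,
                                 seed = NULL) {
  if (any(state_freqs < 0)) stop("state frequencies must be non-negative")
  if (abs(sum(state_freqs) - 1) > 1e-8) {
    stop("state frequencies must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ch in genome$chroms) {
    len <- genome$lengths[[ch]]
    pos <- 0
    starts <- numeric(0); ends <- numeric(0); states <- character(0)
    while (pos < len) {
      sl <- if (length(state_freqs) == 1) len else
        max(1, round(stats::rexp(1, 1 / mean_len)))
      st <- sample(names(state_freqs), 1, prob = state_freqs)
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + sl, len))
      states <- c(states, st)
      pos <- pos + sl
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            state = states)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete two-species study with a ground-truth ledger
#'
#' Orchestrates the full generator: assemblies and orthology map, TAD
#' structure, per-individual Hi-C counts, genes (mediation genes placed in
#' anchor bins of planted differential contacts), expression counts, and an
#' annotation track. All randomness is driven by \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list with \code{config}, \code{genomes}, \code{map}, \code{tads},
#'   \code{hic}, \code{genes}, \code{expression}, \code{annotations}, and
#'   \code{truth} (the combined ledger).
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  ga <- genome_spec(names(config$chrom_lengths), config$chrom_lengths,
                    config$resolution)
  gp <- simulate_genome_pair(ga, config$rearrangements)
  n <- config$n_per_species
  ids <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  tads <- simulate_tads(gp, config, individuals = ids,
                        species_b = rep(c(FALSE, TRUE), each = n))
  cfg_hic <- config
  cfg_hic$seed <- NULL  # stay on the study RNG stream
  hic <- simulate_hic(gp, cfg_hic, tads)

  res <- config$resolution
  planted <- hic$truth$planted
  n_med <- min(config$n_mediation, nrow(planted))
  med_rows <- if (n_med > 0) sort(sample(nrow(planted), n_med)) else integer()
  genes <- list()
  if (n_med > 0) {
    genes[[1]] <- data.frame(
      gene = sprintf("medgene%03d", seq_len(n_med)),
      chrom = planted$chrom[med_rows],
      tss = planted$start1[med_rows] + res / 2,
      length = round(stats::runif(n_med, 500, 5000)))
  }
  n_other <- config$n_genes - n_med
  if (n_other > 0) {
    ch <- sample(ga$chroms, n_other, replace = TRUE)
    genes[[length(genes) + 1]] <- data.frame(
      gene = sprintf("gene%04d", seq_len(n_other)),
      chrom = ch,
      tss = floor(stats::runif(n_other) * ga$lengths[ch] / res) * res +
        res / 2,
      length = round(stats::runif(n_other, 500, 5000)))
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  mediation <- if (n_med > 0) {
    data.frame(gene = sprintf("medgene%03d", seq_len(n_med)),
               contact_id = planted$contact_id[med_rows],
               beta = config$med_beta)
  } else NULL
  freq <- hic$truth$planted_freq
  rownames(freq) <- planted$contact_id
  species <- stats::setNames(hic$design$species, ids)
  expr <- simulate_expression(genes, species, mediation = mediation,
                              freq = freq, de_frac = config$de_frac,
                              de_effect = config$de_effect,
                              noise_sd = config$expr_noise_sd,
                              base_mean = config$expr_base_mean,
                              base_sd = config$expr_base_sd,
                              lib_size = config$lib_size)
  ann <- simulate_annotations(ga, config$state_freqs, config$state_mean_len)
  list(config = config, genomes = gp[c("genome_a", "genome_b")],
       map = gp$map, tads = tads, hic = hic, genes = genes,
       expression = expr, annotations = ann,
       truth = list(digest = .config_digest(config), seed = config$seed,
                    planted_dc = planted, tads = tads$truth,
                    de = expr$truth$de, mediation = mediation))
}
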