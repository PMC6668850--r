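test_that("genome pair with no rearrangements is an identity map", {
  g <- small_genome()
  gp <- simulate_genome_pair(g, list())
  b <- gp$map$blocks
  expect_equal(nrow(b), 2)
  expect_equal(b$start_b, b$start_a)
  expect_equal(b$chrom_b, b$chrom_a)
  expect_true(all(b$strand == "+"))
  expect_equal(unname(gp$genome_b$lengths), unname(g$lengths))
})

test_that("a deletion covering 10% of the genome maps exactly 90% of it", {
  g <- genome_spec("chr1", 4e6)
  gp <- simulate_genome_pair(g, list(
    list(type = "deletion", chrom = "chr1", start = 1e6, end = 1.4e6)))
  mapped <- sum(gp$map$blocks$end_a - gp$map$blocks$start_a)
  expect_equal(mapped / sum(g$lengths), 0.9)
  expect_equal(unname(gp$genome_b$lengths), 3.6e6)
})

test_that("rearrangement validation catches overlap and out-of-bounds", {
  g <- small_genome()
  expect_error(simulate_genome_pair(g, list(
    list(type = "deletion", chrom = "chr1", start = 1e5, end = 3e5),
    list(type = "inversion", chrom = "chr1", start = 2e5, end = 4e5))),
    "overlap")
  expect_error(simulate_genome_pair(g, list(
    list(type = "deletion", chrom = "chr1", start = 1.9e6, end = 2.1e6))),
    "bounds")
  expect_error(simulate_genome_pair(g, list(
    list(type = "duplication", chrom = "chr1", start = 0, end = 1e5))),
    "unknown")
})

test_that("hic counts are deterministic, depth-conserving, distance-decaying", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 3e6),
                    rearrangements = list(), max_distance = 1.5e6,
                    tad_boost = 1, loop_frac = 0, frac_dc = 0,
                    sex_effect_sd = 0, batch_effect_sd = 0, decay = 1,
                    depth = 2e6)
  gp <- simulate_genome_pair(genome_spec("chr1", 3e6), list())
  h1 <- simulate_hic(gp, cfg)
  h2 <- simulate_hic(gp, cfg)
  expect_identical(h1$individuals$A1$counts$pairs, h2$individuals$A1$counts$pairs)
  totals <- vapply(h1$individuals, function(x) x$counts$total, 0)
  expect_true(all(totals == cfg$depth))
  # decay exponent 1: mean count at 2d is half the mean at d
  p <- h1$individuals$A1$counts$pairs
  d <- p$start2 - p$start1
  nb <- 300
  mean_at <- function(dd) sum(p$count[d == dd]) / (nb - dd / 1e4)
  ratio <- mean_at(4e5) / mean_at(2e5)
  expect_lt(abs(ratio - 0.5), 0.05)
  expect_error(simulate_hic(gp, sim_config(depth = 1, seed = 1)), NA)
  expect_error(sim_config(depth = 0), "positive")
})

test_that("null configuration yields species effects centered at zero", {
  cfg <- sim_config(seed = 6, chrom_lengths = c(chr1 = 2e6),
                    rearrangements = list(), max_distance = 1e6,
                    tad_shared = 1, loop_frac = 1, loop_boost = 1,
                    frac_dc = 0.05, dc_effect = 0,
                    n_genes = 5, n_mediation = 0)
  sim <- simulate_study(cfg)
  pe <- planted_effect_estimates(sim, n_null = 500)
  expect_lt(abs(mean(pe$beta_sp)), 0.05)
})

test_that("expression composes alpha and beta exactly at zero noise", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      tss = c(15000, 25000), length = c(1000, 2000))
  x <- stats::setNames(rep(c(0, 1), each = 4), paste0("i", 1:8))
  m <- matrix(rep(x, each = 1) + rep(c(-1.5, -0.5, 0.5, 1.5), 2),
              1, 8, dimnames = list("c1", names(x)))  # alpha = 1
  med <- data.frame(gene = "g1", contact_id = "c1", beta = 2)
  e <- simulate_expression(genes, x, mediation = med, freq = m,
                           de_frac = 0, noise_sd = 0, seed = 3)
  diff <- mean(e$log2rpkm["g1", x == 1]) - mean(e$log2rpkm["g1", x == 0])
  expect_equal(diff, 2.0)
  d2 <- mean(e$log2rpkm["g2", x == 1]) - mean(e$log2rpkm["g2", x == 0])
  expect_equal(d2, 0)
  # determinism and referential integrity
  e2 <- simulate_expression(genes, x, mediation = med, freq = m,
                            de_frac = 0, noise_sd = 0, seed = 3)
  expect_identical(e$counts, e2$counts)
  expect_error(simulate_expression(genes, x,
                                   mediation = data.frame(gene = "nope",
                                                          contact_id = "c1",
                                                          beta = 1),
                                   freq = m), "unknown gene")
  expect_error(simulate_expression(genes, x,
                                   mediation = data.frame(gene = "g1",
                                                          contact_id = "cX",
                                                          beta = 1),
                                   freq = m), "unknown contact")
})

test_that("annotation tracks tile the genome at the configured frequencies", {
  g1 <- genome_spec("chr1", 1e6)
  one <- simulate_annotations(g1, c(Only = 1), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 0)
  expect_equal(one$end, 1e6)
  # two states at 0.5/0.5 over ~10^4 segments
  g2 <- genome_spec("chr1", 5e7, resolution = 10000)
  tr <- simulate_annotations(g2, c(A = 0.5, B = 0.5), mean_len = 5000,
                             seed = 2)
  expect_gt(nrow(tr), 5000)
  lens <- tapply(tr$end - tr$start, tr$state, sum)
  expect_lt(abs(lens[["A"]] / sum(lens) - 0.5), 0.02)
  # segments tile without overlap
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)] | tr$chrom[-1] !=
                    tr$chrom[-nrow(tr)]))
  empty <- simulate_annotations(genome_spec(character(), numeric()),
                                c(A = 1))
  expect_equal(nrow(empty), 0)
  expect_error(simulate_annotations(g1, c(A = -0.1, B = 1.1)), "non-negative")
  expect_error(simulate_annotations(g1, c(A = 0.4, B = 0.4)), "sum to 1")
})

test_that("planted TAD sharing matches the configured fraction", {
  cfg <- sim_config(seed = 8, chrom_lengths = stats::setNames(
    rep(1e7, 10), paste0("chr", 1:10)),
    rearrangements = list(), tad_shared = 0.7,
    tad_size_range = c(2e5, 5e5), tad_gap_range = c(0, 5e4))
  gp <- simulate_genome_pair(genome_spec(names(cfg$chrom_lengths),
                                         cfg$chrom_lengths), list())
  tads <- simulate_tads(gp, cfg)
  expect_gt(nrow(tads$truth), 150)
  cs <- conservation_summary(tads$consensus_a, tads$consensus_b_in_a,
                             "reciprocal90")
  expect_lt(abs(cs$proportion - 0.7), 0.07)
})
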