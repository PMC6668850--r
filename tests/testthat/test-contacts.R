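test_that("decay expectation reproduces flat and degenerate profiles", {
  g <- genome_spec("chr1", 1e5)  # 10 bins
  # uniform count 3 at every possible pair within 50 kb
  pairs <- list()
  for (d in 1:5) {
    s <- seq(0, (10 - d - 1) * 1e4, by = 1e4)
    pairs[[d]] <- data.frame(chrom = "chr1", start1 = s, start2 = s + d * 1e4,
                             count = 3)
  }
  cm <- count_matrix(do.call(rbind, pairs), g, max_distance = 5e4)
  prof <- estimate_expected(cm)
  expect_equal(unname(prof$expected), rep(3, 5))
  # single nonzero pair in a two-bin genome: expected equals that count
  g2 <- genome_spec("chr1", 2e4)
  cm2 <- count_matrix(data.frame(chrom = "chr1", start1 = 0, start2 = 1e4,
                                 count = 7), g2, max_distance = 1e4)
  expect_equal(unname(estimate_expected(cm2)$expected), 7)
  expect_error(estimate_expected(count_matrix(
    data.frame(chrom = "chr1", start1 = 0, start2 = 1e4, count = 0), g2)),
    "empty")
})

test_that("estimated expectation tracks the generating decay curve", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 3e6),
                    rearrangements = list(), max_distance = 1.5e6,
                    tad_boost = 1, loop_frac = 0, frac_dc = 0,
                    sex_effect_sd = 0, batch_effect_sd = 0, decay = 1,
                    depth = 1e6)
  gp <- simulate_genome_pair(genome_spec("chr1", 3e6), list())
  h <- simulate_hic(gp, cfg)
  cm <- h$individuals$A1$counts
  prof <- estimate_expected(cm)
  # generating curve: lambda(d) = depth * (d/res)^-1 / sum of weights
  d <- prof$distance
  w <- (d / 1e4)^-1 * prof$npairs
  lambda <- cfg$depth * (d / 1e4)^-1 / sum(w)
  dense <- prof$npairs >= 100
  expect_true(all(abs(prof$expected[dense] / lambda[dense] - 1) < 0.1))
  # expectation preserves the matrix total
  expect_lt(abs(sum(prof$expected * prof$npairs) / cm$total - 1), 0.01)
})

test_that("binomial tail p-values match a log-space summation oracle", {
  g <- genome_spec("chr1", 3e4)
  # craft totals: pair under test (obs = 10, expected = 2) plus filler mass
  cm <- count_matrix(data.frame(chrom = "chr1", start1 = c(0, 0),
                                start2 = c(1e4, 2e4), count = c(10, 9990)),
                     g, max_distance = 2e4)
  prof <- structure(list(distance = c(1e4, 2e4), expected = c(2, 9990),
                         npairs = c(2, 1), resolution = 1e4, total = 1e4),
                    class = "decay_profile")
  calls <- call_contacts(cm, prof, alpha = 1)
  # independent oracle: log-space tail sum of the binomial pmf
  log_tail <- function(obs, n, pr) {
    k <- obs:min(n, obs + 2000)
    lp <- lchoose(n, k) + k * log(pr) + (n - k) * log1p(-pr)
    m <- max(lp)
    exp(m) * sum(exp(lp - m))
  }
  for (obs in c(1, 5, 10, 25, 50)) {
    cm_i <- count_matrix(data.frame(chrom = "chr1", start1 = c(0, 0),
                                    start2 = c(1e4, 2e4),
                                    count = c(obs, 1e4 - obs)),
                         g, max_distance = 2e4)
    prof_i <- structure(list(distance = c(1e4, 2e4),
                             expected = c(2, 1e4 - obs),
                             npairs = c(2, 1), resolution = 1e4, total = 1e4),
                        class = "decay_profile")
    p_pkg <- call_contacts(cm_i, prof_i, alpha = 1)$p[1]
    p_orc <- log_tail(obs, 1e4, 2e-4)
    expect_lt(abs(p_pkg / p_orc - 1), 1e-8)
  }
  # monotone: more observed reads never increases the p-value
  expect_true(all(diff(sapply(c(1, 5, 10, 25, 50), function(o)
    log_tail(o, 1e4, 2e-4))) < 0))
  # the significance threshold is inclusive
  p_at_10 <- calls$p[1]
  kept <- call_contacts(cm, prof, alpha = p_at_10)
  expect_true(10 %in% kept$obs)
  expect_error(call_contacts(cm, structure(list(
    distance = c(1e4, 2e4), expected = c(2e4, 1), npairs = c(2, 1),
    resolution = 1e4, total = 1e4), class = "decay_profile")),
    "exceeds")
})

test_that("caller p-values are uniform under the simulated null", {
  # flat decay: every pair has the same multinomial cell probability, so
  # marginal counts are Binomial(N, 1/n_pairs), the caller's exact null
  cfg <- sim_config(seed = 10, chrom_lengths = c(chr1 = 2e6),
                    rearrangements = list(), max_distance = 1e6,
                    tad_boost = 1, loop_frac = 0, frac_dc = 0,
                    sex_effect_sd = 0, batch_effect_sd = 0, decay = 0,
                    depth = 6e6, n_per_species = 1)
  gp <- simulate_genome_pair(genome_spec("chr1", 2e6), list())
  h <- simulate_hic(gp, cfg)
  cm <- h$individuals$A1$counts
  prof <- estimate_expected(cm)
  pv <- call_contacts(cm, prof, alpha = 1)$p
  expect_gt(length(pv), 1e4)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("normalized frequency follows the stated log-ratio definition", {
  expect_equal(normalized_frequency(4, 4, 0.5), 0)
  expect_equal(normalized_frequency(4, 1, 0), 2)
  expect_equal(normalized_frequency(0, 1, 0.5), log2(0.5 / 1.5),
               tolerance = 1e-10)
  expect_equal(round(normalized_frequency(0, 1, 0.5), 5), -1.58496)
  expect_error(normalized_frequency(1, 0, 0), "pseudocount")
})

test_that("discovery filter is inclusive at the threshold", {
  tb <- data.frame(id = 1:3, discovery_count = c(3, 4, 8))
  expect_equal(filter_by_discovery(tb, 4)$id, c(2, 3))
  expect_equal(nrow(filter_by_discovery(tb[0, , drop = FALSE], 4)), 0)
  all8 <- data.frame(id = 1:5, discovery_count = 8)
  expect_equal(filter_by_discovery(all8, 8), all8)
})

test_that("variance by discovery count computes per-row sample variance", {
  tb <- data.frame(discovery_count = c(4, 5))
  fr <- rbind(rep(2, 8), c(1, 2, 3, 4, 1, 2, 3, 4))
  v <- variance_by_discovery(tb, fr)
  expect_equal(v$mean_var[v$discovery_count == 4], 0)
  expect_equal(v$mean_var[v$discovery_count == 5], 10 / 7,
               tolerance = 1e-6)
  expect_equal(round(10 / 7, 4), 1.4286)
})

test_that("discovery count tracks frequency precision in a planted study", {
  # rows discovered in more individuals are given lower noise by design
  set.seed(11)
  counts <- rep(2:8, each = 30)
  fr <- t(sapply(counts, function(k) rnorm(8, 0, 1 / k)))
  v <- variance_by_discovery(data.frame(discovery_count = counts), fr)
  expect_true(all(diff(v$mean_var) < 0))
})

test_that("cyclic loess removes offsets and MA trends, and is idempotent", {
  set.seed(12)
  base <- rnorm(500, 0, 1)
  x <- cbind(a = base + rnorm(500, 0, 0.05), b = base + rnorm(500, 0, 0.05),
             c = base + rnorm(500, 0, 0.05))
  expect_equal(cyclic_loess_normalize(cbind(x[, 1], x[, 1])),
               cbind(x[, 1], x[, 1]), tolerance = 1e-8)
  shifted <- x
  shifted[, 2] <- shifted[, 2] + 1
  norm <- cyclic_loess_normalize(shifted)
  expect_lt(abs(mean(norm[, 2]) - mean(norm[, 1])), 0.01)
  # opposite linear MA trends
  y <- cbind(base + 0.3 * base, base - 0.3 * base)
  ny <- cyclic_loess_normalize(y)
  mval <- ny[, 1] - ny[, 2]
  aval <- rowMeans(ny)
  expect_lt(abs(unname(coef(lm(mval ~ aval))[2])), 0.05)
  # idempotence
  again <- cyclic_loess_normalize(norm)
  expect_lt(max(abs(again - norm)), 0.05)
  const <- x
  const[, 3] <- 5
  expect_warning(out <- cyclic_loess_normalize(const), "constant")
  expect_identical(out, const)
})
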