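test_that("boundary derivation extends domain edges by the flank", {
  d <- data.frame(chrom = "chr1", start = 100000, end = 200000)
  b <- boundaries_from_domains(d)
  expect_equal(b$start, c(92500, 192500))
  expect_equal(b$end, c(107500, 207500))
  expect_true(all(b$end - b$start == 15000))
  # left edge clamped at 0
  b0 <- boundaries_from_domains(data.frame(chrom = "chr1", start = 0,
                                           end = 100000))
  expect_equal(b0$start[b0$side == "left"], 0)
  expect_equal(b0$end[b0$side == "left"], 7500)
  # 2n boundaries for n domains
  dn <- data.frame(chrom = "chr1", start = (1:5) * 1e5, end = (2:6) * 1e5)
  expect_equal(nrow(boundaries_from_domains(dn)), 10)
})

test_that("reciprocal overlap criterion follows the 90% rule both ways", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100000)
  expect_true(reciprocal_overlap_conserved(a, a))
  b <- data.frame(chrom = "chr1", start = 5000, end = 105000)
  expect_true(reciprocal_overlap_conserved(a, b))   # 95% both ways
  c3 <- data.frame(chrom = "chr1", start = 20000, end = 120000)
  expect_false(reciprocal_overlap_conserved(a, c3)) # 80% < 90%
  expect_equal(reciprocal_overlap_conserved(a, b),
               reciprocal_overlap_conserved(b, a))
  other <- data.frame(chrom = "chr2", start = 0, end = 100000)
  expect_false(reciprocal_overlap_conserved(a, other))
})

test_that("endpoint-distance criterion uses min(50 kb, half own size)", {
  a <- data.frame(chrom = "chr1", start = 100000, end = 200000)
  expect_true(rao_conserved(a, a))
  b <- data.frame(chrom = "chr1", start = 110000, end = 210000)
  expect_true(rao_conserved(a, b))    # 10000 * sqrt(2) ~ 14142 < 50000
  a80 <- data.frame(chrom = "chr1", start = 0, end = 80000)
  b80 <- data.frame(chrom = "chr1", start = 30000, end = 110000)
  expect_false(rao_conserved(a80, b80))  # ~42426 >= min(50000, 40000)
  # asymmetric when lengths differ: threshold is the given domain's size
  long <- data.frame(chrom = "chr1", start = 0, end = 100000)
  short <- data.frame(chrom = "chr1", start = 40000, end = 100000)
  expect_true(rao_conserved(long, short))   # 40000 < 50000
  expect_false(rao_conserved(short, long))  # 40000 >= 30000
})

test_that("conservation summary takes the larger directional estimate", {
  d1 <- data.frame(chrom = "chr1", start = 0, end = 300000)
  a <- rbind(d1, data.frame(chrom = "chr1", start = 5000, end = 305000))
  b <- rbind(d1, data.frame(chrom = "chr2", start = 0, end = 300000))
  cs <- conservation_summary(a, b, "reciprocal90")
  expect_equal(cs$shared_a, 2)
  expect_equal(cs$shared_b, 1)
  expect_equal(cs$conserved, 2)
  expect_equal(cs$specific, 1)
  expect_equal(cs$proportion, 2 / 3)
  # identical sets are fully conserved under both criteria
  for (crit in c("reciprocal90", "rao")) {
    expect_equal(conservation_summary(a, a, crit)$proportion, 1.0)
  }
  # disjoint chromosome sets share nothing
  expect_equal(conservation_summary(
    d1, data.frame(chrom = "chr9", start = 0, end = 300000),
    "reciprocal90")$proportion, 0)
  expect_true(is.na(conservation_summary(d1[0, ], b, "rao")$proportion))
})

test_that("large shifts abolish conservation under both criteria", {
  set.seed(15)
  s <- sort(sample(seq(0, 9e6, 5e5), 10))
  a <- data.frame(chrom = "chr1", start = s, end = s + 4e5)
  shift <- pmax(50000, 0.15 * (a$end - a$start))
  b <- data.frame(chrom = "chr1", start = a$start + shift,
                  end = a$end + shift)
  expect_equal(conservation_summary(a, b, "reciprocal90")$proportion, 0)
  expect_equal(conservation_summary(a, b, "rao")$proportion, 0)
})

test_that("boundary merging matches a sweep-line union oracle", {
  # single-bp overlap across species marks the merged element conserved
  sp <- c(h1 = "human", c1 = "chimp")
  b <- data.frame(chrom = "chr1",
                  start = c(92500, 107499), end = c(107500, 122499),
                  sample = c("h1", "c1"))
  bc <- boundary_conservation(b, sp)
  expect_equal(nrow(bc$elements), 1)
  expect_true(bc$elements$conserved)
  expect_equal(bc$proportion, 1)
  # half-open adjacency does not merge
  b2 <- data.frame(chrom = "chr1", start = c(0, 15000), end = c(15000, 30000),
                   sample = c("h1", "c1"))
  bc2 <- boundary_conservation(b2, sp)
  expect_equal(nrow(bc2$elements), 2)
  expect_false(any(bc2$elements$conserved))
  # oracle equivalence on random interval sets
  sweep_union <- function(start, end) {
    o <- order(start)
    s <- start[o]; e <- end[o]
    us <- s[1]; ue <- e[1]; out <- NULL
    for (i in seq_along(s)[-1]) {
      if (s[i] < ue) ue <- max(ue, e[i]) else {
        out <- rbind(out, c(us, ue)); us <- s[i]; ue <- e[i]
      }
    }
    rbind(out, c(us, ue))
  }
  set.seed(16)
  for (rep in 1:3) {
    n <- 300
    st <- sample(0:100000, n, replace = TRUE)
    iv <- data.frame(chrom = "chr1", start = st,
                     end = st + sample(1:5000, n, replace = TRUE),
                     sample = sample(c("h1", "c1"), n, replace = TRUE))
    got <- boundary_conservation(iv, sp)$elements
    want <- sweep_union(iv$start, iv$end)
    expect_equal(got$start, want[, 1])
    expect_equal(got$end, want[, 2])
  }
})

test_that("sharing matrix rows normalize by the query individual", {
  d <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(4e5, 9e5))
  sets <- list(i1 = d, i2 = d[1, , drop = FALSE])
  sm <- sharing_matrix(sets, "reciprocal90")
  expect_equal(unname(sm$matrix["i1", "i2"]), 0.5)
  expect_equal(unname(sm$matrix["i2", "i1"]), 1.0)
  same <- sharing_matrix(list(a = d, b = d, c = d))
  expect_true(all(same$matrix == 1))
})

test_that("clustering of sharing proportions splits planted species", {
  set.seed(17)
  starts <- seq(0, 9e6, 5e5)
  template <- function() {
    keep <- runif(length(starts)) < 0.9
    data.frame(chrom = "chr1", start = starts[keep],
               end = starts[keep] + 4e5)
  }
  base_a <- template()
  # species B shares ~40% of A's domains, rest shifted out of reach
  base_b <- base_a
  mv <- runif(nrow(base_b)) > 0.4
  base_b$start[mv] <- base_b$start[mv] + 2.2e5
  base_b$end[mv] <- base_b$end[mv] + 2.2e5
  jitter_set <- function(d) {
    keep <- runif(nrow(d)) < 0.95
    d[keep, , drop = FALSE]
  }
  sets <- c(lapply(1:3, function(i) jitter_set(base_a)),
            lapply(1:3, function(i) jitter_set(base_b)))
  names(sets) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  sm <- sharing_matrix(sets, "reciprocal90")
  grp <- stats::cutree(sm$hclust, 2)
  expect_equal(length(unique(grp[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(grp[c("b1", "b2", "b3")])), 1)
  expect_true(grp[["a1"]] != grp[["b1"]])
})
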