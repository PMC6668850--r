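# Shared fixtures built in code.

# identity orthology map over a genome
identity_map <- function(genome) {
  orthology_map(data.frame(chrom_a = genome$chroms, start_a = 0,
                           end_a = unname(genome$lengths),
                           chrom_b = genome$chroms, start_b = 0,
                           end_b = unname(genome$lengths), strand = "+"))
}

# 4 Mb two-chromosome genome at 10 kb
small_genome <- function() genome_spec(c("chr1", "chr2"), c(2e6, 2e6))

# balanced 4 + 4 design
toy_design <- function() {
  study_design(species = rep(c(0, 1), each = 4),
               sex = rep(c(0, 1, 0, 1), 2),
               batch = rep(c(0, 0, 1, 1), 2))
}

# genome pair with one 0.5 Mb inversion (chr1) and one 0.2 Mb deletion (chr2)
rearranged_pair <- function(genome = small_genome()) {
  simulate_genome_pair(genome, list(
    list(type = "inversion", chrom = "chr1", start = 5e5, end = 1e6),
    list(type = "deletion", chrom = "chr2", start = 1e6, end = 1.2e6)))
}

# independent brute-force RBH oracle: walks every block explicitly
oracle_rbh <- function(map, chrom, start, resolution) {
  fwd_one <- function(b, ch, s, e) {
    hit <- b[b$chrom_a == ch & b$start_a < e & b$end_a > s, , drop = FALSE]
    if (nrow(hit) != 1) return(NULL)                    # none or split
    if (s < hit$start_a || e > hit$end_a) return(NULL)  # hangs off edge
    if (hit$strand == "+") {
      c(hit$chrom_b, hit$start_b + (s - hit$start_a))
    } else {
      c(hit$chrom_b, hit$start_b + (hit$end_a - e))
    }
  }
  back_blocks <- map$blocks
  back_blocks[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                  "end_b")] <-
    back_blocks[, c("chrom_b", "start_b", "end_b", "chrom_a", "start_a",
                    "end_a")]
  f <- fwd_one(map$blocks, chrom, start, start + resolution)
  if (is.null(f)) return(NULL)
  ts <- round(as.numeric(f[2]) / resolution) * resolution
  g <- fwd_one(back_blocks, f[1], ts, ts + resolution)
  if (is.null(g)) return(NULL)
  bs <- round(as.numeric(g[2]) / resolution) * resolution
  if (g[1] == chrom && bs == start) c(f[1], ts) else NULL
}
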