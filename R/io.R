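# Readers and writers for the plain-text interchange formats: BEDPE contact
# counts, BED domain/boundary/annotation tracks, the 8-column orthology map
# TSV, expression tables, and the truth ledger.

#' Write a contact count matrix as BEDPE with a count column
#' @param cm A \code{\link{count_matrix}}.
#' @param path Output file.
#' @export
write_contact_counts <- function(cm, path) {
  res <- cm$resolution
  p <- cm$pairs
  utils::write.table(
    data.frame(chrom1 = p$chrom, start1 = p$start1, end1 = p$start1 + res,
               chrom2 = p$chrom, start2 = p$start2, end2 = p$start2 + res,
               count = p$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BEDPE + count file into a count matrix
#' @param path BEDPE file with 7 columns (chrom1, start1, end1, chrom2,
#'   start2, end2, count).
#' @param genome The \code{\link{genome_spec}} the bins live on.
#' @param max_distance Maximum represented distance.
#' @return A \code{\link{count_matrix}}.
#' @export
read_contact_counts <- function(path, genome, max_distance = 2e6) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom1", "start1", "end1", "chrom2",
                                       "start2", "end2", "count"))
  count_matrix(data.frame(chrom = d$chrom1,
                          start1 = pmin(d$start1, d$start2),
                          start2 = pmax(d$start1, d$start2),
                          count = d$count),
               genome, max_distance)
}

#' Write intervals as BED (0-based half-open)
#' @param x data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally a name column.
#' @param path Output file.
#' @param name_col Optional column written as the BED name field.
#' @export
write_bed <- function(x, path, name_col = NULL) {
  cols <- x[, c("chrom", "start", "end"), drop = FALSE]
  if (!is.null(name_col)) cols$name <- x[[name_col]]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED file
#' @param path BED file (3+ columns); a 4th column is read as \code{name}.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name}.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d
}

#' Write an orthology map as an 8-column TSV
#' @param map An \code{\link{orthology_map}}.
#' @param path Output file.
#' @export
write_orthology_map <- function(map, path) {
  b <- map$blocks
  utils::write.table(
    b[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
          "strand", "block_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
}

#' Read an orthology map TSV
#' @param path File written by \code{\link{write_orthology_map}}.
#' @return An \code{\link{orthology_map}}.
#' @export
read_orthology_map <- function(path) {
  orthology_map(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write an expression count table (gene, length, counts per individual)
#' @param expr The expression element of a simulated study.
#' @param path Output file.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene = rownames(expr$counts),
                    length = expr$lengths[rownames(expr$counts)],
                    expr$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write the ground-truth ledger of a simulated study
#'
#' Planted differential contacts, domain categories, expression effects and
#' mediation assignments, with a header line recording the config digest and
#' seed.
#'
#' @param sim Output of \code{\link{simulate_study}}.
#' @param path Output file.
#' @export
write_truth_ledger <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crossmap3d truth ledger; seed=%d; config=%s",
                     sim$truth$seed, sim$truth$digest), con)
  sec <- function(name, df) {
    if (is.null(df) || !nrow(df)) return(invisible())
    writeLines(paste0("## ", name), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  sec("planted_dc", sim$truth$planted_dc)
  sec("tads", sim$truth$tads)
  sec("de", sim$truth$de)
  sec("mediation", sim$truth$mediation)
}

#' Write all files of a simulated study to a directory
#'
#' Emits per-individual contact BEDPEs, per-individual and consensus TAD
#' BEDs, the orthology map TSV, the expression table, the annotation BED,
#' and the truth ledger.
#'
#' @param sim Output of \code{\link{simulate_study}}.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (id in names(sim$hic$individuals)) {
    f <- file.path(outdir, paste0(id, ".contacts.bedpe"))
    write_contact_counts(sim$hic$individuals[[id]]$counts, f)
    files <- c(files, f)
    if (!is.null(sim$tads$individual[[id]])) {
      f <- file.path(outdir, paste0(id, ".tads.bed"))
      write_bed(sim$tads$individual[[id]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(outdir, "map.tsv")
  write_orthology_map(sim$map, f)
  files <- c(files, f)
  for (nm in c("consensus_a", "consensus_b")) {
    f <- file.path(outdir, paste0(nm, ".tads.bed"))
    write_bed(sim$tads[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "expression.tsv")
  write_expression(sim$expression, f)
  files <- c(files, f)
  f <- file.path(outdir, "annotations.bed")
  write_bed(sim$annotations, f, name_col = "state")
  files <- c(files, f)
  f <- file.path(outdir, "truth.tsv")
  write_truth_ledger(sim, f)
  files <- c(files, f)
  invisible(files)
}
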