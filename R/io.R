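#' Write a simulated dataset as a 10x-style directory
#'
#' Writes `matrix.mtx` (sparse triplet counts, genes x cells), `genes.tsv`
#' (the gene catalog), `barcodes.tsv`, `cells.tsv` (cell metadata) and
#' `truth.tsv` (simulation ground truth) into `dir`.
#'
#' @param sim A `sim_data` object from [simulate_cells()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_10x <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(sim$catalog, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style directory written by [write_sim_10x()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#'   and optionally `cells.tsv` / `truth.tsv`.
#' @return A list with `counts` (sparse genes x cells), `catalog`, `cells`
#'   (NULL if absent) and `truth` (NULL if absent).
#' @export
read_counts_10x <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  catalog <- utils::read.delim(file.path(dir, "genes.tsv"),
                               stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  rownames(counts) <- catalog$gene_id
  colnames(counts) <- barcodes
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  list(counts = counts, catalog = catalog,
       cells = read_opt("cells.tsv"), truth = read_opt("truth.tsv"))
}
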