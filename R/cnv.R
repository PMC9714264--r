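#' CNV inference configuration
#'
#' Parameters of the expression-based CNV profile estimator: a uniform
#' (boxcar) moving average of `window_genes` genes along genomic order within
#' each chromosome (windows truncated at chromosome ends), log2 transform with
#' `log_pseudocount` on counts per 10,000, per-cell median re-centering after
#' smoothing, and clipping at +/- `clip_sd` reference-cell standard
#' deviations. The default window of 101 genes suits genome-scale catalogs
#' (~20k genes); pick a window so segments of interest span several windows.
#'
#' @param window_genes Odd window width in genes.
#' @param log_pseudocount Pseudocount added before the log transform.
#' @param clip_sd Clip bound in units of the reference cells' smoothed SD.
#' @param min_genes_per_chromosome Chromosomes with fewer genes are dropped.
#' @param exclude_chromosomes Chromosome labels excluded from the profile.
#' @return An object of class `cnv_config`.
#' @export
cnv_config <- function(window_genes = 101, log_pseudocount = 1, clip_sd = 3,
                       min_genes_per_chromosome = 5,
                       exclude_chromosomes = character(0)) {
  stopifnot(window_genes >= 1, window_genes %% 2 == 1, log_pseudocount > 0,
            clip_sd > 0, min_genes_per_chromosome >= 1)
  structure(list(window_genes = as.integer(window_genes),
                 log_pseudocount = log_pseudocount, clip_sd = clip_sd,
                 min_genes_per_chromosome = as.integer(min_genes_per_chromosome),
                 exclude_chromosomes = exclude_chromosomes),
            class = "cnv_config")
}

#' Reference-centered log expression
#'
#' Depth-normalizes counts to counts per 10,000, log2-transforms with a
#' pseudocount, and centers each gene by subtracting its mean over the
#' reference cells. Reference cells therefore average 0 at every gene; an
#' observation cell expressing a gene at twice the reference level scores
#' ~log2(2) = 1 there.
#'
#' @param counts Genes x cells count matrix with gene and cell ids.
#' @param reference_cells Character vector of reference cell ids (non-empty,
#'   present in `counts`).
#' @param config A [cnv_config()].
#' @return Dense genes x cells matrix of centered log2 expression.
#' @export
relative_expression <- function(counts, reference_cells,
                                config = cnv_config()) {
  if (length(reference_cells) == 0) stop("reference cell set is empty")
  missing <- setdiff(reference_cells, colnames(counts))
  if (length(missing) > 0) {
    stop("reference cells absent from counts: ", missing[1])
  }
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cells with zero total counts; run QC first")
  norm <- sweep(as.matrix(counts), 2, total / 1e4, "/")
  lg <- log2(norm + config$log_pseudocount)
  dimnames(lg) <- dimnames(counts)
  ref_mean <- rowMeans(lg[, reference_cells, drop = FALSE])
  lg - ref_mean
}

#' Boxcar moving average with truncated edges
#'
#' Uniform moving average of width `window` over the columns of each row...
#' operates along positions `1..m` of a vector or matrix rows; at the edges
#' the window is truncated to the available positions (average over fewer
#' genes), never reflected or padded.
#'
#' @param x Numeric matrix (positions x series) or vector.
#' @param window Odd window width.
#' @return Smoothed object of the same shape.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  m <- nrow(x)
  h <- (window - 1) / 2
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- pmax(0L, seq_len(m) - h - 1L)
  hi <- pmin(m, seq_len(m) + h)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) /
    (hi - lo)
  dimnames(out) <- dimnames(x)
  if (vec) out[, 1] else out
}

#' Smooth centered expression into CNV profiles
#'
#' The CNV estimator core: for each cell, the centered log-ratios are averaged
#' over a `window_genes`-wide uniform window along genomic gene order within
#' each chromosome (truncated at chromosome ends, so smoothing never crosses a
#' chromosome boundary); each cell is then re-centered by its own median to
#' remove residual per-cell shifts; finally values are clipped at
#' +/- `clip_sd` x SD of the reference cells' smoothed values, bounding
#' outlier genes.
#'
#' @param centered Genes x cells matrix from [relative_expression()].
#' @param ordering Ordered gene table from [order_genes()].
#' @param config A [cnv_config()].
#' @param reference_cells Cell ids used for the clip-bound SD (defaults to
#'   all cells when NULL).
#' @return Object of class `cnv_profile`: list with `matrix` (cells x ordered
#'   genes), `genes` (the ordering table), `reference_cells`, `clip` (the
#'   bound actually applied), `config`.
#' @export
smooth_cnv <- function(centered, ordering, config = cnv_config(),
                       reference_cells = NULL) {
  stopifnot(config$window_genes %% 2 == 1)
  keep <- intersect(ordering$gene_id, rownames(centered))
  ordering <- ordering[ordering$gene_id %in% keep, , drop = FALSE]
  x <- centered[ordering$gene_id, , drop = FALSE]
  chrom <- as.character(ordering$chromosome)
  sm <- x
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    sm[rows, ] <- moving_average(x[rows, , drop = FALSE],
                                 config$window_genes)
  }
  prof <- t(sm)                              # cells x ordered genes
  prof <- prof - apply(prof, 1, stats::median)
  if (is.null(reference_cells)) reference_cells <- rownames(prof)
  ref_sd <- stats::sd(as.vector(prof[reference_cells, , drop = FALSE]))
  clip <- config$clip_sd * ref_sd
  prof[prof > clip] <- clip
  prof[prof < -clip] <- -clip
  structure(list(matrix = prof, genes = ordering,
                 reference_cells = reference_cells, clip = clip,
                 config = config),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$matrix), "cells x", ncol(x$matrix),
      "genes;", nlevels(x$genes$chromosome), "chromosomes; clip +/-",
      signif(x$clip, 3), "\n")
  invisible(x)
}

profile_matrix <- function(profiles) {
  if (inherits(profiles, "cnv_profile")) profiles$matrix else profiles
}

#' Euclidean distance between two CNV vectors
#'
#' @param profile_a,profile_b Numeric vectors of equal length in the same
#'   gene order.
#' @return The Euclidean distance, a nonnegative number.
#' @export
cnv_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop("CNV vectors differ in length: ", length(profile_a), " vs ",
         length(profile_b))
  }
  sqrt(sum((profile_a - profile_b)^2))
}

#' Distances of every cell's profile to a baseline vector
#'
#' @param profiles A `cnv_profile` or cells x genes matrix.
#' @param baseline Baseline vector in the same gene order.
#' @return Named vector of Euclidean distances, one per cell.
#' @export
distance_to_baseline <- function(profiles, baseline) {
  m <- profile_matrix(profiles)
  if (ncol(m) != length(baseline)) stop("baseline length mismatch")
  d <- sweep(m, 2, baseline)
  sqrt(rowSums(d * d))
}
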