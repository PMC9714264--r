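#' Build a synthetic gene catalog
#'
#' Creates an ordered gene annotation table defining the genomic axis used for
#' CNV smoothing: `n_chromosomes` chromosomes labeled `chr1..chrN`, each
#' carrying `genes_per_chromosome` genes at strictly increasing start
#' positions. The first half of each chromosome (by gene rank) is the "p" arm,
#' the second half the "q" arm. A random subset of genes is flagged
#' mitochondrial and another (disjoint) subset hemoglobin, at the requested
#' fractions of the total gene count (realized counts are `round(fraction * n)`,
#' i.e. within one gene of the request).
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param genes_per_chromosome Genes per chromosome (>= 10).
#' @param mito_fraction Fraction of genes flagged mitochondrial, in \[0, 1\].
#' @param hemoglobin_fraction Fraction flagged hemoglobin, in \[0, 1\].
#' @param seed Integer seed; the catalog is deterministic given the seed.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`
#'   (0-based, strictly increasing within a chromosome), `arm` ("p"/"q"),
#'   `is_mito`, `is_hemoglobin`.
#' @examples
#' cat <- make_genome(3, 100, mito_fraction = 0.1, seed = 1)
#' table(cat$chromosome)
#' @export
make_genome <- function(n_chromosomes, genes_per_chromosome,
                        mito_fraction = 0, hemoglobin_fraction = 0,
                        seed = 1L) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1 ||
      !is.numeric(genes_per_chromosome) || genes_per_chromosome < 10) {
    stop("invalid argument: need n_chromosomes >= 1 and genes_per_chromosome >= 10")
  }
  if (mito_fraction < 0 || mito_fraction > 1 ||
      hemoglobin_fraction < 0 || hemoglobin_fraction > 1) {
    stop("invalid argument: flag fractions must lie in [0, 1]")
  }
  if (mito_fraction + hemoglobin_fraction > 1) {
    stop("invalid argument: flag fractions sum to more than 1")
  }
  n_chromosomes <- as.integer(n_chromosomes)
  genes_per_chromosome <- as.integer(genes_per_chromosome)
  set.seed(as.integer(seed))

  n <- n_chromosomes * genes_per_chromosome
  chromosome <- rep(paste0("chr", seq_len(n_chromosomes)),
                    each = genes_per_chromosome)
  # strictly increasing 0-based positions within each chromosome
  start <- unlist(lapply(seq_len(n_chromosomes), function(i) {
    sort(sample.int(2e8L, genes_per_chromosome)) - 1L
  }), use.names = FALSE)
  rank_in_chrom <- rep(seq_len(genes_per_chromosome), times = n_chromosomes)
  arm <- ifelse(rank_in_chrom <= genes_per_chromosome / 2, "p", "q")

  n_mito <- round(mito_fraction * n)
  n_hb <- round(hemoglobin_fraction * n)
  flagged <- if (n_mito + n_hb > 0) sample.int(n, n_mito + n_hb) else integer(0)
  is_mito <- is_hb <- rep(FALSE, n)
  if (n_mito > 0) is_mito[flagged[seq_len(n_mito)]] <- TRUE
  if (n_hb > 0) is_hb[flagged[n_mito + seq_len(n_hb)]] <- TRUE

  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chromosome = chromosome,
    start = start,
    arm = arm,
    is_mito = is_mito,
    is_hemoglobin = is_hb,
    stringsAsFactors = FALSE
  )
}

#' Order genes along the genome
#'
#' Stable sort of a gene catalog by (chromosome, start position), breaking
#' position ties lexicographically by gene id. Chromosome order follows first
#' appearance in the catalog. Chromosomes with fewer than
#' `min_genes_per_chromosome` genes (after removing `exclude_chromosomes`) are
#' dropped with a warning — short chromosomes cannot support windowed
#' smoothing.
#'
#' @param catalog Gene catalog as returned by [make_genome()] (or any
#'   data.frame with `gene_id`, `chromosome`, `start`).
#' @param min_genes_per_chromosome Minimum genes a chromosome must retain.
#' @param exclude_chromosomes Character vector of chromosome labels to drop.
#' @return The catalog rows in genomic order, with `chromosome` as a factor
#'   whose levels give the chromosome order.
#' @export
order_genes <- function(catalog, min_genes_per_chromosome = 5,
                        exclude_chromosomes = character(0)) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(catalog)))
  dup <- duplicated(catalog[, c("chromosome", "start", "gene_id")])
  if (any(dup)) {
    stop("duplicate (chromosome, position, gene) entries in catalog: ",
         catalog$gene_id[which(dup)[1]])
  }
  catalog <- catalog[!(catalog$chromosome %in% exclude_chromosomes), ,
                     drop = FALSE]
  chrom_levels <- unique(catalog$chromosome)
  sizes <- table(factor(catalog$chromosome, levels = chrom_levels))
  small <- names(sizes)[sizes < min_genes_per_chromosome]
  if (length(small) > 0) {
    warning("dropping chromosome(s) with fewer than ",
            min_genes_per_chromosome, " genes: ",
            paste(small, collapse = ", "))
    catalog <- catalog[!(catalog$chromosome %in% small), , drop = FALSE]
    chrom_levels <- setdiff(chrom_levels, small)
  }
  chrom <- factor(catalog$chromosome, levels = chrom_levels)
  ord <- order(as.integer(chrom), catalog$start, catalog$gene_id,
               method = "radix")
  out <- catalog[ord, , drop = FALSE]
  out$chromosome <- factor(out$chromosome, levels = chrom_levels)
  rownames(out) <- NULL
  out
}
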