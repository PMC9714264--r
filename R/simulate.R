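#' Stemness gene set
#'
#' The 12-gene stemness signature used for module scoring of epithelial cells.
#' @return Character vector of gene symbols.
#' @export
stemness_genes <- function() {
  c("ALDH1A1", "CD44", "PROM1", "NANOG", "KIT", "NES",
    "KLF4", "CD55", "ALCAM", "NOTCH4", "WNT7A", "PDPN")
}

#' Coarse cell-type marker table
#'
#' Marker genes used to annotate coarse populations (fibroblast, endothelial,
#' epithelial) from cluster mean expression. Restricted to the symbols carried
#' by the synthetic genome.
#' @return Named list mapping cell type to marker gene symbols.
#' @export
default_marker_table <- function() {
  list(
    fibroblast = c("COL1A1", "DCN", "LUM"),
    endothelial = c("PECAM1", "VWF", "ENG"),
    epithelial = c("EPCAM", "KRT19", "CLDN3", "KRT8")
  )
}

#' Epithelial subtype marker genes
#'
#' The six genes driving the myoepithelial-like (MEC: ACTA2+/MYH11+/CNN1+),
#' intercalated-duct-like (Inter-Duct: KRT19+/AQP5+/KIT+) and duct-like
#' (Duct: KRT19+/AQP5-/KIT-) subtype rules.
#' @return Character vector of the six marker symbols.
#' @export
subtype_marker_genes <- function() {
  c("ACTA2", "MYH11", "CNN1", "KRT19", "AQP5", "KIT")
}

# per-population marker boosting map used by the simulator
population_marker_map <- function() {
  list(
    fibroblast = c("COL1A1", "DCN", "LUM"),
    endothelial = c("PECAM1", "VWF", "ENG"),
    MEC = c("EPCAM", "KRT8", "CLDN3", "ACTA2", "MYH11", "CNN1"),
    "Inter-Duct" = c("EPCAM", "KRT8", "CLDN3", "KRT19", "AQP5", "KIT"),
    Duct = c("EPCAM", "KRT8", "CLDN3", "KRT19")
  )
}

all_marker_symbols <- function() {
  unique(c(unlist(population_marker_map(), use.names = FALSE),
           stemness_genes()))
}

epithelial_populations <- function() c("MEC", "Inter-Duct", "Duct")

#' Simulation configuration
#'
#' Parameters of the synthetic multi-sample single-cell experiment. Defaults
#' describe the standard fixture: three pseudo-patients, each contributing a
#' paracarcinoma and a carcinoma sample; stromal (fibroblast, endothelial) and
#' epithelial (MEC, Inter-Duct, Duct) populations; negative-binomial counts
#' with gene-wise baseline means; multiplicative CNV gains (1.5x) on four
#' segment analogues and one loss (0.5x) for malignant cells; a deviant,
#' non-conforming pattern for pre-malignant (pre-M) cells — the same core
#' arms at exaggerated dosage (1.8x) plus a private gain — whose aggregate
#' burden places pre-M cells outside the malignant distance band while still
#' clustering them away from normal stromal cells; marker-gene boosting
#' per population; a stemness boost in pre-M cells; mitochondrial and
#' hemoglobin flag fractions; and a small fraction of QC-outlier cells
#' emulating multiplet/ambient-heavy droplets (inflated depth plus extra
#' mito/hemoglobin content).
#'
#' @param n_chromosomes,genes_per_chromosome Synthetic genome dimensions.
#' @param n_patients Number of pseudo-patients (each has both tissues).
#' @param cell_counts Named list `paracarcinoma`/`carcinoma`, each a named
#'   vector of per-sample cell counts by population.
#' @param nb_mean_range Range (min, max) of uniform per-gene baseline
#'   negative-binomial means.
#' @param nb_dispersion Shared NB size (dispersion) parameter.
#' @param cnv_segments,prem_cnv_segments Data frames with columns
#'   `chromosome`, `start_frac`, `end_frac`, `copy_ratio`: segments carried by
#'   malignant and pre-M epithelial cells respectively (fractional coordinates
#'   along the chromosome's gene ranks; copy ratio multiplies the NB mean).
#' @param prem_fraction Named vector: fraction of epithelial cells per tissue
#'   that are pre-M (rest malignant).
#' @param marker_boost Fold-increase applied to a population's marker genes.
#' @param marker_baseline_mean Baseline mean of marker genes in populations
#'   not expressing them (markers are near-silent off-target).
#' @param stemness_boost Fold-increase of stemness genes in pre-M cells.
#' @param mito_gene_fraction,hemoglobin_gene_fraction Fractions of genes
#'   flagged mito / hemoglobin.
#' @param mito_mean_factor,hemoglobin_mean_factor Mean multipliers for flagged
#'   genes (mito transcripts are abundant, hemoglobin mostly ambient).
#' @param outlier_cell_fraction Fraction of cells turned into QC outliers.
#' @param outlier_depth_factor Depth inflation of outlier cells.
#' @param outlier_contamination_factor Additional mito/hemoglobin inflation of
#'   outlier cells.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 8,
                       genes_per_chromosome = 250,
                       n_patients = 3,
                       cell_counts = list(
                         paracarcinoma = c(fibroblast = 400, endothelial = 150,
                                           MEC = 100, "Inter-Duct" = 150,
                                           Duct = 100),
                         carcinoma = c(fibroblast = 100, endothelial = 50,
                                       MEC = 200, "Inter-Duct" = 400,
                                       Duct = 250)),
                       nb_mean_range = c(0.2, 4),
                       nb_dispersion = 2,
                       cnv_segments = data.frame(
                         chromosome = c("chr3", "chr4", "chr5", "chr6", "chr7"),
                         start_frac = c(0.5, 0.5, 0.5, 0.0, 0.5),
                         end_frac   = c(1.0, 1.0, 1.0, 0.5, 1.0),
                         copy_ratio = c(1.5, 1.5, 1.5, 1.5, 0.5)),
                       prem_cnv_segments = data.frame(
                         chromosome = c("chr3", "chr4", "chr5", "chr6", "chr7",
                                        "chr8"),
                         start_frac = c(0.5, 0.5, 0.5, 0.0, 0.5, 0.5),
                         end_frac   = c(1.0, 1.0, 1.0, 0.5, 1.0, 1.0),
                         copy_ratio = c(1.9, 1.9, 1.9, 1.9, 0.5, 1.8)),
                       prem_fraction = c(paracarcinoma = 0.476,
                                         carcinoma = 0.05),
                       marker_boost = 60,
                       marker_baseline_mean = 0.05,
                       stemness_boost = 2,
                       mito_gene_fraction = 0.01,
                       hemoglobin_gene_fraction = 0.005,
                       mito_mean_factor = 5,
                       hemoglobin_mean_factor = 2,
                       outlier_cell_fraction = 0.01,
                       outlier_depth_factor = 8,
                       outlier_contamination_factor = 4,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_patients = as.integer(n_patients),
    cell_counts = cell_counts,
    nb_mean_range = nb_mean_range,
    nb_dispersion = nb_dispersion,
    cnv_segments = cnv_segments,
    prem_cnv_segments = prem_cnv_segments,
    prem_fraction = prem_fraction,
    marker_boost = marker_boost,
    marker_baseline_mean = marker_baseline_mean,
    stemness_boost = stemness_boost,
    mito_gene_fraction = mito_gene_fraction,
    hemoglobin_gene_fraction = hemoglobin_gene_fraction,
    mito_mean_factor = mito_mean_factor,
    hemoglobin_mean_factor = hemoglobin_mean_factor,
    outlier_cell_fraction = outlier_cell_fraction,
    outlier_depth_factor = outlier_depth_factor,
    outlier_contamination_factor = outlier_contamination_factor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$genes_per_chromosome >= 10,
            cfg$n_patients >= 1)
  counts <- unlist(cfg$cell_counts)
  if (any(counts < 0) || all(counts == 0)) {
    stop("cell_counts must be nonnegative with at least one cell")
  }
  if (!all(cfg$nb_mean_range > 0) || cfg$nb_dispersion <= 0) {
    stop("negative-binomial parameters must be positive")
  }
  for (segs in list(cfg$cnv_segments, cfg$prem_cnv_segments)) {
    if (nrow(segs) > 0) {
      stopifnot(all(segs$copy_ratio > 0),
                all(segs$start_frac >= 0), all(segs$end_frac <= 1),
                all(segs$start_frac < segs$end_frac))
    }
  }
  props <- c(cfg$mito_gene_fraction, cfg$hemoglobin_gene_fraction,
             cfg$outlier_cell_fraction, cfg$prem_fraction)
  if (any(props < 0) || any(props > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  pops <- unique(unlist(lapply(cfg$cell_counts, names)))
  if (!("fibroblast" %in% pops) ||
      !any(epithelial_populations() %in% pops)) {
    stop("cell_counts must include fibroblasts and at least one epithelial ",
         "population: downstream reference and classification stages require both")
  }
  invisible(cfg)
}

#' Label marker genes in a synthetic catalog
#'
#' Renames the first unflagged genes of chr1 to the marker and stemness gene
#' symbols so marker-based annotation, subtyping and module scoring operate on
#' the synthetic data. chr1 carries no CNV segments under the default
#' configuration, keeping marker signal and CNV signal orthogonal.
#'
#' @param catalog Gene catalog from [make_genome()].
#' @param symbols Symbols to place (default: all marker + stemness genes).
#' @return The catalog with `gene_id` entries replaced.
#' @export
seed_marker_genes <- function(catalog, symbols = all_marker_symbols()) {
  slots <- which(catalog$chromosome == catalog$chromosome[1] &
                   !catalog$is_mito & !catalog$is_hemoglobin)
  if (length(slots) < length(symbols)) {
    stop("first chromosome too short to host ", length(symbols),
         " marker genes")
  }
  catalog$gene_id[slots[seq_along(symbols)]] <- symbols
  catalog
}

#' Implant CNV segments into per-gene means
#'
#' Multiplies the expression mean of every gene inside a segment by the
#' segment's copy ratio (linear dosage model: a 1.5x gain raises the mean
#' 1.5-fold, a 0.5x loss halves it). Segment coordinates are fractions of the
#' chromosome's gene ranks: a gene at rank r of m lies at (r - 0.5) / m and is
#' inside a segment `[start_frac, end_frac)` containing that midpoint.
#' Overlapping segments multiply.
#'
#' @param gene_means Positive numeric vector, one mean per catalog gene.
#' @param segments Data frame with `chromosome`, `start_frac`, `end_frac`,
#'   `copy_ratio` (zero rows allowed).
#' @param catalog Gene catalog aligned with `gene_means`.
#' @return The adjusted mean vector.
#' @export
implant_cnv <- function(gene_means, segments, catalog) {
  stopifnot(length(gene_means) == nrow(catalog), all(gene_means > 0))
  if (is.null(segments) || nrow(segments) == 0) return(gene_means)
  unknown <- setdiff(unique(segments$chromosome), unique(catalog$chromosome))
  if (length(unknown) > 0) {
    stop("segment references unknown chromosome: ",
         paste(unknown, collapse = ", "))
  }
  out <- gene_means
  for (i in seq_len(nrow(segments))) {
    on_chrom <- which(catalog$chromosome == segments$chromosome[i])
    m <- length(on_chrom)
    mid <- (seq_len(m) - 0.5) / m
    inside <- on_chrom[mid >= segments$start_frac[i] &
                         mid < segments$end_frac[i]]
    out[inside] <- out[inside] * segments$copy_ratio[i]
  }
  out
}

segments_string <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) return("")
  paste(sprintf("%s:%g-%g:x%g", segments$chromosome, segments$start_frac,
                segments$end_frac, segments$copy_ratio), collapse = ";")
}

#' Simulate multi-sample single-cell counts with known CNV structure
#'
#' Draws negative-binomial counts for every configured (patient, tissue,
#' population) block. Stromal populations (fibroblast, endothelial) sample
#' from the unmodified population means; epithelial cells are split into
#' malignant cells carrying `cnv_segments` and pre-M cells carrying
#' `prem_cnv_segments` (plus a stemness-gene boost), at the configured
#' per-tissue pre-M fraction. A fraction of cells is then converted to QC
#' outliers by redrawing their counts at inflated depth with extra
#' mitochondrial/hemoglobin content.
#'
#' @param config A [sim_config()].
#' @param catalog Gene catalog containing the marker symbols (see
#'   [seed_marker_genes()]).
#' @return List of class `sim_data` with elements `counts` (sparse genes x
#'   cells `dgCMatrix`), `cells` (cell metadata: `cell_id`, `sample_id`,
#'   `patient`, `tissue`, `cell_type`), `truth` (`cell_id`, `population`,
#'   `malignancy_truth`, `segments_applied`, `is_outlier`), `catalog`, and
#'   `group_means` (named list of the exact per-gene means each block was
#'   drawn from).
#' @export
simulate_cells <- function(config, catalog) {
  validate_sim_config(config)
  missing_markers <- setdiff(all_marker_symbols(), catalog$gene_id)
  if (length(missing_markers) > 0) {
    stop("catalog lacks marker genes (run seed_marker_genes): ",
         paste(utils::head(missing_markers, 3), collapse = ", "))
  }
  set.seed(config$seed)
  n_genes <- nrow(catalog)

  # gene-wise baseline means shared by every population
  baseline <- stats::runif(n_genes, config$nb_mean_range[1],
                           config$nb_mean_range[2])
  baseline[catalog$is_mito] <- baseline[catalog$is_mito] * config$mito_mean_factor
  baseline[catalog$is_hemoglobin] <-
    baseline[catalog$is_hemoglobin] * config$hemoglobin_mean_factor
  # population/subtype markers are near-silent off-target; stemness-only
  # genes keep ordinary baseline expression (they are scored, not gating)
  suppress <- unique(c(unlist(population_marker_map(), use.names = FALSE),
                       subtype_marker_genes()))
  baseline[match(suppress, catalog$gene_id)] <- config$marker_baseline_mean

  pop_map <- population_marker_map()
  stem_idx <- match(stemness_genes(), catalog$gene_id)

  population_mean <- function(pop) {
    mu <- baseline
    mk <- match(pop_map[[pop]], catalog$gene_id)
    mu[mk] <- mu[mk] * config$marker_boost
    mu
  }

  blocks <- list()
  group_means <- list()
  cells <- list()
  truth <- list()
  draw_block <- function(mu, k) {
    matrix(stats::rnbinom(n_genes * k, mu = mu, size = config$nb_dispersion),
           nrow = n_genes)
  }

  for (p in seq_len(config$n_patients)) {
    patient <- paste0("P", p)
    for (tissue in names(config$cell_counts)) {
      sample_id <- paste(patient, tissue, sep = "_")
      counts_by_pop <- config$cell_counts[[tissue]]
      cell_no <- 0L
      for (pop in names(counts_by_pop)) {
        k <- as.integer(counts_by_pop[[pop]])
        if (k == 0) next
        mu_pop <- population_mean(pop)
        epithelial <- pop %in% epithelial_populations()
        if (epithelial) {
          n_prem <- round(unname(config$prem_fraction[tissue]) * k)
          states <- c(rep("pre-M", n_prem), rep("malignant", k - n_prem))
        } else {
          states <- rep("normal", k)
        }
        for (state in unique(states)) {
          kk <- sum(states == state)
          mu <- mu_pop
          segs <- NULL
          if (state == "malignant") {
            segs <- config$cnv_segments
            mu <- implant_cnv(mu, segs, catalog)
          } else if (state == "pre-M") {
            segs <- config$prem_cnv_segments
            mu <- implant_cnv(mu, segs, catalog)
            mu[stem_idx] <- mu[stem_idx] * config$stemness_boost
          }
          gkey <- paste(sample_id, pop, state, sep = ".")
          group_means[[gkey]] <- mu
          blocks[[gkey]] <- draw_block(mu, kk)
          ids <- sprintf("%s_%04d", sample_id, cell_no + seq_len(kk))
          cell_no <- cell_no + kk
          cells[[gkey]] <- data.frame(
            cell_id = ids, sample_id = sample_id, patient = patient,
            tissue = tissue,
            cell_type = if (epithelial) "epithelial" else pop,
            stringsAsFactors = FALSE)
          truth[[gkey]] <- data.frame(
            cell_id = ids, population = pop, malignancy_truth = state,
            segments_applied = segments_string(segs),
            is_outlier = FALSE, group = gkey,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  counts <- do.call(cbind, blocks)
  cells <- do.call(rbind, cells)
  truth <- do.call(rbind, truth)
  rownames(cells) <- rownames(truth) <- NULL
  colnames(counts) <- cells$cell_id
  rownames(counts) <- catalog$gene_id

  # QC outliers: redraw selected cells at inflated depth and contamination
  n_cells <- ncol(counts)
  n_out <- round(config$outlier_cell_fraction * n_cells)
  if (n_out > 0) {
    out_idx <- sample.int(n_cells, n_out)
    contam <- catalog$is_mito | catalog$is_hemoglobin
    for (j in out_idx) {
      mu <- group_means[[truth$group[j]]] * config$outlier_depth_factor
      mu[contam] <- mu[contam] * config$outlier_contamination_factor
      counts[, j] <- stats::rnbinom(n_genes, mu = mu,
                                    size = config$nb_dispersion)
    }
    truth$is_outlier[out_idx] <- TRUE
  }
  truth$group <- NULL

  out <- list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cells = cells,
    truth = truth,
    catalog = catalog,
    group_means = group_means
  )
  class(out) <- "sim_data"
  out
}

#' One-call synthetic dataset
#'
#' Builds the synthetic genome, places marker genes, and simulates cells.
#' @param config A [sim_config()].
#' @return A `sim_data` list; see [simulate_cells()].
#' @export
simulate_dataset <- function(config = sim_config()) {
  catalog <- make_genome(config$n_chromosomes, config$genes_per_chromosome,
                         config$mito_gene_fraction,
                         config$hemoglobin_gene_fraction,
                         seed = config$seed)
  catalog <- seed_marker_genes(catalog)
  simulate_cells(config, catalog)
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$cells$sample_id)), "samples;",
      sum(x$truth$is_outlier), "outlier cells\n")
  print(table(x$truth$population, x$truth$malignancy_truth))
  invisible(x)
}
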