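#' Run the full malignancy-calling pipeline
#'
#' End-to-end procedure on a QC'd count matrix with coarse cell annotations:
#'
#' 1. per-sample adaptive QC ([filter_cells()]);
#' 2. spike-in partition of paracarcinoma stromal cells into reference and
#'    spiked observation sets ([spike_in_partition()]);
#' 3. CNV profiles: reference-centered log-ratios smoothed along genomic
#'    order, median-recentered and clipped ([relative_expression()],
#'    [smooth_cnv()]);
#' 4. dendrogram spike-in test for normal epithelial cells
#'    ([classify_normal_epithelial()]);
#' 5. baseline = per-gene median profile of paracarcinoma fibroblasts;
#'    Euclidean distances of epithelial cells to it;
#' 6. malignant band (median +/- k SD of carcinoma-epithelial distances) and
#'    pre-M / malignant calls ([malignant_band()], [call_premalignant()]).
#'
#' @param counts Genes x cells count matrix.
#' @param cells Cell metadata: `cell_id`, `sample_id`, `tissue`
#'   (paracarcinoma / carcinoma), `cell_type` (coarse; fibroblast,
#'   endothelial, epithelial, ...).
#' @param catalog Gene catalog.
#' @param qc A [qc_config()].
#' @param cnv A [cnv_config()].
#' @param spike A [spike_config()].
#' @return List with `qc` (per-cell metrics + verdicts), `partition`,
#'   `profile` (`cnv_profile` over all QC-passed cells), `normal_epithelial`
#'   (ids), `baseline`, `distances` (all profiled cells), `band`, `calls`
#'   (per-epithelial-cell data frame joined with tissue/sample).
#' @export
run_malignancy_pipeline <- function(counts, cells, catalog,
                                    qc = qc_config(),
                                    cnv = cnv_config(),
                                    spike = spike_config()) {
  metrics <- compute_qc_metrics(counts, catalog, cells)
  verdicts <- filter_cells(metrics, qc)
  kept <- verdicts$cell_id[verdicts$keep]
  counts <- counts[, kept, drop = FALSE]
  cells <- cells[match(kept, cells$cell_id), , drop = FALSE]

  stromal <- cells$cell_id[cells$cell_type %in%
                             c("fibroblast", "endothelial") &
                             cells$tissue == "paracarcinoma"]
  epithelial <- cells$cell_id[cells$cell_type == "epithelial"]
  partition <- spike_in_partition(stromal, spike)

  centered <- relative_expression(counts, partition$reference, cnv)
  ordering <- order_genes(catalog, cnv$min_genes_per_chromosome,
                          cnv$exclude_chromosomes)
  profile <- smooth_cnv(centered, ordering, cnv,
                        reference_cells = partition$reference)

  normal_epi <- classify_normal_epithelial(
    profile, partition$observation, epithelial, spike)

  para_fibro <- cells$cell_id[cells$cell_type == "fibroblast" &
                                cells$tissue == "paracarcinoma"]
  baseline <- baseline_profile(profile$matrix[para_fibro, , drop = FALSE])
  distances <- distance_to_baseline(profile, baseline)

  candidates <- setdiff(epithelial, normal_epi)
  carcinoma_epi <- intersect(
    candidates, cells$cell_id[cells$tissue == "carcinoma"])
  band <- malignant_band(distances[carcinoma_epi], spike)
  calls <- call_premalignant(distances, band, epithelial, normal_epi)
  calls$tissue <- cells$tissue[match(calls$cell_id, cells$cell_id)]
  calls$sample_id <- cells$sample_id[match(calls$cell_id, cells$cell_id)]

  list(qc = verdicts, partition = partition, profile = profile,
       normal_epithelial = normal_epi, baseline = baseline,
       distances = distances, band = band, calls = calls)
}
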