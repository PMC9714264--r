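#' QC configuration
#'
#' Thresholding rules for per-cell quality control: an adaptive upper bound of
#' mean + `sd_multiplier` * SD (SD with the n - 1 denominator) on each metric,
#' computed within each sample when `per_sample` is TRUE, combined with fixed
#' floors/ceilings — more than `min_genes` genes detected, mitochondrial
#' percentage below `max_pct_mito`, hemoglobin percentage below
#' `max_pct_hemoglobin` (strict inequalities).
#'
#' @param sd_multiplier Multiplier of the SD in the adaptive upper bound.
#' @param min_genes Minimum genes detected (exclusive floor).
#' @param max_pct_mito,max_pct_hemoglobin Fixed ceilings in percent (exclusive).
#' @param per_sample Compute adaptive thresholds within each sample?
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(sd_multiplier = 2.58, min_genes = 200,
                      max_pct_mito = 30, max_pct_hemoglobin = 10,
                      per_sample = TRUE) {
  stopifnot(sd_multiplier > 0, min_genes > 0, max_pct_mito > 0,
            max_pct_hemoglobin > 0)
  structure(list(sd_multiplier = sd_multiplier, min_genes = min_genes,
                 max_pct_mito = max_pct_mito,
                 max_pct_hemoglobin = max_pct_hemoglobin,
                 per_sample = isTRUE(per_sample)),
            class = "qc_config")
}

#' Per-cell QC metrics
#'
#' Computes genes detected (count > 0), total counts, and the percentage of
#' counts on mitochondrial and hemoglobin genes for every cell. Cells with
#' zero total counts get 0 for both percentages and are flagged.
#'
#' @param counts Genes x cells count matrix (sparse or dense) with gene ids as
#'   row names.
#' @param catalog Gene catalog carrying `gene_id`, `is_mito`, `is_hemoglobin`.
#' @param cells Optional cell metadata with `cell_id` and `sample_id`; when
#'   absent all cells are treated as one sample.
#' @return Data frame with one row per cell: `cell_id`, `sample_id`,
#'   `n_genes_detected`, `total_counts`, `pct_mito`, `pct_hemoglobin`,
#'   `zero_counts`.
#' @export
compute_qc_metrics <- function(counts, catalog, cells = NULL) {
  ids <- rownames(counts)
  if (is.null(ids)) stop("counts must carry gene ids as row names")
  bad <- setdiff(ids, catalog$gene_id)
  if (length(bad) > 0 || length(ids) != nrow(catalog)) {
    stop("gene ids in counts do not match catalog; first offending id: ",
         if (length(bad) > 0) bad[1] else catalog$gene_id[1])
  }
  cat_ord <- catalog[match(ids, catalog$gene_id), ]
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[cat_ord$is_mito, , drop = FALSE])
  hb <- Matrix::colSums(counts[cat_ord$is_hemoglobin, , drop = FALSE])
  denom <- ifelse(total > 0, total, 1)
  out <- data.frame(
    cell_id = colnames(counts),
    sample_id = if (is.null(cells)) "all" else
      cells$sample_id[match(colnames(counts), cells$cell_id)],
    n_genes_detected = as.integer(ngene),
    total_counts = as.numeric(total),
    pct_mito = 100 * mito / denom,
    pct_hemoglobin = 100 * hb / denom,
    zero_counts = total == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Adaptive upper threshold
#'
#' The adaptive QC bound: mean plus `sd_multiplier` standard deviations of the
#' supplied values (SD with the n - 1 denominator).
#'
#' @param values Numeric vector (length >= 2).
#' @param sd_multiplier Positive multiplier (2.58 captures ~99.5% of a
#'   Gaussian one-sided).
#' @return The threshold, a single number.
#' @export
adaptive_threshold <- function(values, sd_multiplier = 2.58) {
  if (length(values) < 2) {
    stop("adaptive threshold needs at least 2 values")
  }
  mean(values) + sd_multiplier * stats::sd(values)
}

qc_metric_names <- c("n_genes_detected", "pct_mito", "pct_hemoglobin")

compute_qc_thresholds <- function(metrics, config) {
  split_by <- if (config$per_sample) metrics$sample_id else
    rep("all", nrow(metrics))
  parts <- split(metrics, split_by)
  do.call(rbind, lapply(names(parts), function(s) {
    m <- parts[[s]]
    data.frame(
      sample_id = s,
      metric = qc_metric_names,
      threshold = vapply(qc_metric_names, function(v)
        adaptive_threshold(m[[v]], config$sd_multiplier), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff it clears the fixed rules (genes detected > `min_genes`,
#' pct mito < `max_pct_mito`, pct hemoglobin < `max_pct_hemoglobin`) and each
#' of the three metrics is <= its adaptive mean + k*SD threshold (computed per
#' sample when configured). Each discarded cell carries every reason that
#' applied. The thresholds used are attached to the result (attribute
#' `thresholds`) and can be passed back in, so re-filtering an already
#' filtered set under the same thresholds is a no-op.
#'
#' @param metrics Output of [compute_qc_metrics()].
#' @param config A [qc_config()].
#' @param thresholds Optional precomputed threshold table (as emitted); when
#'   NULL thresholds are computed from `metrics`.
#' @return `metrics` with `keep` (logical) and `reasons` (comma-joined reason
#'   codes, "" when kept) columns; attribute `thresholds` holds the adaptive
#'   threshold table.
#' @export
filter_cells <- function(metrics, config = qc_config(), thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- compute_qc_thresholds(metrics, config)
  key <- if (config$per_sample) metrics$sample_id else rep("all", nrow(metrics))
  thr <- function(metric) {
    t_sub <- thresholds[thresholds$metric == metric, ]
    t_sub$threshold[match(key, t_sub$sample_id)]
  }
  reasons <- vector("list", nrow(metrics))
  add <- function(which, code) {
    for (i in which(which)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(!(metrics$n_genes_detected > config$min_genes), "min_genes")
  add(!(metrics$pct_mito < config$max_pct_mito), "max_pct_mito")
  add(!(metrics$pct_hemoglobin < config$max_pct_hemoglobin),
      "max_pct_hemoglobin")
  add(metrics$n_genes_detected > thr("n_genes_detected"), "adaptive_n_genes")
  add(metrics$pct_mito > thr("pct_mito"), "adaptive_pct_mito")
  add(metrics$pct_hemoglobin > thr("pct_hemoglobin"),
      "adaptive_pct_hemoglobin")

  out <- metrics
  out$keep <- vapply(reasons, is.null, logical(1))
  out$reasons <- vapply(reasons, function(r)
    if (is.null(r)) "" else paste(r, collapse = ","), character(1))
  empty <- tapply(out$keep, out$sample_id, sum)
  if (any(empty == 0)) {
    warning("sample(s) empty after filtering: ",
            paste(names(empty)[empty == 0], collapse = ", "))
  }
  attr(out, "thresholds") <- thresholds
  out
}

#' Expected multiplet rate at a loading count
#'
#' Fits an ordinary least-squares line through a (cells loaded, multiplet
#' rate) table — the published loading-rate relationship for droplet
#' platforms — and evaluates it at `n_loaded`, floored at 0.
#'
#' @param table Data frame with columns `cells_loaded` and `multiplet_rate`
#'   (rate in percent), at least two distinct loading values.
#' @param n_loaded Number of cells loaded.
#' @return Expected multiplet rate (percent) at `n_loaded`.
#' @export
expected_multiplet_rate <- function(table, n_loaded) {
  stopifnot(all(c("cells_loaded", "multiplet_rate") %in% names(table)))
  if (length(unique(table$cells_loaded)) < 2) {
    stop("rate table needs at least 2 distinct loading values")
  }
  fit <- stats::lm(multiplet_rate ~ cells_loaded, data = table)
  pred <- stats::predict(fit, data.frame(cells_loaded = n_loaded))
  pmax(0, unname(pred))
}
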