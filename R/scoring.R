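#' Module score configuration
#'
#' Binned-control gene-set scoring parameters: genes are split into `n_bins`
#' equal-frequency bins by average expression, and each gene-set gene draws
#' `n_control_per_gene` control genes (with replacement) from its own bin.
#'
#' @param n_bins Number of expression bins (>= 2).
#' @param n_control_per_gene Control genes sampled per gene-set gene.
#' @param seed Seed for the control draw.
#' @return Object of class `module_score_config`.
#' @export
module_score_config <- function(n_bins = 24, n_control_per_gene = 100,
                                seed = 1L) {
  stopifnot(n_bins >= 2, n_control_per_gene >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 n_control_per_gene = as.integer(n_control_per_gene),
                 seed = as.integer(seed)),
            class = "module_score_config")
}

#' Log-normalize counts for scoring
#'
#' Natural-log counts per 10,000 with pseudocount 1 — the normalization
#' module scoring and subtype calls operate on.
#'
#' @param counts Genes x cells count matrix.
#' @return Dense genes x cells matrix of log1p(CP10K) values.
#' @export
lognormalize <- function(counts) {
  total <- Matrix::colSums(counts)
  total[total == 0] <- 1
  out <- log1p(sweep(as.matrix(counts), 2, total / 1e4, "/"))
  dimnames(out) <- dimnames(counts)
  out
}

#' Gene-set module score per cell
#'
#' Scores each cell for a gene set against expression-matched controls:
#' genes are ranked by mean expression across cells and divided into
#' `n_bins` equal-frequency bins; every gene-set gene contributes
#' `n_control_per_gene` control genes drawn with replacement from its bin;
#' the score is the mean expression of the set minus the mean expression of
#' the pooled controls, per cell. Controls cancel depth and bin-level
#' expression, so a set behaving like its bins scores ~0.
#'
#' @param expr Normalized log expression, genes x cells (see
#'   [lognormalize()]); at least `n_bins` genes.
#' @param gene_set Character vector of gene ids; genes absent from `expr` are
#'   dropped with a warning, an entirely absent set is an error.
#' @param config A [module_score_config()].
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(expr, gene_set, config = module_score_config()) {
  stopifnot(nrow(expr) >= config$n_bins)
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) {
    stop("gene set entirely absent from expression matrix")
  }
  if (length(present) < length(gene_set)) {
    warning("dropping ", length(gene_set) - length(present),
            " gene(s) absent from expression matrix")
  }
  set.seed(config$seed)
  avg <- rowMeans(expr)
  # equal-frequency bins over the expression ranks
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (length(rk) / config$n_bins))
  bin_members <- split(rownames(expr), bin)
  ctrl <- unlist(lapply(present, function(g) {
    sample(bin_members[[as.character(bin[g])]], config$n_control_per_gene,
           replace = TRUE)
  }), use.names = FALSE)
  set_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Annotate clusters with cell types from marker tables
#'
#' Scales each gene's mean expression across clusters to z-scores (genes with
#' zero variance contribute 0) and assigns every cluster the type whose
#' markers have the highest mean z-score. Clusters whose best score does not
#' exceed `min_margin` are labeled "unknown".
#'
#' @param cluster_mean_expr Clusters x genes matrix of mean expression.
#' @param markers Named list mapping type to marker gene ids; markers absent
#'   from the matrix are dropped with a warning, a type losing all markers is
#'   an error.
#' @param min_margin Minimum best score for a confident call.
#' @return Named character vector: type per cluster.
#' @export
annotate_cell_types <- function(cluster_mean_expr, markers, min_margin = 0) {
  if (length(markers) == 0) stop("empty marker table")
  z <- scale(cluster_mean_expr)
  z[is.nan(z)] <- 0
  z[is.na(z)] <- 0
  scores <- vapply(names(markers), function(type) {
    mk <- intersect(markers[[type]], colnames(cluster_mean_expr))
    if (length(mk) < length(markers[[type]])) {
      warning("type ", type, ": dropping markers absent from matrix")
    }
    if (length(mk) == 0) stop("type ", type, " has no markers in matrix")
    rowMeans(z[, mk, drop = FALSE])
  }, numeric(nrow(cluster_mean_expr)))
  scores <- matrix(scores, nrow = nrow(cluster_mean_expr),
                   dimnames = list(rownames(cluster_mean_expr),
                                   names(markers)))
  best <- max.col(scores, ties.method = "first")
  label <- colnames(scores)[best]
  label[scores[cbind(seq_len(nrow(scores)), best)] <= min_margin] <- "unknown"
  stats::setNames(label, rownames(scores))
}

#' Epithelial subtype from the six-marker rule
#'
#' Marker positivity: a marker is "+" for a cell when its normalized
#' expression exceeds `positivity_threshold`; with cluster labels supplied, a
#' marker is "+" for all cells of a cluster in which at least
#' `min_positive_fraction` of cells exceed the threshold. Rules are applied
#' in precedence order: MEC (ACTA2+ & MYH11+ & CNN1+), else Inter-Duct
#' (KRT19+ & AQP5+ & KIT+), else Duct (KRT19+ & AQP5- & KIT-), else
#' unresolved.
#'
#' @param expr Normalized expression, genes x cells, containing the six
#'   marker genes (see [subtype_marker_genes()]).
#' @param positivity_threshold Expression above this is "+".
#' @param clusters Optional cluster label per cell (same order as columns).
#' @param min_positive_fraction Cluster-level positivity fraction.
#' @return Character vector per cell: MEC, Inter-Duct, Duct, or unresolved.
#' @export
epithelial_subtype <- function(expr, positivity_threshold = 0,
                               clusters = NULL,
                               min_positive_fraction = 0.25) {
  need <- subtype_marker_genes()
  missing <- setdiff(need, rownames(expr))
  if (length(missing) > 0) {
    stop("missing subtype marker gene: ", missing[1])
  }
  pos <- as.matrix(expr[need, , drop = FALSE]) > positivity_threshold
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == ncol(expr))
    for (cl in unique(clusters)) {
      j <- clusters == cl
      frac <- rowMeans(pos[, j, drop = FALSE])
      pos[, j] <- frac >= min_positive_fraction
    }
  }
  p <- function(g) pos[g, ]
  out <- rep("unresolved", ncol(expr))
  duct <- p("KRT19") & !p("AQP5") & !p("KIT")
  inter <- p("KRT19") & p("AQP5") & p("KIT")
  mec <- p("ACTA2") & p("MYH11") & p("CNN1")
  out[duct] <- "Duct"
  out[inter] <- "Inter-Duct"
  out[mec] <- "MEC"
  stats::setNames(out, colnames(expr))
}

#' Relative abundance per stratum
#'
#' Counts and percentages of each label within each stratum (percentages sum
#' to 100 per stratum). Strata without cells are omitted with a warning.
#'
#' @param labels Label per cell.
#' @param strata Stratum (e.g. tissue or sample) per cell.
#' @return Data frame `stratum`, `label`, `n`, `pct`.
#' @export
abundance_table <- function(labels, strata) {
  stopifnot(length(labels) == length(strata))
  if (is.factor(strata) && any(table(strata) == 0)) {
    warning("omitting empty stratum: ",
            paste(names(which(table(strata) == 0)), collapse = ", "))
  }
  tab <- table(stratum = as.character(strata), label = as.character(labels))
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  totals <- rowSums(tab)
  df$pct <- 100 * df$n / totals[df$stratum]
  df <- df[order(df$stratum, df$label), ]
  rownames(df) <- NULL
  df
}
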