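#' Spike-in / banding configuration
#'
#' Parameters of the malignancy classifier: `n_spike_total` stromal cells are
#' drawn from the paracarcinoma samples, of which `n_reference` serve as the
#' CNV reference and the rest are spiked into the observation set; the
#' malignant distance band is the median +/- `band_sd_multiplier` SD of
#' carcinoma-epithelial distances, under the assumption that
#' `assumed_malignant_fraction` of carcinoma epithelial cells are truly
#' malignant.
#'
#' @param n_spike_total Total stromal cells picked.
#' @param n_reference How many of them form the reference (< `n_spike_total`).
#' @param band_sd_multiplier SD multiplier of the distance band.
#' @param assumed_malignant_fraction Assumed malignant fraction among
#'   carcinoma epithelial cells (audited, not enforced).
#' @param linkage Hierarchical clustering linkage for the dendrogram test
#'   (`stats::hclust` method; Ward by default).
#' @param max_k Largest number of clusters tried when the dendrogram test
#'   escalates.
#' @param seed Seed for the stochastic spike-in draw.
#' @return Object of class `spike_config`.
#' @export
spike_config <- function(n_spike_total = 1600, n_reference = 1000,
                         band_sd_multiplier = 2,
                         assumed_malignant_fraction = 0.95,
                         linkage = "ward.D2", max_k = 10, seed = 1L) {
  stopifnot(n_reference < n_spike_total, band_sd_multiplier > 0,
            assumed_malignant_fraction > 0, assumed_malignant_fraction < 1,
            max_k >= 2)
  structure(list(n_spike_total = as.integer(n_spike_total),
                 n_reference = as.integer(n_reference),
                 band_sd_multiplier = band_sd_multiplier,
                 assumed_malignant_fraction = assumed_malignant_fraction,
                 linkage = linkage, max_k = as.integer(max_k),
                 seed = as.integer(seed)),
            class = "spike_config")
}

#' Partition stromal cells into reference and spiked observation sets
#'
#' Stochastically picks `n_spike_total` stromal cells without replacement;
#' the first `n_reference` become the CNV reference, the remainder are the
#' "spiked" normal cells carried into the observation set for the dendrogram
#' test. Deterministic given the config seed.
#'
#' @param stromal_cell_ids Ids of available paracarcinoma stromal cells
#'   (fibroblasts and endothelial cells).
#' @param config A [spike_config()].
#' @return List with `reference` and `observation` id vectors (disjoint).
#' @export
spike_in_partition <- function(stromal_cell_ids, config = spike_config()) {
  n <- length(stromal_cell_ids)
  if (n < config$n_spike_total) {
    stop("need ", config$n_spike_total, " stromal cells, only ", n,
         " available")
  }
  set.seed(config$seed)
  picked <- sample(stromal_cell_ids, config$n_spike_total)
  list(reference = picked[seq_len(config$n_reference)],
       observation = picked[(config$n_reference + 1):config$n_spike_total])
}

#' Dendrogram spike-in test for normal epithelial cells
#'
#' Hierarchically clusters the pooled CNV profiles of the spiked stromal
#' cells and the epithelial cells (Euclidean distance, configured linkage)
#' and cuts the tree into 2 clusters. The cluster holding more than half of
#' the spiked stromal cells is the "normal" cluster; epithelial members of it
#' are called normal-epithelial. If no cluster holds a strict majority of the
#' spiked cells, the cut is escalated one cluster at a time up to `max_k`
#' before failing with a diagnostic. When all profiles are (numerically)
#' identical there is a single effective cluster containing every spiked
#' cell, so every epithelial cell is normal-epithelial.
#'
#' @param profiles A `cnv_profile` or cells x genes matrix covering both id
#'   sets.
#' @param spiked_observation_ids Ids of the spiked stromal cells.
#' @param epithelial_ids Ids of the epithelial cells under test.
#' @param config A [spike_config()].
#' @return Character vector of the epithelial ids labeled normal-epithelial
#'   (possibly empty), with the cut `k` attached as attribute `k`.
#' @export
classify_normal_epithelial <- function(profiles, spiked_observation_ids,
                                       epithelial_ids,
                                       config = spike_config()) {
  m <- profile_matrix(profiles)
  ids <- c(spiked_observation_ids, epithelial_ids)
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0) stop("profiles missing cells: ", missing[1])
  x <- m[ids, , drop = FALSE]
  d <- euclidean_dist(x)
  if (max(d) < 1e-6 * (1 + max(abs(x)))) {
    # degenerate: one effective cluster containing all spiked cells
    return(structure(epithelial_ids, k = 1L))
  }
  tree <- stats::hclust(d, method = config$linkage)
  n_spiked <- length(spiked_observation_ids)
  for (k in 2:config$max_k) {
    cl <- stats::cutree(tree, k = k)
    spiked_per_cluster <- table(cl[spiked_observation_ids])
    winner <- names(spiked_per_cluster)[spiked_per_cluster > n_spiked / 2]
    if (length(winner) == 1) {
      members <- names(cl)[cl == as.integer(winner)]
      return(structure(intersect(epithelial_ids, members), k = k))
    }
  }
  stop("dendrogram test unresolved: no cluster holds >50% of the ", n_spiked,
       " spiked stromal cells at any cut k = 2..", config$max_k,
       "; the spiked cells split evenly across clusters")
}

# all-pairs Euclidean distances via the Gram matrix (BLAS-backed; equivalent
# to stats::dist up to floating-point rounding)
euclidean_dist <- function(x) {
  g <- tcrossprod(x)
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0
  stats::as.dist(sqrt(d2))
}

#' Fibroblast baseline CNV profile
#'
#' Per-gene median of the supplied fibroblast profiles — the zero point that
#' epithelial distances are measured against.
#'
#' @param fibroblast_profiles A `cnv_profile` or cells x genes matrix
#'   restricted to paracarcinoma fibroblasts (>= 1 cell).
#' @return Named numeric vector, one median per gene.
#' @export
baseline_profile <- function(fibroblast_profiles) {
  m <- profile_matrix(fibroblast_profiles)
  if (nrow(m) < 1) stop("need at least one fibroblast profile")
  apply(m, 2, stats::median)
}

#' Malignant distance band
#'
#' The closed interval median +/- `band_sd_multiplier` x SD (n - 1
#' denominator) of the carcinoma-epithelial distances, floored at 0 since
#' distances are nonnegative. The realized in-band fraction is reported so the
#' assumed malignant fraction can be audited against it.
#'
#' @param distances_carcinoma_epithelial Nonnegative distances of carcinoma
#'   epithelial cells to the baseline (>= 2 values).
#' @param config A [spike_config()].
#' @return Object of class `malignant_band`: list with `lo`, `hi`, `median`,
#'   `sd`, `realized_fraction`, `n`.
#' @export
malignant_band <- function(distances_carcinoma_epithelial,
                           config = spike_config()) {
  d <- distances_carcinoma_epithelial
  if (length(d) < 2) stop("need at least 2 distances to build a band")
  med <- stats::median(d)
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero SD of distances: degenerate band [median, median]")
  }
  lo <- max(0, med - config$band_sd_multiplier * s)
  hi <- med + config$band_sd_multiplier * s
  structure(list(lo = lo, hi = hi, median = med, sd = s,
                 realized_fraction = mean(d >= lo & d <= hi),
                 n = length(d)),
            class = "malignant_band")
}

#' @export
print.malignant_band <- function(x, ...) {
  cat(sprintf(
    "malignant_band: [%.4g, %.4g] (median %.4g, SD %.4g); %.1f%% of %d cells in band\n",
    x$lo, x$hi, x$median, x$sd, 100 * x$realized_fraction, x$n))
  invisible(x)
}

#' Call pre-malignant versus malignant epithelial cells
#'
#' Epithelial cells whose distance lies inside the (closed) malignant band
#' are malignant; cells outside it are pre-M. Cells previously labeled
#' normal-epithelial by the dendrogram test keep that label.
#'
#' @param distances Named vector of distances covering all epithelial cells.
#' @param band A [malignant_band()].
#' @param epithelial_ids Ids of epithelial cells to call.
#' @param normal_epithelial_ids Ids already labeled normal-epithelial.
#' @return Data frame `cell_id`, `label` (one of normal-epithelial,
#'   malignant, pre-M), `distance`, `in_band`.
#' @export
call_premalignant <- function(distances, band, epithelial_ids,
                              normal_epithelial_ids = character(0)) {
  missing <- setdiff(epithelial_ids, names(distances))
  if (length(missing) > 0) {
    stop("no distance available for cell: ", missing[1])
  }
  d <- distances[epithelial_ids]
  in_band <- d >= band$lo & d <= band$hi
  label <- ifelse(in_band, "malignant", "pre-M")
  label[epithelial_ids %in% normal_epithelial_ids] <- "normal-epithelial"
  data.frame(cell_id = epithelial_ids, label = label,
             distance = unname(d), in_band = unname(in_band),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise rank-sum comparison of distance groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests between every pair of
#' groups: exact when both groups have <= 20 observations (and falls back to
#' the normal approximation under ties), otherwise the normal approximation
#' with continuity correction.
#'
#' @param distances Numeric vector.
#' @param group_labels Group label per observation (>= 2 non-empty groups).
#' @return Data frame `group1`, `group2`, `n1`, `n2`, `statistic` (W),
#'   `p_value`.
#' @export
compare_distance_groups <- function(distances, group_labels) {
  groups <- split(distances, group_labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  pairs <- utils::combn(names(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    exact <- length(x) <= 20 && length(y) <= 20
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Class-wise F1 score
#'
#' Harmonic mean of precision and recall for one label, comparing predicted
#' against true labels (0 when the label is never predicted or never true).
#'
#' @param truth,predicted Label vectors of equal length.
#' @param label The class evaluated.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(truth, predicted, label) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == label & predicted == label)
  fp <- sum(truth != label & predicted == label)
  fn <- sum(truth == label & predicted != label)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
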