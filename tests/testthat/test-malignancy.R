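test_that("spike-in partition draws disjoint reference and observation sets", {
  ids <- sprintf("cell%04d", 1:1600)
  part <- spike_in_partition(ids, spike_config(seed = 5))
  expect_length(part$reference, 1000)
  expect_length(part$observation, 600)
  expect_length(intersect(part$reference, part$observation), 0)
  expect_setequal(c(part$reference, part$observation), ids)

  part2 <- spike_in_partition(ids, spike_config(seed = 5))
  expect_identical(part, part2)

  expect_error(spike_in_partition(ids[1:1599], spike_config()), "1599")
})

test_that("dendrogram test separates flat from CNV-bearing epithelium", {
  set.seed(6)
  n_genes <- 120
  mk <- function(n, shift_genes = integer(0), shift = 0, prefix) {
    m <- matrix(rnorm(n * n_genes, sd = 0.05), n, n_genes)
    m[, shift_genes] <- m[, shift_genes] + shift
    rownames(m) <- paste0(prefix, seq_len(n))
    m
  }
  spiked <- mk(20, prefix = "s")
  flat_epi <- mk(6, prefix = "flat")
  cnv_epi <- mk(15, shift_genes = 1:40, shift = 0.8, prefix = "mal")
  prof <- rbind(spiked, flat_epi, cnv_epi)
  normal <- classify_normal_epithelial(
    prof, rownames(spiked), c(rownames(flat_epi), rownames(cnv_epi)),
    spike_config(seed = 6))
  expect_setequal(normal, rownames(flat_epi))
  expect_equal(attr(normal, "k"), 2L)
})

test_that("identical profiles collapse to one normal cluster", {
  prof <- matrix(0.3, 12, 30,
                 dimnames = list(paste0("c", 1:12), NULL))
  normal <- classify_normal_epithelial(prof, paste0("c", 1:6),
                                       paste0("c", 7:12))
  expect_setequal(as.character(normal), paste0("c", 7:12))
  expect_equal(attr(normal, "k"), 1L)
})

test_that("an even spiked split escalates and then fails with a diagnostic", {
  set.seed(7)
  a <- matrix(rnorm(2 * 30, mean = 0, sd = 0.01), 2, 30)
  b <- matrix(rnorm(2 * 30, mean = 10, sd = 0.01), 2, 30)
  epi <- matrix(rnorm(5 * 30, mean = 10, sd = 0.01), 5, 30)
  prof <- rbind(a, b, epi)
  rownames(prof) <- c("s1", "s2", "s3", "s4", paste0("e", 1:5))
  expect_error(
    classify_normal_epithelial(prof, paste0("s", 1:4), paste0("e", 1:5),
                               spike_config(max_k = 4, seed = 7)),
    "k = 2..4", fixed = TRUE)
})

test_that("baseline profile is the per-gene median", {
  one <- matrix(rnorm(25), 1, 25)
  expect_equal(baseline_profile(one), one[1, ])

  three <- rbind(a = c(0, 2), b = c(1, 9), c = c(5, 4))
  expect_equal(unname(baseline_profile(three)), c(1, 4))

  set.seed(8)
  m <- matrix(rnorm(5 * 40), 5, 40)
  oracle <- vapply(seq_len(40), function(j) sort(m[, j])[3], numeric(1))
  expect_equal(unname(baseline_profile(m)), oracle)

  expect_error(baseline_profile(m[0, , drop = FALSE]), "at least one")
})

test_that("the malignant band is median +/- k SD, closed and floored", {
  d <- c(1, 2, 3, 4, 100)
  band <- malignant_band(d, spike_config(band_sd_multiplier = 2))
  expect_equal(band$median, 3)
  expect_equal(band$sd, sd(d))
  expect_equal(band$hi, 3 + 2 * sd(d))
  expect_equal(band$lo, max(0, 3 - 2 * sd(d)))

  expect_warning(deg <- malignant_band(rep(4, 10)), "degenerate")
  expect_equal(c(deg$lo, deg$hi), c(4, 4))
  expect_equal(deg$realized_fraction, 1)

  expect_error(malignant_band(3), "at least 2")
})

test_that("a Gaussian distance cloud lands ~95.45% inside the band", {
  set.seed(9)
  d <- rnorm(10000, mean = 10, sd = 1)
  band <- malignant_band(d)
  expect_lt(abs(band$realized_fraction - (2 * pnorm(2) - 1)), 0.01)
  expect_gte(band$realized_fraction, 0.95)
})

test_that("pre-M calls fall outside the closed band", {
  band <- structure(list(lo = 2, hi = 6, median = 4, sd = 1,
                         realized_fraction = NA, n = 0),
                    class = "malignant_band")
  d <- c(a = 4, b = 6, c = 6 + 1e-9, d = 1.99, e = 2)
  calls <- call_premalignant(d, band, names(d))
  expect_equal(calls$label[calls$cell_id == "a"], "malignant")
  expect_equal(calls$label[calls$cell_id == "b"], "malignant")  # boundary in
  expect_equal(calls$label[calls$cell_id == "c"], "pre-M")
  expect_equal(calls$label[calls$cell_id == "d"], "pre-M")
  expect_equal(calls$label[calls$cell_id == "e"], "malignant")

  withheld <- call_premalignant(d, band, names(d),
                                normal_epithelial_ids = "a")
  expect_equal(withheld$label[withheld$cell_id == "a"], "normal-epithelial")

  expect_error(call_premalignant(d, band, c(names(d), "ghost")), "ghost")
})

test_that("widening the band never converts malignant calls to pre-M", {
  set.seed(10)
  d <- setNames(abs(rnorm(300, 5, 2)), paste0("c", 1:300))
  calls2 <- call_premalignant(d, malignant_band(d, spike_config()), names(d))
  calls3 <- call_premalignant(
    d, malignant_band(d, spike_config(band_sd_multiplier = 3)), names(d))
  mal2 <- calls2$cell_id[calls2$label == "malignant"]
  mal3 <- calls3$cell_id[calls3$label == "malignant"]
  expect_true(all(mal2 %in% mal3))
})

test_that("rank-sum comparisons match enumeration and detect separation", {
  # exact small-sample p against brute-force enumeration of rank splits
  set.seed(11)
  x <- rnorm(5); y <- rnorm(5) + 0.5
  got <- compare_distance_groups(c(x, y), rep(c("g1", "g2"), each = 5))
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[1:5]) - 5 * 6 / 2
  combos <- utils::combn(10, 5)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - 15
  p_oracle <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(got$p_value, p_oracle)

  # fully separated large groups: p at the reporting threshold
  set.seed(12)
  big <- compare_distance_groups(
    c(rnorm(600), rnorm(600) + 10),
    rep(c("lo", "hi"), each = 600))
  expect_lte(big$p_value, 1e-4)

  expect_error(compare_distance_groups(rnorm(5), rep("a", 5)), "2 groups")
})

test_that("every epithelial cell receives exactly one label", {
  sim <- small_sim()
  res <- run_malignancy_pipeline(sim$counts, sim$cells, sim$catalog,
                                 qc = small_qc_config(),
                                 cnv = small_cnv_config(),
                                 spike = small_spike_config())
  epi_kept <- intersect(sim$cells$cell_id[sim$cells$cell_type == "epithelial"],
                        res$qc$cell_id[res$qc$keep])
  expect_setequal(res$calls$cell_id, epi_kept)
  expect_false(any(duplicated(res$calls$cell_id)))
  expect_true(all(res$calls$label %in%
                    c("normal-epithelial", "malignant", "pre-M")))
  # label/flag consistency
  expect_true(all(res$calls$in_band[res$calls$label == "malignant"]))
  expect_false(any(res$calls$in_band[res$calls$label == "pre-M"]))
})

test_that("calls are stable under a different spike-in seed", {
  sim <- small_sim()
  res_a <- run_malignancy_pipeline(sim$counts, sim$cells, sim$catalog,
                                   qc = small_qc_config(),
                                   cnv = small_cnv_config(),
                                   spike = small_spike_config(seed = 1))
  res_b <- run_malignancy_pipeline(sim$counts, sim$cells, sim$catalog,
                                   qc = small_qc_config(),
                                   cnv = small_cnv_config(),
                                   spike = small_spike_config(seed = 2))
  shared <- intersect(res_a$calls$cell_id, res_b$calls$cell_id)
  la <- res_a$calls$label[match(shared, res_a$calls$cell_id)]
  lb <- res_b$calls$label[match(shared, res_b$calls$cell_id)]
  expect_lt(mean(la != lb), 0.05)
})
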