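test_that("make_genome builds an ordered, flag-accurate catalog", {
  cat1 <- make_genome(1, 10, 0, 0, seed = 3)
  expect_equal(nrow(cat1), 10)
  expect_equal(unique(cat1$chromosome), "chr1")
  expect_false(any(cat1$is_mito | cat1$is_hemoglobin))

  # positions strictly increasing within each chromosome
  cat2 <- make_genome(5, 100, seed = 4)
  for (ch in unique(cat2$chromosome)) {
    expect_true(all(diff(cat2$start[cat2$chromosome == ch]) > 0))
  }

  # determinism
  expect_identical(make_genome(5, 100, 0.01, 0.005, seed = 9),
                   make_genome(5, 100, 0.01, 0.005, seed = 9))

  # flag counts within one gene of the requested fractions, by direct count
  cat3 <- make_genome(3, 100, 0.1, 0.1, seed = 5)
  expect_lte(abs(sum(cat3$is_mito) - 0.1 * 300), 1)
  expect_lte(abs(sum(cat3$is_hemoglobin) - 0.1 * 300), 1)
  expect_false(any(cat3$is_mito & cat3$is_hemoglobin))

  expect_error(make_genome(0, 100), "invalid")
  expect_error(make_genome(3, 5), "invalid")
})

test_that("implant_cnv scales means inside segments and only there", {
  cat <- make_genome(3, 20, seed = 1)
  mu <- runif(nrow(cat), 0.5, 2)

  whole <- implant_cnv(mu, data.frame(chromosome = "chr2", start_frac = 0,
                                      end_frac = 1, copy_ratio = 1.5), cat)
  on2 <- cat$chromosome == "chr2"
  expect_equal(whole[on2], mu[on2] * 1.5)
  expect_equal(whole[!on2], mu[!on2])

  expect_identical(implant_cnv(mu, data.frame(chromosome = character(0),
                                              start_frac = numeric(0),
                                              end_frac = numeric(0),
                                              copy_ratio = numeric(0)), cat),
                   mu)

  # half-chromosome loss, checked by recomputing each gene independently
  segs <- data.frame(chromosome = "chr3", start_frac = 0.5, end_frac = 1,
                     copy_ratio = 0.5)
  half <- implant_cnv(mu, segs, cat)
  expected <- mu
  rows3 <- which(cat$chromosome == "chr3")
  for (i in seq_along(rows3)) {
    if ((i - 0.5) / length(rows3) >= 0.5) {
      expected[rows3[i]] <- mu[rows3[i]] * 0.5
    }
  }
  expect_equal(half, expected)
  altered <- half != mu
  expect_equal(mean(half[altered] / mu[altered]), 0.5)

  # overlapping segments multiply
  twice <- implant_cnv(mu, rbind(segs, segs), cat)
  expect_equal(twice[altered], mu[altered] * 0.25)

  expect_error(implant_cnv(mu, data.frame(chromosome = "chr9",
                                          start_frac = 0, end_frac = 1,
                                          copy_ratio = 2), cat), "chr9")
})

test_that("simulate_cells is deterministic and honors the outlier fraction", {
  cfg <- small_config(seed = 21)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)

  clean <- simulate_dataset(small_config(seed = 22,
                                         outlier_cell_fraction = 0))
  expect_false(any(clean$truth$is_outlier))

  expect_equal(sum(a$truth$is_outlier),
               round(0.01 * ncol(a$counts)))
})

test_that("empirical gene means match the configured means", {
  # one epithelial population, no outliers, 2,000 cells
  cfg <- sim_config(
    n_chromosomes = 2, genes_per_chromosome = 150, n_patients = 1,
    cell_counts = list(paracarcinoma = c(fibroblast = 1, Duct = 2000),
                       carcinoma = c(fibroblast = 1, Duct = 1)),
    cnv_segments = data.frame(chromosome = "chr2", start_frac = 0.5,
                              end_frac = 1, copy_ratio = 1.5),
    prem_cnv_segments = data.frame(chromosome = "chr2", start_frac = 0,
                                   end_frac = 0.5, copy_ratio = 0.5),
    prem_fraction = c(paracarcinoma = 0, carcinoma = 0),
    outlier_cell_fraction = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  tr <- truth_for(sim, colnames(sim$counts))
  duct <- tr$population == "Duct" & tr$malignancy_truth == "malignant" &
    sim$cells$tissue == "paracarcinoma"
  mu <- sim$group_means[["P1_paracarcinoma.Duct.malignant"]]
  x <- sim$counts[, duct, drop = FALSE]
  emp <- Matrix::rowMeans(x)
  se <- sqrt((mu + mu^2 / cfg$nb_dispersion) / ncol(x))
  expect_gte(mean(abs(emp - mu) <= 3 * se), 0.99)
})

test_that("stromal means carry no CNV leakage; malignant means differ only on segments", {
  sim <- small_sim()
  gm <- sim$group_means
  # stromal means identical across tissues and populations up to markers
  fib_pc <- gm[["P1_paracarcinoma.fibroblast.normal"]]
  fib_c <- gm[["P1_carcinoma.fibroblast.normal"]]
  expect_identical(fib_pc, fib_c)
  endo <- gm[["P1_paracarcinoma.endothelial.normal"]]
  markers <- match(unique(c(unlist(default_marker_table()),
                            subtype_marker_genes())), sim$catalog$gene_id)
  non_marker <- setdiff(seq_along(fib_pc), markers)
  expect_identical(fib_pc[non_marker], endo[non_marker])

  # malignant means equal stromal means times the segment copy ratios at
  # non-marker genes, and exactly equal them outside all segments
  duct_mal <- gm[["P1_carcinoma.Duct.malignant"]]
  cfg <- small_config()
  ratio <- implant_cnv(rep(1, nrow(sim$catalog)), cfg$cnv_segments,
                       sim$catalog)
  stem <- match(stemness_genes(), sim$catalog$gene_id)
  plain <- setdiff(non_marker, stem)
  outside <- intersect(plain, which(ratio == 1))
  inside <- intersect(plain, which(ratio != 1))
  expect_identical(duct_mal[outside], fib_pc[outside])
  expect_equal(duct_mal[inside], fib_pc[inside] * ratio[inside])
})

test_that("implanted gains are visible in empirical expression ratios", {
  # segment-effect invariant: inside/outside mean ratio near the copy ratio
  cfg <- sim_config(
    n_chromosomes = 2, genes_per_chromosome = 100, n_patients = 1,
    cell_counts = list(paracarcinoma = c(fibroblast = 1, Duct = 1),
                       carcinoma = c(fibroblast = 1, Duct = 2000)),
    cnv_segments = data.frame(chromosome = "chr2", start_frac = 0,
                              end_frac = 1, copy_ratio = 1.5),
    prem_cnv_segments = data.frame(chromosome = "chr2", start_frac = 0,
                                   end_frac = 0.5, copy_ratio = 0.5),
    prem_fraction = c(paracarcinoma = 0, carcinoma = 0),
    outlier_cell_fraction = 0, seed = 41)
  sim <- simulate_dataset(cfg)
  tr <- truth_for(sim, colnames(sim$counts))
  mal <- tr$malignancy_truth == "malignant"
  mu0 <- sim$group_means[["P1_carcinoma.fibroblast.normal"]]
  emp <- Matrix::rowMeans(sim$counts[, mal, drop = FALSE])
  # marker genes are population-boosted; compare unboosted genes only
  markers <- sim$catalog$gene_id %in%
    unique(c(unlist(default_marker_table()), subtype_marker_genes(),
             stemness_genes()))
  on2 <- sim$catalog$chromosome == "chr2" & !markers
  off2 <- sim$catalog$chromosome != "chr2" & !markers
  ratio <- mean(emp[on2] / mu0[on2]) / mean(emp[off2] / mu0[off2])
  expect_lt(abs(ratio - 1.5) / 1.5, 0.1)
})

test_that("configurations without fibroblasts or epithelium are rejected", {
  expect_error(sim_config(cell_counts = list(
    paracarcinoma = c(endothelial = 50, Duct = 50),
    carcinoma = c(endothelial = 50, Duct = 50))), "fibroblast")
  expect_error(sim_config(cell_counts = list(
    paracarcinoma = c(fibroblast = 50, endothelial = 50),
    carcinoma = c(fibroblast = 50, endothelial = 50))), "epithelial")
})

test_that("10x-style directory round-trips through write and read", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim_10x(sim, dir)
  back <- read_counts_10x(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$counts))
  expect_equal(back$catalog$gene_id, sim$catalog$gene_id)
  expect_equal(back$cells$sample_id, sim$cells$sample_id)
  expect_equal(back$truth$malignancy_truth, sim$truth$malignancy_truth)
})
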