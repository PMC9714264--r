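#!/usr/bin/env Rscript
# Step 2 — per-sample adaptive quality control: each metric (genes detected,
# % mitochondrial, % hemoglobin) is bounded above by mean + 2.58 SD within
# its sample, on top of the fixed floors (>200 genes, <30% mito, <10% hb).
# Also fits the loading/multiplet-rate line used to pick doublet rates.

suppressPackageStartupMessages(library(premcnv))

seed <- 1L
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_dataset(sim_config(seed = seed))
metrics <- compute_qc_metrics(sim$counts, sim$catalog, sim$cells)
verdicts <- filter_cells(metrics, qc_config())

write.table(attr(verdicts, "thresholds"),
            "results/tables/02_qc_thresholds.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

per_sample <- do.call(rbind, lapply(split(verdicts, verdicts$sample_id),
  function(s) data.frame(sample_id = s$sample_id[1], n = nrow(s),
                         kept = sum(s$keep),
                         discarded = sum(!s$keep))))
write.table(per_sample, "results/tables/02_qc_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- sim$truth[match(verdicts$cell_id, sim$truth$cell_id), ]
message(sprintf("kept %d / %d cells (%.2f%%)", sum(verdicts$keep),
                nrow(verdicts), 100 * mean(verdicts$keep)))
message(sprintf("implanted outliers discarded: %d / %d",
                sum(!verdicts$keep & truth$is_outlier),
                sum(truth$is_outlier)))
message(sprintf("normal cells kept: %.2f%%",
                100 * mean(verdicts$keep[!truth$is_outlier])))

# expected multiplet rate at this loading, from a published-style rate table
rate_table <- data.frame(cells_loaded = c(800, 1600, 3200, 6400, 12800),
                         multiplet_rate = c(0.4, 0.8, 1.6, 3.2, 6.4))
n_loaded <- max(table(sim$cells$sample_id))
message(sprintf("expected multiplet rate at %d loaded cells: %.2f%%",
                n_loaded, expected_multiplet_rate(rate_table, n_loaded)))
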