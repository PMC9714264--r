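# Small, fast simulation used by most unit tests: one pseudo-patient, a
# 4 x 60-gene genome, one gain and one loss for malignant cells, and the
# deviant amplified-plus-private pattern for pre-M cells. Window 9 keeps the
# 30-gene segments >= 3 windows wide.
small_config <- function(seed = 11L, ...) {
  sim_config(
    n_chromosomes = 4, genes_per_chromosome = 60, n_patients = 1,
    cell_counts = list(
      paracarcinoma = c(fibroblast = 60, endothelial = 30, MEC = 20,
                        "Inter-Duct" = 30, Duct = 20),
      carcinoma = c(fibroblast = 10, endothelial = 5, MEC = 30,
                    "Inter-Duct" = 60, Duct = 40)),
    cnv_segments = data.frame(
      chromosome = c("chr2", "chr3"),
      start_frac = c(0.5, 0.0), end_frac = c(1.0, 0.5),
      copy_ratio = c(1.5, 0.5)),
    prem_cnv_segments = data.frame(
      chromosome = c("chr2", "chr3", "chr4"),
      start_frac = c(0.5, 0.0, 0.5), end_frac = c(1.0, 0.5, 1.0),
      copy_ratio = c(1.9, 0.5, 1.8)),
    seed = seed, ...)
}

small_spike_config <- function(seed = 11L) {
  spike_config(n_spike_total = 80, n_reference = 50, seed = seed)
}

small_cnv_config <- function(...) cnv_config(window_genes = 9, ...)

# the 240-gene toy genome cannot clear the production >200-genes floor
small_qc_config <- function(...) qc_config(min_genes = 50, ...)

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_config())
    cache
  }
})

# Standard fixture at full defaults (3 pseudo-patients, ~5,700 cells), with
# the pipeline run once and shared across tests.
standard_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_dataset(sim_config(seed = 101L))
      res <- run_malignancy_pipeline(
        sim$counts, sim$cells, sim$catalog,
        cnv = cnv_config(window_genes = 31),
        spike = spike_config(seed = 101L))
      cache <<- list(sim = sim, res = res)
    }
    cache
  }
})

# truth rows aligned to a vector of cell ids
truth_for <- function(sim, cell_ids) {
  sim$truth[match(cell_ids, sim$truth$cell_id), ]
}
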