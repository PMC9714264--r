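# premcnv

Identify **pre-malignant (pre-M) epithelial cells** in single-cell RNA-seq of
carcinoma and adjacent (paracarcinoma) tissue, from expression-based
copy-number-variation (CNV) profiles.

Gland-derived carcinomas recur even after resection with clean margins; one
explanation is that the "normal" adjacent tissue already harbors epithelial
cells with aberrant genomes that histology cannot detect. Large chromosomal
gains and losses leave a dosage footprint on expression, so each cell's CNV
landscape — and how far it sits from a normal baseline — can be estimated
from its transcriptome. `premcnv` is aimed at computational biologists who
want that calling procedure as tested, reusable functions rather than a
one-off analysis script.

## The method

For cell *i* with counts *x·ᵢ*, the CNV profile is

* *y_gi* = log₂(10⁴ · x_gi / Σ_g x_gi + 1) − mean over reference cells,
  per gene *g* (reference: 1,000 of 1,600 randomly drawn paracarcinoma
  stromal cells);
* *s·ᵢ* = boxcar moving average of *y·ᵢ* over *w* genes in genomic order
  within each chromosome (edges truncated), re-centered by median(*s·ᵢ*),
  clipped at ±3 SD of the reference cells' smoothed values.

The remaining 600 stromal cells are "spiked" into the observation set; after
Ward clustering of pooled profiles is cut at k = 2, epithelial members of the
cluster holding >50% of the spiked cells are *normal epithelial* and leave
the analysis. With baseline *b* = per-gene median profile of paracarcinoma
fibroblasts and distances *dᵢ* = ‖*sᵢ* − *b*‖₂, the **malignant band** is

  [ median(d) − 2·SD(d), median(d) + 2·SD(d) ]

over carcinoma-sample epithelial cells — justified by assuming ~95% of
carcinoma epithelium is truly malignant (a Gaussian cloud puts
2Φ(2) − 1 ≈ 95.45% of cells in the band). Epithelial cells inside the band
are **malignant**, outside it **pre-M**.

Around the core sit: per-sample adaptive QC (each metric bounded by
mean + 2.58 SD, plus fixed floors >200 genes, <30% mito, <10% hemoglobin),
an OLS loading→multiplet-rate line, binned-control gene-set (stemness)
scoring, marker-rule epithelial subtyping (MEC / Inter-Duct / Duct), and
Wilcoxon rank-sum group comparisons. A negative-binomial simulator with
implanted CNV segments (`simulate_dataset()`) makes every stage testable
offline against ground truth.

## Worked example

```r
library(premcnv)

sim <- simulate_dataset(sim_config(seed = 1))
sim
#> sim_data: 2000 genes x 5700 cells; 6 samples; 57 outlier cells
#>              malignant normal pre-M
#>   Duct             870      0   180
#>   endothelial        0    600     0
#>   fibroblast         0   1500     0
#>   Inter-Duct      1377      0   273
#>   MEC              726      0   174

res <- run_malignancy_pipeline(sim$counts, sim$cells, sim$catalog,
                               cnv = cnv_config(window_genes = 31),
                               spike = spike_config(seed = 1))
res$band
#> malignant_band: [12.47, 16.72] (median 14.59, SD 1.061); 94.3% of 2511 cells in band

truth <- sim$truth[match(res$calls$cell_id, sim$truth$cell_id), ]
f1_score(truth$malignancy_truth, res$calls$label, "pre-M")
#> [1] 0.9431818
f1_score(truth$malignancy_truth, res$calls$label, "malignant")
#> [1] 0.9880587
```

Reading the output: the band's realized in-band fraction (94.3%) audits the
95%-malignant assumption; the two F1 scores say the procedure recovers the
implanted pre-M / malignant split almost perfectly. The dendrogram test
found 0 normal epithelial cells here — consistent with CNV-bearing
epithelium throughout. Stemness module scores are higher in pre-M than in
malignant cells (`analysis/05_scoring.R` prints the means and the rank-sum
p-value).

## The analysis workflow

Numbered drivers under `analysis/` run the study end-to-end on the simulated
design and write summary tables to `results/tables/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the 3-patient, ~5,700-cell fixture; design table |
| `02_qc.R` | adaptive QC; thresholds and per-sample keep counts; multiplet-rate fit |
| `03_cnv_infer.R` | CNV profiles; per-arm mean profile by truth class |
| `04_malignancy.R` | spike-in test, band, pre-M/malignant calls, rank-sum comparisons, abundances |
| `05_scoring.R` | stemness scores by label; subtype calls and their abundance |

Each script regenerates the data deterministically from its seed, so no
large intermediates are stored.

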