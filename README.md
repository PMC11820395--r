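# sebumetrics

Sebum — the lipid film on the skin — can be sampled painlessly by
"groomed" latent fingerprints: a fingertip rubbed over a sebum-rich body
region (forehead, cheek, neck) and pressed onto foil. Flow-injection
ESI-MS of such samples is a promising, noninvasive source of lipidomic
data for biomarker studies, but only if the measurements are reproducible
and the nuisance variables (donor sex, grooming region, MS batch) are
understood. `sebumetrics` implements that assessment as a tested R
workflow:

* **Spectrum binning** — reads centroided MS1 text files (and mzML),
  sums peak intensities over the 0.8–1.0 min retention window into
  half-open 0.01 Da m/z bins spanning 250–1300 m/z, and assembles the
  105,000-bin × samples feature matrix.
* **Normalization chain** — sparse-bin filter (bin kept iff nonzero in
  ≥ 1% of samples), total-ion-current normalization, log2(v + 1e-10),
  per-feature batch correction (intercept + sum-to-zero batch least
  squares via limma), top-median feature selection.
* **Reproducibility** — per-bin percent relative standard deviation
  (100·sd/mean) across technical replicates within each MS batch
  (intrabatch) and across each sample's repeat injections (interbatch),
  summarized by the median per grooming region.
* **Donor-aware classification** — gradient-boosted trees (fixed,
  non-optimized hyperparameters; 50 rounds) under leave-one-out CV that
  excludes the test sample's donor from training; accuracy, ROC and
  trapezoidal AUC; PCA score plots with 95% normal-probability
  concentration ellipses.
* **Synthetic cohort generator** — emits MS1 files + metadata with the
  study's statistical structure (per-donor lipid baselines, a neck-region
  intensity shift, an optional — default null — sex effect,
  feature-specific batch drift, per-sample lipid-load variation, 3%
  technical CV), so the whole pipeline is testable without instrument
  data.

## Worked example

Simulate a replicate reproducibility study (6 technical replicates × 5
injection batches × 3 regions), bin it, run the normalization chain, and
measure reproducibility:

```r
library(sebumetrics)

cfg <- cohort_config(rng_seed = 1)          # 3% technical CV, 4% batch drift
sim <- generate_replicate_study(cfg, tempfile("replicates"))
raw <- build_feature_matrix(sim$files, sim$metadata)
chain <- normalize_matrix(raw, assign_batches(sim$metadata, "explicit"))
intrabatch_rsd(chain, sim$metadata, "forehead")
#> <rsd_summary> intrabatch, region forehead (tic scale): median %RSD = 2.71% over 250 (bin, group) values (0 non-finite excluded)
interbatch_rsd(chain, sim$metadata, "forehead")
#> <rsd_summary> interbatch, region forehead (tic scale): median %RSD = 4.63% over 300 (bin, group) values (0 non-finite excluded)
```

Within a batch the replicates differ only by the injected 3% technical
noise (the median sits slightly below 3% because the n = 6 sample SD is
median-biased low); across batches the feature-specific drift adds in
quadrature, pushing the median toward 5%.

Classify grooming regions under donor-exclusion LOOCV on a 30-donor
cohort (180 samples; neck profiles carry a +1 log2 shift on 20% of
peaks, cheek and forehead are identical):

```r
sim <- generate_cohort(cfg, tempfile("cohort"), order_by = "sex")
chain <- normalize_matrix(build_feature_matrix(sim$files, sim$metadata),
                          assign_batches(sim$metadata, "explicit"))
meta <- sim$metadata; m <- chain$top_selected
sel <- meta$region %in% c("neck", "forehead")
sub <- feature_matrix(m$values[, sel], m$bin_edges, m$sample_ids[sel],
                      "top_selected")
run_cv(sub, meta$region[sel], meta[sel, ], positive = "neck", seed = 1)
#> <cv_result> 120 samples, positive class 'neck': accuracy 97.5%, AUC 0.996
```

The same cohort with the (null) sex labels stays at chance — accuracy
50.0%, AUC 0.46 — which is the point: donor-exclusion CV prevents donor
identity from masquerading as a sex effect.

The numbered scripts under `analysis/` run these analyses end to end
(`01_simulate.R` … `06_pca.R`), writing summary tables to `results/` and
bulky intermediates to `scratch/`; `run_pipeline()` offers the same via a
single YAML config with a provenance manifest.

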