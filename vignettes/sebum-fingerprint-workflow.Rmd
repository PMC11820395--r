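---
title: "Methods: groomed-fingerprint sebum lipidomics, from MS1 spectra to reproducibility and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groomed-fingerprint sebum lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebumetrics)
```

## The measurement and the data model

Sebum — the lipid film secreted across the skin surface — can be sampled
noninvasively by "grooming": rubbing a fingertip over a sebum-rich region
(forehead, cheek, or back of the neck) and depositing a latent fingerprint.
Flow-injection ESI mass spectrometry of such samples yields a handful of
MS1 scans per injection over a short elution plug. Because there is no
chromatographic separation to align, the whole analysis runs on binned
spectra: every centroid peak with retention time inside a fixed window
(0.8–1.0 min, closed interval) is assigned to a half-open m/z bin
$[\ell, \ell + 0.01)$ Da over the instrument scan range 250–1300 m/z, and
intensities are summed per bin. That produces a 105,000-bin × samples
feature matrix; each bin is one "feature", with no attempt at lipid
identification.

Bin assignment uses `floor((mz - 250)/0.01)` computed in double precision
with a 1 nDa guard against representation error at bin boundaries; a peak
sitting exactly on a boundary belongs to the bin whose lower edge it is.
Peaks at exactly 1300.00 fall outside the last half-open bin and are
dropped (counted, not silently lost). Both endpoint conventions — the
closed RT interval and the half-open bins — are package decisions; the
binning itself is checked in the tests against a brute-force loop over
every (scan, peak) pair, and total intensity is conserved to 1e-6
relative.

## The processing chain

The chain runs in a fixed order, enforced by a stage tag on the matrix:

1. **Sparse-bin filter.** A bin survives iff the fraction of samples with
   a nonzero value is **at least** `min_nonzero_fraction` (default 0.01;
   the comparison is inclusive, so with 200 samples a bin nonzero in
   exactly 2 survives).
2. **TIC normalization.** Each column is divided by its total, making
   values fractional ion counts. This absorbs per-sample differences in
   total lipid load (people deposit different amounts of sebum), and with
   it any purely scalar per-injection scale factor.
3. **Shifted log2.** $v \mapsto \log_2(v + \varepsilon)$ with
   $\varepsilon = 10^{-10}$; zeros map to $-10\log_2 10 \approx -33.22$.
4. **Batch correction.** Per feature, an intercept-plus-batch linear model
   with sum-to-zero contrasts is fitted and the batch terms subtracted
   (`limma::removeBatchEffect`, the standard tool for this step; the
   package's tests verify it against an independent per-feature
   least-squares oracle, including unbalanced designs, and check that the
   per-feature intercept is preserved to 1e-8). No covariates are
   preserved in the design — the correction sees batch labels only, so
   batches must not be confounded with the contrast of interest (see
   "Injection layouts" below).
5. **Top-median selection.** Bins are ranked by per-bin median and the top
   `n_keep` retained, ties at the cutoff broken toward the lower m/z
   edge, row order preserved, values untouched. `n_keep` defaults to 10%
   of the bins surviving the sparse filter, and can be pinned to an exact
   count (e.g. 3000 or 4000) when matching an externally processed
   matrix.

## The synthetic cohort generator

The generator exists so that every stage — file parsing included — is
testable against known ground truth. It emits real MS1 text files (and
mzML via `mzR`), one per sample, each with 3 scans inside the retention
window and 2 decoy scans outside it so the RT filter is always exercised.
A sample's peak intensities are

$$ I_{sj} = B_j \cdot 2^{d_{(s)j} + r_j[\text{region}] + x_j[\text{sex}]}
  \cdot m_{b(s)} \cdot g_{b(s)j} \cdot t_s \cdot (1 + \epsilon_{sj}) $$

with $B_j$ log-normal baselines over ~500 peaks in [250, 1300) Da,
per-donor per-peak offsets $d$ (log2 SD 0.3), a region shift $r$ (+1 log2
unit on 20% of peaks in neck samples; cheek and forehead identical), an
optional sex shift $x$ (zero by default — the reference scenario is a null
sex effect), scalar batch multipliers $m_b$ (default 1), feature-specific
batch drift $g_{bj}$ (CV 0.04), a per-sample total-load factor $t_s$
(log SD 0.25), and technical noise $\epsilon$ (CV 0.03, truncated so
intensities stay nonnegative). Everything is a deterministic function of
the configuration and seed, down to the file bytes.

Three modeling decisions deserve explanation:

* **Noise is drawn once per (sample, peak)** and distributed over the
  in-window scans by fixed weights, rather than independently per scan.
  Independent per-scan draws would shrink the CV of the binned sum by
  $\sqrt{3}$, so a nominal 3% technical CV would register as ~1.7% — the
  parameter would no longer mean what it says. With the chosen model the
  intrabatch median %RSD concentrates near 3% (slightly below, because
  the sample SD at $n = 6$ is median-biased low by the factor
  $\sqrt{\chi^2_{5,0.5}/5} \approx 0.93$).
* **Batch effects need a feature-specific component.** A scalar per-batch
  multiplier is algebraically indistinguishable from total-load variation
  and cancels exactly under TIC normalization; a per-feature-constant
  batch effect is in turn removed exactly by the per-feature batch
  correction. Real batch-to-batch irreproducibility is neither, which is
  why studies observe interbatch %RSD above intrabatch even after
  correction. The generator therefore draws multiplicative drift per
  (batch, peak) with CV 0.04; combined with 3% technical noise this puts
  interbatch %RSD near $\sqrt{0.03^2 + 0.04^2} = 5\%$, the regime such
  fingerprint studies report. The drift CV and the other unpublished
  variance magnitudes (donor SD, load SD) are plausible choices fixed
  once, not fitted values.
* **Peaks are single centroids** — no isotope envelopes, adducts, charge
  states, or resolution effects — because the pipeline only ever consumes
  binned sums. Consequently, passing tests say nothing about centroiding
  quality or mass accuracy on real data; they validate the statistics
  downstream of peak picking.

## Reproducibility metrics

The replicate design is 6 technical replicate fingerprints per region,
with the randomized series re-injected 5 times (each series one MS
batch). Per bin, the percent relative standard deviation
$100 \cdot s/\bar{x}$ (sample SD, $n-1$) is computed across the 6
replicates within each batch (intrabatch, 5 groups) or across the 5
repeat injections of each replicate (interbatch, 6 groups), and all
(bin, group) values are pooled into one median per region and mode.
Zero-mean groups yield non-finite %RSD; they are excluded from the median
and counted.

%RSD is computed by default on **TIC-normalized linear intensities of the
selected bins, without batch correction**. This is a deliberate choice:
in the simulation the injected batch effects are per-feature constants,
exactly the structure the correction removes, so measuring after
correction would collapse interbatch to intrabatch by construction and
the metric would no longer measure batch-to-batch reproducibility at all.
Computing %RSD on log-scale values is not meaningful as an intensity CV,
so the log/correction stages are undone or skipped for this readout.
Post-correction linear scale (`scale = "corrected"`) and raw scale
(`scale = "raw"`) remain available for sensitivity analysis; the raw
scale is also where the closed-form identity lives (with pure scalar
batch multipliers and no noise, every bin's interbatch %RSD equals the
%RSD of the multiplier set).

## Donor-exclusion LOOCV and its interaction with batch correction

Classification (sex, or one pairwise region contrast) uses
gradient-boosted trees with fixed, deliberately un-tuned hyperparameters
(binary logistic gbtree; eta 0.3, gamma 0, max_depth 6, min_child_weight
1, subsample 1, colsample_bytree 1, 50 rounds) under leave-one-out
cross-validation in which **all samples from the test sample's donor are
excluded from training**. Since every split for one donor shares the same
training set, the implementation fits one model per donor. Fits are
single-threaded with an explicit seed; with subsample and colsample at 1
the procedure is deterministic. Accuracy thresholds the out-of-fold
probability at 0.5 (exact ties count as positive — a documented, if
arbitrary, rule); ROC/AUC pool all out-of-fold probabilities, with the
curve built by descending-score thresholding (ties grouped) and AUC by
the trapezoidal rule, which the tests pin to the pair-counting statistic
to 1e-12.

**Injection layouts matter.** The cohort simulator lays samples out in
injection order grouped by one variable and randomized within groups,
then batches are consecutive 30-sample blocks. For the sex analysis the
cohort is injected in region order (sex randomized within blocks); for
the region analyses, in sex order (region randomized). If instead batches
align with the contrast of interest, the covariate-free batch correction
subtracts the class difference itself — and under donor-exclusion CV it
does so using the held-out donor's samples, producing systematically
*inverted* out-of-fold predictions (AUC far below 0.5). The package keeps
the correction covariate-free to match the upstream processing decision,
and manages the risk the way the study design does: by randomizing the
variable under test within injection blocks.

## PCA and concentration ellipses

PCA mean-centers features without unit-variance scaling (inputs are
already log-scale, batch-corrected, and restricted to high-median bins; a
`scale.` switch exists for sensitivity checks). Components are oriented
so each one's largest-magnitude loading is positive, making score plots
reproducible across runs. Group concentration ellipses are
normal-probability ellipses at level 0.95: axes from the eigenvectors of
the group's 2×2 score covariance, semi-axes
$\sqrt{\lambda_i \, \chi^2_{2,0.95}}$ (an isotropic unit-variance group
gives a circle of radius ≈ 2.448). Degenerate covariances floor the axes
at zero with a warning.

## Problem sizes and numerical choices

The analysis scripts and the acceptance script run the full design the
generator defaults encode: 30 donors × 3 regions × 2 fingerprints (180
samples, batches of 30) for the variability analyses and 6 × 5 × 3 = 90
spectra for the reproducibility study, with 500 lipid peaks per spectrum.
These sizes keep a complete end-to-end run (three acquisitions, binning,
normalization, four LOOCV comparisons) around a minute on one CPU. With
500 peaks, roughly 500 bins are occupied, so the "top 10%" rule keeps ~50
features; the real study's 3000/4000-bin counts arise from its much
denser spectra and are reachable by pinning `n_keep` when processing
external matrices. Other numerical conventions: TIC columns sum to 1
within 1e-9; batch correction is checked to 1e-8 against its closed form;
the sparse raw matrix is stored as `Matrix::sparseMatrix` (contracts are
value-wise and storage-independent); single-batch correction is an
identity with a warning rather than an error.

## Known limitations

* The generator does not emulate chromatographic drift, isotope
  structure, adducts, detector saturation, or m/z calibration error; all
  conclusions from synthetic data concern the post-binning statistics.
* Replicate fingerprints are modeled as pure technical replicates (no
  replicate-level biological variation), so intrabatch %RSD reflects the
  technical CV alone.
* Externally deposited study-scale matrices can be ingested via
  `read_raw_matrix()` (TSV/CSV; first column = bin edge), skipping
  binning; XLSX is not read directly.
* Booster behavior across library versions is outside the package's
  control; the determinism contract covers repeated runs within one
  environment.
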