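# Small configurations and hand-built matrices shared across tests.

# A cohort small enough for fast round-trips but with every design axis.
small_cohort_config <- function(rng_seed = 11, ...) {
  cohort_config(n_donors = 4, samples_per_donor_per_region = 1,
                n_lipid_peaks = 40, batch_size = 6, rng_seed = rng_seed, ...)
}

# All stochastic components switched off (individually re-enable via args).
noise_free_config <- function(rng_seed = 11, tic_sd = 0, ...) {
  small_cohort_config(rng_seed = rng_seed, technical_cv = 0, donor_sd = 0,
                      tic_sd = tic_sd, batch_peak_cv = 0,
                      region_effect_log2fc = 0, sex_effect_log2fc = 0, ...)
}

# Build a sebum_matrix at an arbitrary stage directly (unit-test entry).
toy_matrix <- function(values, stage, edges = NULL, ids = NULL) {
  if (is.null(edges)) edges <- 250 + 0.01 * (seq_len(nrow(values)) - 1)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(values)))
  feature_matrix(values, edges, ids, stage = stage)
}

# Independent per-feature batch-correction oracle: least squares with
# sum-to-zero batch contrasts, subtracting only the batch terms.
batch_correct_oracle <- function(values, batch) {
  fb <- factor(batch)
  out <- values
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    fit <- stats::lm(y ~ fb, contrasts = list(fb = "contr.sum"))
    batch_part <- stats::model.matrix(fit)[, -1, drop = FALSE] %*%
      stats::coef(fit)[-1]
    out[i, ] <- y - as.numeric(batch_part)
  }
  out
}

# Brute-force AUC: pair counting, P(pos > neg) + 0.5 P(equal).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force binning: loop over every (scan, peak) pair.
bin_brute_force <- function(spectra, bin_def, rt_window) {
  out <- numeric(bin_def$n_bins)
  for (sp in spectra) {
    if (sp$rt < rt_window[1] || sp$rt > rt_window[2]) next
    for (k in seq_along(sp$mz)) {
      b <- floor((sp$mz[k] - bin_def$mz_min + 1e-9) / bin_def$width) + 1
      if (b >= 1 && b <= bin_def$n_bins) out[b] <- out[b] + sp$intensity[k]
    }
  }
  out
}

# Random centroid spectra for oracle comparisons.
random_spectra <- function(n_scans, peaks_per_scan, rt = NULL,
                           mz_range = c(250, 1300)) {
  lapply(seq_len(n_scans), function(s) {
    mz <- sort(stats::runif(peaks_per_scan, mz_range[1] - 10, mz_range[2] + 10))
    list(rt = if (is.null(rt)) stats::runif(1, 0.5, 1.3) else rt[s],
         mz = mz, intensity = stats::rexp(peaks_per_scan, 1 / 100))
  })
}
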