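#' Configuration for a synthetic fingerprint cohort
#'
#' Describes the statistical structure of a simulated groomed-fingerprint
#' study: per-donor baseline lipid profiles over 250-1300 m/z, a
#' region-specific intensity shift (neck distinct from cheek/forehead by
#' default), an optional sex effect (null by default), per-batch effects,
#' per-sample total-lipid-load variation, and multiplicative technical
#' noise.
#'
#' All effect sizes are log2 fold-changes applied before exponentiation.
#' Batch effects have two components: a scalar per-batch multiplier
#' (`batch_multipliers`, default all 1) applied to every peak, and
#' feature-specific batch drift (`batch_peak_cv`) drawn per (batch, peak).
#' The scalar component is indistinguishable from total-load variation and
#' is removed by TIC normalization; the feature-specific drift is what
#' batch-to-batch reproducibility actually measures.
#'
#' @param n_donors number of donors (>= 2).
#' @param samples_per_donor_per_region fingerprints per donor per region.
#' @param regions ordered set of grooming regions, a subset of
#'   `c("forehead", "cheek", "neck")`.
#' @param n_lipid_peaks number of lipid centroids, m/z drawn in \[250, 1300) Da.
#' @param region_effect_region region whose profile is shifted.
#' @param region_effect_fraction fraction of peaks carrying the region shift.
#' @param region_effect_log2fc log2 fold-change of the region shift.
#' @param sex_effect_log2fc log2 fold-change of the (male) sex effect;
#'   0 disables it (the reference scenario).
#' @param sex_effect_fraction fraction of peaks carrying the sex effect.
#' @param donor_sd between-donor log2 SD of per-peak baselines.
#' @param batch_size consecutive samples per MS batch when generating a
#'   multi-donor cohort.
#' @param batch_multipliers scalar per-batch scale factors; `NULL` = all 1.
#' @param batch_peak_cv fractional SD of per-(batch, peak) drift.
#' @param tic_sd SD (log scale) of the per-sample total-load factor.
#' @param technical_cv fractional SD of per-(sample, peak) multiplicative
#'   noise, truncated at zero.
#' @param scans_in_window,scans_out_window scans per sample inside/outside
#'   the 0.8-1.0 min retention window.
#' @param rng_seed integer seed; the whole cohort (including file bytes) is
#'   a deterministic function of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_donors = 30,
                          samples_per_donor_per_region = 2,
                          regions = c("forehead", "cheek", "neck"),
                          n_lipid_peaks = 500,
                          region_effect_region = "neck",
                          region_effect_fraction = 0.2,
                          region_effect_log2fc = 1.0,
                          sex_effect_log2fc = 0,
                          sex_effect_fraction = 0.2,
                          donor_sd = 0.3,
                          batch_size = 30,
                          batch_multipliers = NULL,
                          batch_peak_cv = 0.04,
                          tic_sd = 0.25,
                          technical_cv = 0.03,
                          scans_in_window = 3,
                          scans_out_window = 2,
                          rng_seed = 1) {
  cfg <- list(n_donors = n_donors,
              samples_per_donor_per_region = samples_per_donor_per_region,
              regions = regions, n_lipid_peaks = n_lipid_peaks,
              region_effect_region = region_effect_region,
              region_effect_fraction = region_effect_fraction,
              region_effect_log2fc = region_effect_log2fc,
              sex_effect_log2fc = sex_effect_log2fc,
              sex_effect_fraction = sex_effect_fraction,
              donor_sd = donor_sd, batch_size = batch_size,
              batch_multipliers = batch_multipliers,
              batch_peak_cv = batch_peak_cv, tic_sd = tic_sd,
              technical_cv = technical_cv,
              scans_in_window = scans_in_window,
              scans_out_window = scans_out_window,
              rng_seed = as.integer(rng_seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

region_vocabulary <- c("forehead", "cheek", "neck")

validate_cohort_config <- function(cfg) {
  if (!length(cfg$regions) || anyDuplicated(cfg$regions) ||
      !all(cfg$regions %in% region_vocabulary)) {
    stop("regions must be a non-empty unique subset of {",
         paste(region_vocabulary, collapse = ", "), "}")
  }
  counts <- c(cfg$n_donors, cfg$samples_per_donor_per_region,
              cfg$n_lipid_peaks, cfg$scans_in_window, cfg$scans_out_window)
  if (any(counts <= 0)) stop("counts must be positive")
  if (cfg$n_donors < 2) stop("n_donors must be >= 2")
  if (cfg$technical_cv < 0 || cfg$batch_peak_cv < 0 || cfg$tic_sd < 0 ||
      cfg$donor_sd < 0) {
    stop("noise parameters must be nonnegative")
  }
  for (f in c("region_effect_fraction", "sex_effect_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  invisible(cfg)
}

# Draw peak m/z values in [250, 1300), strictly increasing and unique at
# the 5-decimal precision of the MS1 text format.
draw_peak_mz <- function(n) {
  mz <- sort(round(stats::runif(n, 250, 1300 - 1e-4), 5))
  while (anyDuplicated(mz)) {
    dup <- duplicated(mz)
    mz[dup] <- round(stats::runif(sum(dup), 250, 1300 - 1e-4), 5)
    mz <- sort(mz)
  }
  mz
}

# Truncated multiplicative noise factors: max(0, 1 + N(0, cv)).
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  pmax(0, 1 + stats::rnorm(n, 0, cv))
}

# Core simulator shared by generate_cohort and generate_replicate_study.
# meta must carry donor_idx, region, sex, batch; returns intensity matrix
# (samples x peaks) plus the realized truth components.
simulate_intensities <- function(cfg, meta, n_batches) {
  np <- cfg$n_lipid_peaks
  ns <- nrow(meta)
  peak_mz <- draw_peak_mz(np)
  baseline <- stats::rlnorm(np, meanlog = log(1e6), sdlog = 1.5)

  region_peaks <- sort(sample.int(np, round(cfg$region_effect_fraction * np)))
  region_shift <- numeric(np)
  region_shift[region_peaks] <- cfg$region_effect_log2fc
  sex_peaks <- sort(sample.int(np, round(cfg$sex_effect_fraction * np)))
  sex_shift <- numeric(np)
  sex_shift[sex_peaks] <- cfg$sex_effect_log2fc

  donor_offsets <- matrix(stats::rnorm(cfg$n_donors * np, 0, cfg$donor_sd),
                          nrow = cfg$n_donors)
  batch_mult <- cfg$batch_multipliers
  if (is.null(batch_mult)) batch_mult <- rep(1, n_batches)
  if (length(batch_mult) != n_batches) {
    stop("need ", n_batches, " batch multipliers, got ", length(batch_mult))
  }
  batch_peak <- matrix(noise_factors(n_batches * np, cfg$batch_peak_cv),
                       nrow = n_batches)
  tic_factor <- exp(stats::rnorm(ns, 0, cfg$tic_sd))

  log2fc <- donor_offsets[meta$donor_idx, , drop = FALSE] +
    outer(meta$region == cfg$region_effect_region, region_shift) +
    outer(meta$sex == "M", sex_shift)
  noise <- matrix(noise_factors(ns * np, cfg$technical_cv), nrow = ns)
  intensities <- matrix(baseline, ns, np, byrow = TRUE) * 2^log2fc *
    batch_mult[meta$batch] * batch_peak[meta$batch, , drop = FALSE] *
    tic_factor * noise

  list(intensities = intensities,
       truth = list(peak_mz = peak_mz, baseline = baseline,
                    sample_intensities = intensities,
                    region_peaks = region_peaks,
                    region_effect_log2fc = cfg$region_effect_log2fc,
                    sex_peaks = sex_peaks,
                    sex_effect_log2fc = cfg$sex_effect_log2fc,
                    donor_offsets = donor_offsets,
                    batch_multipliers = batch_mult,
                    batch_peak_multipliers = batch_peak,
                    tic_factors = tic_factor,
                    technical_cv = cfg$technical_cv))
}

# Write one sample's spectra: the peak total intensity is split over the
# in-window scans by fixed weights (so binned sums conserve the generated
# totals); out-of-window scans carry decoy copies that the RT filter must
# exclude.
sample_spectra <- function(cfg, peak_mz, intensity) {
  n_in <- cfg$scans_in_window
  n_out <- cfg$scans_out_window
  rt_in <- seq(0.82, 0.98, length.out = n_in)
  rt_out <- c(seq(0.30, 0.60, length.out = ceiling(n_out / 2)),
              seq(1.40, 1.70, length.out = floor(n_out / 2)))[seq_len(n_out)]
  w <- rev(seq_len(n_in))
  w <- w / sum(w)
  spectra <- lapply(seq_len(n_in), function(k)
    list(rt = rt_in[k], mz = peak_mz, intensity = intensity * w[k]))
  c(spectra, lapply(rt_out, function(rt)
    list(rt = rt, mz = peak_mz, intensity = intensity * 0.05)))
}

write_sample_files <- function(cfg, meta, peak_mz, intensities, out_dir,
                               format) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "mzml") "mzML" else "ms1"
  files <- file.path(out_dir, paste0(meta$sample_id, ".", ext))
  names(files) <- meta$sample_id
  for (s in seq_len(nrow(meta))) {
    spectra <- sample_spectra(cfg, peak_mz, intensities[s, ])
    if (format == "mzml") write_mzml(spectra, files[s])
    else write_ms1(spectra, files[s])
  }
  files
}

write_metadata <- function(meta, out_dir) {
  path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Generate a synthetic multi-donor fingerprint cohort
#'
#' Emits one spectrum file per sample plus a metadata table, with the
#' design of a study in which every donor grooms every region: `n_donors`
#' donors x `length(regions)` regions x `samples_per_donor_per_region`
#' fingerprints (180 samples at the defaults). Donor sex is assigned half
#' male / half female. Samples are laid out in injection order grouped by
#' `order_by` (the variable held contiguous, emulating acquisition order)
#' and randomized within groups with respect to the other variables;
#' consecutive blocks of `batch_size` samples form the MS batches.
#'
#' @param config a [cohort_config()].
#' @param out_dir directory for the MS1/mzML files and `metadata.tsv`.
#' @param order_by variable that defines the injection blocks: `"region"`
#'   (use for sex comparisons, so batch is not confounded with sex) or
#'   `"sex"` (use for region comparisons).
#' @param format `"ms1"` (text) or `"mzml"`.
#' @return A list with `files` (named vector of per-sample paths),
#'   `metadata` (data.frame: sample_id, donor_id, sex, region, replicate,
#'   injection_order, batch), and `truth` (the realized simulation
#'   parameters).
#' @export
generate_cohort <- function(config, out_dir,
                            order_by = c("region", "sex"),
                            format = c("ms1", "mzml")) {
  validate_cohort_config(config)
  order_by <- match.arg(order_by)
  format <- match.arg(format)
  set.seed(config$rng_seed)

  donors <- sprintf("D%02d", seq_len(config$n_donors))
  sex <- rep(c("M", "F"), length.out = config$n_donors)
  grid <- expand.grid(replicate = seq_len(config$samples_per_donor_per_region),
                      region = config$regions, donor_idx = seq_len(config$n_donors),
                      stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("%s_%s_%d", donors[grid$donor_idx],
                                         grid$region, grid$replicate),
                     donor_id = donors[grid$donor_idx],
                     donor_idx = grid$donor_idx,
                     sex = sex[grid$donor_idx],
                     region = grid$region,
                     replicate = grid$replicate,
                     stringsAsFactors = FALSE)

  key <- if (order_by == "region") {
    factor(meta$region, levels = config$regions)
  } else {
    factor(meta$sex, levels = c("M", "F"))
  }
  ord <- order(as.integer(key), sample.int(nrow(meta)))
  meta <- meta[ord, ]
  meta$injection_order <- seq_len(nrow(meta))
  ns <- nrow(meta)
  if (ns %% config$batch_size == 0) {
    meta$batch <- ceiling(meta$injection_order / config$batch_size)
  } else {
    meta$batch <- 1L
  }
  sim <- simulate_intensities(config, meta, n_batches = max(meta$batch))
  files <- write_sample_files(config, meta, sim$truth$peak_mz,
                              sim$intensities, out_dir, format)
  meta_out <- meta[, c("sample_id", "donor_id", "sex", "region", "replicate",
                       "injection_order", "batch")]
  rownames(meta_out) <- NULL
  write_metadata(meta_out, out_dir)
  list(files = files, metadata = meta_out,
       truth = c(sim$truth, list(config = config, order_by = order_by)))
}

#' Generate a synthetic replicate reproducibility study
#'
#' Emulates a design in which one donor provides `n_replicates` technical
#' replicate fingerprints per region, and the whole randomized series is
#' re-injected `n_batches` times, each injection series forming one MS
#' batch (6 replicates x 5 batches x 3 regions = 90 spectra at the
#' defaults). Feature-specific batch drift (`batch_peak_cv`) and scalar
#' batch multipliers are applied per injection series.
#'
#' @param config a [cohort_config()]; `n_donors` is ignored (single donor).
#' @param out_dir output directory.
#' @param n_replicates technical replicates per region.
#' @param n_batches repeat-injection series.
#' @param format `"ms1"` or `"mzml"`.
#' @return As [generate_cohort()]; metadata carries `replicate` and `batch`.
#' @export
generate_replicate_study <- function(config, out_dir, n_replicates = 6,
                                     n_batches = 5, format = c("ms1", "mzml")) {
  validate_cohort_config(config)
  format <- match.arg(format)
  set.seed(config$rng_seed)

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      region = config$regions,
                      batch = seq_len(n_batches),
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("R%d_%s_b%d", grid$replicate, grid$region, grid$batch),
    donor_id = "D01", donor_idx = 1L, sex = "F",
    region = grid$region, replicate = grid$replicate, batch = grid$batch,
    stringsAsFactors = FALSE)
  # randomize sample order within each injection series
  ord <- order(meta$batch, sample.int(nrow(meta)))
  meta <- meta[ord, ]
  meta$injection_order <- seq_len(nrow(meta))

  cfg <- config
  cfg$n_donors <- 2L  # truth needs >= 2 donor rows; only donor 1 is sampled
  sim <- simulate_intensities(cfg, meta, n_batches = n_batches)
  files <- write_sample_files(config, meta, sim$truth$peak_mz,
                              sim$intensities, out_dir, format)
  meta_out <- meta[, c("sample_id", "donor_id", "sex", "region", "replicate",
                       "injection_order", "batch")]
  rownames(meta_out) <- NULL
  write_metadata(meta_out, out_dir)
  list(files = files, metadata = meta_out,
       truth = c(sim$truth, list(config = config)))
}
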