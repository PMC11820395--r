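#' Assign samples to MS batches
#'
#' @param metadata data.frame with `sample_id` and `injection_order` (and a
#'   `batch` column for `mode = "explicit"` when `batches` is not given).
#' @param mode `"consecutive_blocks"` treats each run of `block_size`
#'   consecutive injections as one batch; `"explicit"` passes a provided
#'   assignment through.
#' @param block_size samples per batch for block mode.
#' @param batches integer vector (aligned with `metadata` rows) for
#'   explicit mode; defaults to `metadata$batch`.
#' @return Integer vector of batch indices (contiguous from 1), named by
#'   sample id.
#' @export
assign_batches <- function(metadata, mode = c("consecutive_blocks", "explicit"),
                           block_size = 30, batches = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(metadata$injection_order) ||
      anyNA(metadata$injection_order)) {
    stop("injection_order must be present and unique")
  }
  if (mode == "consecutive_blocks") {
    n <- nrow(metadata)
    if (n %% block_size != 0) {
      stop(sprintf("block size %d does not divide %d samples", block_size, n))
    }
    b <- ceiling(rank(metadata$injection_order) / block_size)
  } else {
    if (is.null(batches)) batches <- metadata$batch
    if (is.null(batches) || length(batches) != nrow(metadata)) {
      stop("explicit mode needs one batch index per sample")
    }
    b <- as.integer(factor(batches, levels = sort(unique(batches))))
  }
  b <- as.integer(b)
  names(b) <- metadata$sample_id
  b
}

# Reorder a per-sample vector (named, or aligned with metadata) to match
# the matrix's column order.
align_to_samples <- function(x, m) {
  if (!is.null(names(x))) {
    if (!all(m$sample_ids %in% names(x))) {
      stop("assignment missing samples: ",
           paste(setdiff(m$sample_ids, names(x)), collapse = ", "))
    }
    x <- x[m$sample_ids]
  } else if (length(x) != length(m$sample_ids)) {
    stop("per-sample vector has wrong length")
  }
  x
}

#' Drop bins observed in too few samples
#'
#' Retains a bin iff the fraction of samples with a value > 0 is at least
#' `min_nonzero_fraction` (inclusive: "at least 1%" keeps a bin nonzero in
#' exactly 1% of samples).
#'
#' @param m `sebum_matrix` at stage `raw`.
#' @param min_nonzero_fraction minimum nonzero fraction, in (0, 1).
#' @return `sebum_matrix` at stage `sparse_filtered` (dense storage).
#' @export
filter_sparse_bins <- function(m, min_nonzero_fraction = 0.01) {
  assert_stage(m, "raw")
  if (min_nonzero_fraction <= 0 || min_nonzero_fraction >= 1) {
    stop("min_nonzero_fraction must lie in (0, 1)")
  }
  nz <- Matrix::rowSums(m$values > 0)
  keep <- nz / ncol(m$values) >= min_nonzero_fraction
  if (!any(keep)) {
    stop("no bins survive the sparsity filter; review min_nonzero_fraction")
  }
  feature_matrix(as.matrix(m$values[keep, , drop = FALSE]),
                 m$bin_edges[keep], m$sample_ids, stage = "sparse_filtered")
}

#' Total-ion-current normalization
#'
#' Divides every value by its sample's column sum, so each column holds
#' fractional ion counts summing to 1.
#'
#' @param m `sebum_matrix` at stage `sparse_filtered`.
#' @return `sebum_matrix` at stage `tic_normalized`.
#' @export
tic_normalize <- function(m) {
  assert_stage(m, "sparse_filtered")
  tic <- colSums(m$values)
  zero <- tic <= 0
  if (any(zero)) {
    stop("zero total intensity for sample(s): ",
         paste(m$sample_ids[zero], collapse = ", "))
  }
  feature_matrix(sweep(m$values, 2, tic, "/"), m$bin_edges, m$sample_ids,
                 stage = "tic_normalized")
}

#' Shifted log2 transform
#'
#' Maps every value v to log2(v + epsilon); the shift eliminates zeros
#' (log2(1e-10) = -10 log2 10, about -33.22).
#'
#' @param m `sebum_matrix` at stage `tic_normalized`.
#' @param epsilon positive shift added before the log.
#' @return `sebum_matrix` at stage `log2`.
#' @export
log_transform <- function(m, epsilon = 1e-10) {
  assert_stage(m, "tic_normalized")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (any(m$values < 0)) stop("negative values reached the log transform")
  out <- feature_matrix(log2(m$values + epsilon), m$bin_edges, m$sample_ids,
                        stage = "log2")
  attr(out, "epsilon") <- epsilon
  out
}

#' Per-feature batch-effect removal
#'
#' For every feature, fits intercept + batch by least squares with
#' sum-to-zero batch contrasts and subtracts the fitted batch terms
#' (limma's removeBatchEffect). The grand-mean structure (per-feature
#' least-squares intercept) is preserved; in balanced designs per-feature
#' batch means become equal.
#'
#' @param m `sebum_matrix` at stage `log2`.
#' @param batch batch assignment from [assign_batches()] (named integer
#'   vector) or any vector aligned with the matrix columns.
#' @return `sebum_matrix` at stage `batch_corrected`.
#' @export
remove_batch_effects <- function(m, batch) {
  assert_stage(m, "log2")
  batch <- align_to_samples(batch, m)
  fb <- factor(batch)
  if (any(table(fb) == 0)) stop("every batch must contain at least one sample")
  eps <- attr(m, "epsilon")
  if (nlevels(fb) < 2) {
    warning("single batch: batch correction is the identity")
    corrected <- m$values
  } else {
    corrected <- limma::removeBatchEffect(m$values, batch = fb)
    dimnames(corrected) <- NULL
  }
  out <- feature_matrix(corrected, m$bin_edges, m$sample_ids,
                        stage = "batch_corrected")
  attr(out, "epsilon") <- eps
  out
}

#' Keep the bins with the highest median values
#'
#' Ranks bins by their per-bin median across samples (descending) and
#' retains exactly `n_keep`, breaking ties at the cutoff by lower m/z edge
#' first. Row order among survivors is preserved; retained values are
#' unchanged.
#'
#' @param m `sebum_matrix` at stage `batch_corrected`.
#' @param n_keep number of bins to retain (positive, at most the bin count).
#' @return `sebum_matrix` at stage `top_selected`.
#' @export
select_top_median_bins <- function(m, n_keep) {
  assert_stage(m, "batch_corrected")
  if (n_keep <= 0) stop("n_keep must be positive")
  if (n_keep > nrow(m$values)) {
    stop("n_keep (", n_keep, ") exceeds bin count (", nrow(m$values), ")")
  }
  med <- apply(m$values, 1, stats::median)
  keep <- sort(order(-med, m$bin_edges)[seq_len(n_keep)])
  out <- feature_matrix(m$values[keep, , drop = FALSE], m$bin_edges[keep],
                        m$sample_ids, stage = "top_selected")
  attr(out, "epsilon") <- attr(m, "epsilon")
  out
}

#' Run the full normalization chain
#'
#' Applies, in order: sparse-bin filtering, TIC normalization, shifted log2
#' transform, per-feature batch correction, and top-median feature
#' selection. Returns every intermediate stage so downstream analyses can
#' read values on the scale they need (the reproducibility metrics read
#' TIC-normalized linear intensities of the selected bins by default).
#'
#' @param m `sebum_matrix` at stage `raw`.
#' @param batch batch assignment (see [remove_batch_effects()]).
#' @param min_nonzero_fraction sparse-filter threshold.
#' @param epsilon log-transform shift.
#' @param n_keep bins to retain; `NULL` keeps
#'   `round(keep_fraction * surviving bins)`.
#' @param keep_fraction fraction used when `n_keep` is `NULL` (the "top
#'   10%" rule).
#' @return A `sebum_chain` list with elements `raw`, `sparse_filtered`,
#'   `tic_normalized`, `log2`, `batch_corrected`, `top_selected`,
#'   `selected_edges`, and `config`.
#' @export
normalize_matrix <- function(m, batch, min_nonzero_fraction = 0.01,
                             epsilon = 1e-10, n_keep = NULL,
                             keep_fraction = 0.10) {
  filtered <- filter_sparse_bins(m, min_nonzero_fraction)
  tic <- tic_normalize(filtered)
  logm <- log_transform(tic, epsilon)
  corrected <- remove_batch_effects(logm, batch)
  if (is.null(n_keep)) n_keep <- max(1L, round(keep_fraction * nrow(corrected$values)))
  selected <- select_top_median_bins(corrected, n_keep)
  structure(list(raw = m, sparse_filtered = filtered, tic_normalized = tic,
                 log2 = logm, batch_corrected = corrected,
                 top_selected = selected,
                 selected_edges = selected$bin_edges,
                 config = list(min_nonzero_fraction = min_nonzero_fraction,
                               epsilon = epsilon, n_keep = n_keep,
                               batch = align_to_samples(batch, m))),
            class = "sebum_chain")
}

#' @export
#' @method print sebum_chain
print.sebum_chain <- function(x, ...) {
  cat(sprintf("<sebum_chain> %d raw bins -> %d filtered -> %d selected; %d samples, %d batches\n",
              nrow(x$raw$values), nrow(x$sparse_filtered$values),
              nrow(x$top_selected$values), length(x$raw$sample_ids),
              length(unique(x$config$batch))))
  invisible(x)
}
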