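#' Percent relative standard deviation
#'
#' 100 x sample standard deviation (n-1 denominator) / mean. Scale
#' invariant: multiplying all values by k > 0 leaves it unchanged.
#'
#' @param values numeric vector of at least 2 replicate measurements.
#' @return %RSD; `NaN` when the mean is zero (callers exclude and count
#'   such values).
#' @export
percent_rsd <- function(values) {
  if (length(values) < 2) stop("percent_rsd needs at least 2 values")
  mu <- mean(values)
  if (mu == 0) return(NaN)
  100 * stats::sd(values) / mu
}

# Per-(bin, group) %RSD for a linear-intensity matrix (bins x samples).
rsd_by_group <- function(values, group) {
  groups <- sort(unique(group))
  out <- sapply(groups, function(g) {
    cols <- which(group == g)
    if (length(cols) < 2) {
      stop("group '", g, "' has fewer than 2 replicates")
    }
    apply(values[, cols, drop = FALSE], 1, percent_rsd)
  })
  out <- matrix(out, nrow = nrow(values),
                dimnames = list(NULL, as.character(groups)))
  out
}

# Pull the linear-intensity matrix for the selected bins out of a chain at
# the requested scale. "tic" (default): TIC-normalized fractions;
# "corrected": 2^v - epsilon back-transformed from the batch-corrected
# selection; "raw": raw binned intensities.
linear_values <- function(chain, scale = c("tic", "corrected", "raw")) {
  scale <- match.arg(scale)
  sel <- chain$selected_edges
  if (scale == "corrected") {
    eps <- chain$config$epsilon
    return(2^chain$top_selected$values - eps)
  }
  src <- if (scale == "tic") chain$tic_normalized else chain$raw
  idx <- match(sel, src$bin_edges)
  as.matrix(src$values[idx, , drop = FALSE])
}

rsd_summary <- function(mode, region, scale, values) {
  finite <- is.finite(values)
  structure(list(mode = mode, region = region, scale = scale,
                 values = values,
                 median_percent_rsd = stats::median(values[finite]),
                 n_nonfinite = sum(!finite)),
            class = "rsd_summary")
}

#' @export
#' @method print rsd_summary
print.rsd_summary <- function(x, ...) {
  cat(sprintf("<rsd_summary> %s, region %s (%s scale): median %%RSD = %.2f%% over %d (bin, group) values (%d non-finite excluded)\n",
              x$mode, x$region, x$scale, x$median_percent_rsd,
              sum(is.finite(x$values)), x$n_nonfinite))
  invisible(x)
}

# Shared front end: accept a sebum_chain (preferred) or a linear-scale
# sebum_matrix, subset one region's samples, and hand back (values, meta).
rsd_inputs <- function(x, metadata, region, scale) {
  if (inherits(x, "sebum_chain")) {
    values <- linear_values(x, scale)
    ids <- x$tic_normalized$sample_ids
  } else if (inherits(x, "sebum_matrix")) {
    values <- as.matrix(x$values)
    ids <- x$sample_ids
    scale <- paste0("as-is (stage ", x$stage, ")")
  } else stop("x must be a sebum_chain or sebum_matrix")
  need <- c("sample_id", "replicate", "batch", "region")
  if (!all(need %in% names(metadata))) {
    stop("metadata must contain ", paste(need, collapse = ", "))
  }
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata is missing matrix samples")
  sel <- meta$region == region
  if (!any(sel)) stop("no samples for region '", region, "'")
  list(values = values[, sel, drop = FALSE], meta = meta[sel, ], scale = scale)
}

#' Intrabatch reproducibility (%RSD across technical replicates)
#'
#' For one grooming region, computes the per-bin %RSD across the technical
#' replicates within each MS batch independently, then summarizes all
#' (bin, batch) values by their median.
#'
#' @param x a `sebum_chain` from [normalize_matrix()] (or a linear-scale
#'   `sebum_matrix` used as-is).
#' @param metadata data.frame with `sample_id`, `replicate`, `batch`,
#'   `region`.
#' @param region grooming region to evaluate.
#' @param scale intensity scale when `x` is a chain: `"tic"` (default,
#'   TIC-normalized linear), `"corrected"` (back-transformed
#'   batch-corrected), or `"raw"`.
#' @return An `rsd_summary`.
#' @export
intrabatch_rsd <- function(x, metadata, region,
                           scale = c("tic", "corrected", "raw")) {
  inp <- rsd_inputs(x, metadata, region, match.arg(scale))
  vals <- rsd_by_group(inp$values, inp$meta$batch)
  rsd_summary("intrabatch", region, inp$scale, vals)
}

#' Interbatch reproducibility (%RSD across repeat injections)
#'
#' For one grooming region, computes the per-bin %RSD across the repeat
#' injections of each replicate sample (one injection per batch), then
#' summarizes all (bin, replicate) values by their median.
#'
#' @inheritParams intrabatch_rsd
#' @return An `rsd_summary`.
#' @export
interbatch_rsd <- function(x, metadata, region,
                           scale = c("tic", "corrected", "raw")) {
  inp <- rsd_inputs(x, metadata, region, match.arg(scale))
  tab <- table(inp$meta$replicate, inp$meta$batch)
  if (any(tab != 1)) {
    gaps <- which(tab == 0, arr.ind = TRUE)
    stop("replicate/batch design incomplete; missing (replicate, batch): ",
         paste(sprintf("(%s, %s)", rownames(tab)[gaps[, 1]],
                       colnames(tab)[gaps[, 2]]), collapse = ", "))
  }
  vals <- rsd_by_group(inp$values, inp$meta$replicate)
  rsd_summary("interbatch", region, inp$scale, vals)
}
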