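#' Fixed-width m/z bin grid
#'
#' Defines the half-open bin grid \[lower, lower + width) spanning the
#' instrument scan range. With the defaults (250-1300 Da, 0.01 Da) the grid
#' has 105,000 bins.
#'
#' @param mz_min,mz_max scan range limits in Da.
#' @param width bin width in Da.
#' @return A `bin_definition` list with elements `mz_min`, `mz_max`,
#'   `width`, `n_bins`, `edges` (lower edges).
#' @export
bin_definition <- function(mz_min = 250, mz_max = 1300, width = 0.01) {
  if (mz_max <= mz_min || width <= 0) stop("invalid bin definition")
  n_bins <- as.integer(round((mz_max - mz_min) / width))
  structure(list(mz_min = mz_min, mz_max = mz_max, width = width,
                 n_bins = n_bins,
                 edges = mz_min + width * (seq_len(n_bins) - 1)),
            class = "bin_definition")
}

# Map m/z values to 1-based bin indices; NA outside [mz_min, mz_max).
# A 1e-9 Da guard absorbs representation error for peaks on a boundary.
bin_index <- function(mz, bin_def) {
  ix <- floor((mz - bin_def$mz_min + 1e-9) / bin_def$width) + 1
  ix[ix < 1 | ix > bin_def$n_bins] <- NA
  as.integer(ix)
}

#' Sum a sample's peak intensities into m/z bins
#'
#' Pools all scans whose retention time falls inside `rt_window` (closed
#' interval, minutes) and sums peak intensities per half-open m/z bin.
#' Peaks outside the bin grid are silently dropped (count reported via the
#' `n_out_of_range` attribute).
#'
#' @param spectra list of centroid spectra (see [read_ms1()]).
#' @param bin_def a [bin_definition()].
#' @param rt_window numeric length-2, retention-time window in minutes.
#' @return Numeric vector of length `bin_def$n_bins`.
#' @export
accumulate_sample <- function(spectra, bin_def = bin_definition(),
                              rt_window = c(0.8, 1.0)) {
  acc <- accumulate_pairs(spectra, bin_def, rt_window)
  out <- numeric(bin_def$n_bins)
  if (length(acc$idx)) out[acc$idx] <- acc$val
  attr(out, "n_out_of_range") <- acc$n_out
  out
}

# Shared accumulator: returns nonzero (bin index, summed value) pairs.
accumulate_pairs <- function(spectra, bin_def, rt_window) {
  keep <- vapply(spectra, function(sp)
    sp$rt >= rt_window[1] & sp$rt <= rt_window[2], TRUE)
  mz <- unlist(lapply(spectra[keep], `[[`, "mz"), use.names = FALSE)
  it <- unlist(lapply(spectra[keep], `[[`, "intensity"), use.names = FALSE)
  if (!length(mz)) return(list(idx = integer(), val = numeric(), n_out = 0L))
  ix <- bin_index(mz, bin_def)
  n_out <- sum(is.na(ix))
  ok <- !is.na(ix)
  if (!any(ok)) return(list(idx = integer(), val = numeric(), n_out = n_out))
  sums <- rowsum(it[ok], group = ix[ok])
  list(idx = as.integer(rownames(sums)), val = as.numeric(sums), n_out = n_out)
}

#' Build the raw bins-by-samples feature matrix
#'
#' Reads one spectrum file per sample (MS1 text or mzML, by extension),
#' bins each over the retention window, and assembles the sparse raw
#' matrix. Columns are ordered by the metadata's `injection_order`, so the
#' result is independent of the order in which files are supplied.
#'
#' @param files character vector of spectrum file paths, named by sample id
#'   (unnamed files are matched to metadata by file base name).
#' @param metadata data.frame with at least `sample_id` and
#'   `injection_order` columns.
#' @param bin_def a [bin_definition()].
#' @param rt_window retention window in minutes (closed interval).
#' @return A `sebum_matrix` at stage `raw` (sparse storage).
#' @export
build_feature_matrix <- function(files, metadata, bin_def = bin_definition(),
                                 rt_window = c(0.8, 1.0)) {
  ids <- names(files)
  if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(files))
  if (!all(c("sample_id", "injection_order") %in% names(metadata))) {
    stop("metadata must contain sample_id and injection_order")
  }
  missing_files <- setdiff(metadata$sample_id, ids)
  extra_files <- setdiff(ids, metadata$sample_id)
  if (length(missing_files) || length(extra_files)) {
    stop("files/metadata mismatch; missing files: [",
         paste(missing_files, collapse = ", "), "]; unmatched files: [",
         paste(extra_files, collapse = ", "), "]")
  }
  meta <- metadata[order(metadata$injection_order), ]
  files <- files[match(meta$sample_id, ids)]

  parts <- lapply(seq_along(files), function(j) {
    f <- files[[j]]
    spectra <- if (tolower(tools::file_ext(f)) == "mzml") {
      read_mzml(f)
    } else {
      read_ms1(f)
    }
    acc <- accumulate_pairs(spectra, bin_def, rt_window)
    list(i = acc$idx, j = rep.int(j, length(acc$idx)), x = acc$val)
  })
  values <- Matrix::sparseMatrix(
    i = unlist(lapply(parts, `[[`, "i")),
    j = unlist(lapply(parts, `[[`, "j")),
    x = unlist(lapply(parts, `[[`, "x")),
    dims = c(bin_def$n_bins, length(files))
  )
  feature_matrix(values, bin_def$edges, meta$sample_id, stage = "raw")
}
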