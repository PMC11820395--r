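#' Bins-by-samples feature matrix
#'
#' Container for the binned MS1 intensity table. Rows are fixed-width m/z
#' bins (identified by their lower edge in Da), columns are samples. The
#' `stage` tag records where the matrix sits in the processing chain and is
#' checked by every downstream operation, so steps can only be applied in
#' the documented order:
#' raw -> sparse_filtered -> tic_normalized -> log2 -> batch_corrected ->
#' top_selected.
#'
#' @param values numeric matrix or Matrix sparse matrix, bins x samples.
#' @param bin_edges numeric vector of bin lower edges (Da), one per row.
#' @param sample_ids character vector of sample identifiers, one per column.
#' @param stage processing stage tag.
#' @return An object of class `sebum_matrix`.
#' @export
feature_matrix <- function(values, bin_edges, sample_ids,
                           stage = c("raw", "sparse_filtered", "tic_normalized",
                                     "log2", "batch_corrected", "top_selected")) {
  stage <- match.arg(stage)
  if (nrow(values) != length(bin_edges)) {
    stop("nrow(values) must equal length(bin_edges)")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("ncol(values) must equal length(sample_ids)")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  structure(
    list(values = values, bin_edges = as.numeric(bin_edges),
         sample_ids = as.character(sample_ids), stage = stage),
    class = "sebum_matrix"
  )
}

matrix_stages <- c("raw", "sparse_filtered", "tic_normalized", "log2",
                   "batch_corrected", "top_selected")

# Stop unless `m` is at one of the allowed stages; names the violation.
assert_stage <- function(m, allowed) {
  if (!inherits(m, "sebum_matrix")) stop("expected a sebum_matrix")
  if (!m$stage %in% allowed) {
    stop(sprintf("matrix is at stage '%s'; this step requires stage %s",
                 m$stage, paste(sQuote(allowed), collapse = " or ")))
  }
  invisible(m)
}

#' @export
dim.sebum_matrix <- function(x) dim(x$values)

#' @export
#' @method print sebum_matrix
print.sebum_matrix <- function(x, ...) {
  cat(sprintf("<sebum_matrix> %d bins x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  m/z bin edges: %.2f .. %.2f Da\n",
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Extract the intensity table as a base matrix
#'
#' @param m a `sebum_matrix`.
#' @return A dense numeric matrix with bin edges as row names and sample ids
#'   as column names.
#' @export
as_dense <- function(m) {
  v <- as.matrix(m$values)
  rownames(v) <- sprintf("%.2f", m$bin_edges)
  colnames(v) <- m$sample_ids
  v
}

#' Write / read a feature matrix as TSV
#'
#' The TSV layout is one row per m/z bin: first column `mz_bin` holds the
#' bin lower edge printed to 2 decimals, remaining columns are samples. A
#' JSON sidecar (`<path>.json`) records the processing stage so the matrix
#' can be re-read without losing its position in the chain.
#'
#' @param m a `sebum_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  v <- as.matrix(m$values)
  df <- data.frame(mz_bin = sprintf("%.2f", m$bin_edges), v,
                   check.names = FALSE)
  colnames(df) <- c("mz_bin", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(stage = m$stage), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stage <- "raw"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) stage <- jsonlite::read_json(sidecar)$stage
  feature_matrix(as.matrix(df[, -1, drop = FALSE]),
                 bin_edges = as.numeric(df[[1]]),
                 sample_ids = colnames(df)[-1],
                 stage = stage)
}

#' Read a pre-built raw feature matrix (TSV/CSV)
#'
#' Entry point for externally supplied bins-by-samples matrices (for example
#' a study's deposited supplementary tables), bypassing spectrum binning.
#' The first column must hold the m/z bin identifier (numeric lower edge);
#' remaining columns are samples. XLSX is not supported; export to CSV first.
#'
#' @param path TSV or CSV file; format chosen by extension.
#' @return A `sebum_matrix` at stage `raw`.
#' @export
read_raw_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE),
    stop("unsupported matrix format '", ext, "' (use TSV or CSV)")
  )
  edges <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(edges)) stop("first column must hold numeric m/z bin edges")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("matrix body must be numeric")
  if (any(vals < 0)) stop("raw intensities must be nonnegative")
  feature_matrix(vals, edges, colnames(df)[-1], stage = "raw")
}
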