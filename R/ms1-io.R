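#' Read a plain-text MS1 spectrum file
#'
#' Parses the MS1 dialect written by raw-file converters: optional `H`
#' header lines, then one block per scan starting `S <num> <num>`, an
#' `I RTime <minutes>` line, and whitespace-separated `<mz> <intensity>`
#' peak lines.
#'
#' @param file path to an MS1 text file.
#' @return A list of centroid spectra, one per scan, each a list with
#'   elements `rt` (retention time, minutes), `mz` and `intensity`
#'   (equal-length numeric vectors, m/z ascending). An empty file yields an
#'   empty list.
#' @export
read_ms1 <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  first <- substr(lines, 1L, 1L)
  is_scan <- first == "S"
  if (!any(is_scan)) return(list())
  scan_id <- cumsum(is_scan)

  rt_mask <- grepl("^I[ \t]+RTime[ \t]", lines)
  rts <- rep(NA_real_, max(scan_id))
  if (any(rt_mask)) {
    parts <- strsplit(trimws(lines[rt_mask]), "[ \t]+")
    rts[scan_id[rt_mask]] <- vapply(parts, function(p) as.numeric(p[3]), 0)
  }
  scan_lines <- which(is_scan)
  missing_rt <- which(is.na(rts))
  if (length(missing_rt)) {
    stop(sprintf("scan starting at line %d has no 'I RTime' entry",
                 scan_lines[missing_rt[1]]))
  }

  peak_mask <- scan_id > 0 & grepl("^[0-9.+-]", lines)
  pk <- strsplit(trimws(lines[peak_mask]), "[ \t]+")
  mz <- vapply(pk, function(p) suppressWarnings(as.numeric(p[1])), 0)
  it <- vapply(pk, function(p) suppressWarnings(as.numeric(p[2])), 0)
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad)) {
    stop(sprintf("non-numeric peak entry at line %d",
                 which(peak_mask)[bad[1]]))
  }
  pk_scan <- scan_id[peak_mask]

  lapply(seq_len(max(scan_id)), function(s) {
    sel <- pk_scan == s
    spec <- list(rt = rts[s], mz = mz[sel], intensity = it[sel])
    if (is.unsorted(spec$mz, strictly = TRUE)) {
      stop(sprintf("scan %d: m/z values must be strictly increasing", s))
    }
    if (any(spec$intensity < 0)) {
      stop(sprintf("scan %d: negative intensity", s))
    }
    spec
  })
}

#' Write centroid spectra as an MS1 text file
#'
#' Inverse of [read_ms1()]; numeric formatting is fixed (m/z to 5 decimals,
#' intensity to 4) so identical inputs produce byte-identical files.
#'
#' @param spectra list of spectra as returned by [read_ms1()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ms1 <- function(spectra, file) {
  out <- c("H\tCreationTool\tsebumetrics synthetic generator",
           "H\tDataType\tCentroided MS1")
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    out <- c(out,
             sprintf("S\t%d\t%d", s, s),
             sprintf("I\tRTime\t%.4f", sp$rt),
             sprintf("%.5f %.4f", sp$mz, sp$intensity))
  }
  writeLines(out, file)
  invisible(file)
}

#' Read MS1-level centroid spectra from an mzML file
#'
#' Convenience reader with the same semantic output as [read_ms1()].
#' Requires the `mzR` package. Retention times are converted from seconds
#' (mzML convention) to minutes.
#'
#' @param file path to an mzML file containing centroided MS1 scans.
#' @return A list of centroid spectra (see [read_ms1()]).
#' @export
read_mzml <- function(file) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("read_mzml requires the 'mzR' package")
  }
  fh <- mzR::openMSfile(file)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 scans in '", file, "' (MS2-only input?)")
  if (any(!is.na(hd$centroided[ms1]) & !hd$centroided[ms1])) {
    stop("profile-mode spectra are not supported; centroid the data first")
  }
  lapply(ms1, function(i) {
    p <- mzR::peaks(fh, i)
    list(rt = hd$retentionTime[i] / 60, mz = p[, 1], intensity = p[, 2])
  })
}

#' Write centroid spectra as mzML
#'
#' @param spectra list of spectra as returned by [read_ms1()].
#' @param file output mzML path.
#' @return `file`, invisibly.
#' @export
write_mzml <- function(spectra, file) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("write_mzml requires the 'mzR' package")
  }
  n <- length(spectra)
  pks <- lapply(spectra, function(sp) cbind(mz = sp$mz, intensity = sp$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(spectra, function(sp) length(sp$mz), 0L),
    totIonCurrent = vapply(spectra, function(sp) sum(sp$intensity), 0),
    retentionTime = vapply(spectra, function(sp) sp$rt * 60, 0),
    basePeakMZ = vapply(spectra, function(sp)
      if (length(sp$mz)) sp$mz[which.max(sp$intensity)] else 0, 0),
    basePeakIntensity = vapply(spectra, function(sp)
      if (length(sp$intensity)) max(sp$intensity) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(sp) if (length(sp$mz)) min(sp$mz) else 0, 0),
    highMZ = vapply(spectra, function(sp) if (length(sp$mz)) max(sp$mz) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pks, file, header = hdr)
  invisible(file)
}
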