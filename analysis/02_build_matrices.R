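#!/usr/bin/env Rscript
# Bin every simulated MS1 file into the 105,000-bin (0.01 Da, 250-1300 m/z)
# raw feature matrix per acquisition, summing peak intensities over the
# 0.8-1.0 min retention window.

library(sebumetrics)

data_dir <- "scratch/analysis/data"
mat_dir <- "scratch/analysis/matrices"
dir.create(mat_dir, recursive = TRUE, showWarnings = FALSE)

for (acq in c("replicates", "cohort_region_order", "cohort_sex_order")) {
  dir <- file.path(data_dir, acq)
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  files <- setdiff(list.files(dir, full.names = TRUE, pattern = "\\.ms1$"), "")
  names(files) <- tools::file_path_sans_ext(basename(files))
  raw <- build_feature_matrix(files, meta)
  # store only occupied bins: empty rows carry no information
  nz <- Matrix::rowSums(raw$values) > 0
  compact <- feature_matrix(as.matrix(raw$values[nz, , drop = FALSE]),
                            raw$bin_edges[nz], raw$sample_ids, "raw")
  write_feature_matrix(compact, file.path(mat_dir, paste0(acq, "_raw.tsv")))
  cat(sprintf("%-22s %d x %d raw matrix; %d occupied bins; total ion count %.3g\n",
              acq, nrow(raw$values), ncol(raw$values), sum(nz),
              sum(raw$values)))
}
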