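#!/usr/bin/env Rscript
# Unsupervised view: PCA score plots with 95% concentration ellipses for
# the sex grouping and for each pairwise region comparison.

library(sebumetrics)
library(ggplot2)

mat_dir <- "scratch/analysis/matrices"
data_dir <- "scratch/analysis/data"
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

plot_pca <- function(m, groups, title, file) {
  pc <- pca_projection(m)
  ells <- group_ellipse(pc$scores, groups, level = 0.95)
  df <- data.frame(PC1 = pc$scores[, 1], PC2 = pc$scores[, 2], group = groups)
  edf <- do.call(rbind, lapply(names(ells), function(g) {
    data.frame(group = g, ellipse_points(ells[[g]]) |>
                 (\(p) setNames(as.data.frame(p), c("PC1", "PC2")))())
  }))
  gg <- ggplot(df, aes(PC1, PC2, colour = group)) +
    geom_point(alpha = 0.8) +
    geom_path(data = edf, linewidth = 0.6) +
    labs(title = title,
         x = sprintf("PC1 (%.1f%%)", 100 * pc$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * pc$var_explained[2])) +
    theme_minimal()
  ggsave(file, gg, width = 5.5, height = 4.5)
  data.frame(comparison = title,
             pc1_var = round(pc$var_explained[1], 3),
             pc2_var = round(pc$var_explained[2], 3))
}

rows <- list()
sex_chain <- readRDS(file.path(mat_dir, "cohort_region_order_chain.rds"))
sex_meta <- read.delim(file.path(data_dir, "cohort_region_order/metadata.tsv"))
sex_meta <- sex_meta[match(sex_chain$top_selected$sample_ids, sex_meta$sample_id), ]
rows$sex <- plot_pca(sex_chain$top_selected, sex_meta$sex,
                     "sex", "results/figures/pca_sex.pdf")

reg_chain <- readRDS(file.path(mat_dir, "cohort_sex_order_chain.rds"))
reg_meta <- read.delim(file.path(data_dir, "cohort_sex_order/metadata.tsv"))
reg_meta <- reg_meta[match(reg_chain$top_selected$sample_ids, reg_meta$sample_id), ]
m <- reg_chain$top_selected
for (pair in list(c("cheek", "forehead"), c("neck", "forehead"),
                  c("neck", "cheek"))) {
  keep <- reg_meta$region %in% pair
  sub <- feature_matrix(m$values[, keep, drop = FALSE], m$bin_edges,
                        m$sample_ids[keep], "top_selected")
  nm <- paste(pair, collapse = "_vs_")
  rows[[nm]] <- plot_pca(sub, reg_meta$region[keep], nm,
                         file.path("results/figures",
                                   paste0("pca_", nm, ".pdf")))
}

tab <- do.call(rbind, rows)
write.table(tab, "results/pca_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
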