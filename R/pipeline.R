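#' Run the end-to-end workflow from one configuration
#'
#' Orchestrates simulate -> build matrix -> normalize -> reproducibility /
#' classification / PCA from a single configuration (a YAML file path or an
#' equivalent named list), writing each stage's outputs plus a run manifest
#' (config snapshot, seeds, per-artifact MD5 digests, package version,
#' timestamps) into a run directory. Deterministic stages reproduce
#' identical digests when re-run with an identical configuration; reruns
#' write to fresh run directories rather than mutating earlier outputs.
#'
#' Configuration keys (all optional unless noted):
#' \describe{
#'   \item{seed}{integer; drives the generator and model fits (default 1).}
#'   \item{study}{`"cohort"` (default) or `"replicates"`.}
#'   \item{cohort}{named list of [cohort_config()] overrides.}
#'   \item{order_by}{injection layout for cohort studies, `"region"` or
#'     `"sex"`.}
#'   \item{normalize}{list: `min_nonzero_fraction`, `epsilon`, `n_keep`,
#'     `keep_fraction`, `batch_mode` (`"blocks"` or `"explicit"`),
#'     `block_size`.}
#'   \item{rsd}{list: `regions`, `scale` — runs both %RSD modes (requires
#'     `study: replicates`).}
#'   \item{classify}{list of comparisons, each
#'     `list(task = "sex"|"region", regions = c(...), positive = ...)`.}
#'   \item{pca}{list: `group_by` (`"sex"` or `"region"`), `ellipse_level`.}
#' }
#'
#' @param config YAML file path or named list.
#' @param out_dir parent directory for run directories.
#' @param run_id name of this run's directory; default `run-<seed>`.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = "pipeline-runs", run_id = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  seed <- config$seed
  if (is.null(run_id)) run_id <- paste0("run-", seed)
  run_dir <- file.path(out_dir, run_id)
  if (dir.exists(run_dir)) {
    stop("run directory already exists (outputs are immutable): ", run_dir)
  }
  dir.create(run_dir, recursive = TRUE)

  manifest <- list(config = config,
                   seed = seed,
                   tool_version = as.character(utils::packageVersion("sebumetrics")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = list())
  add_output <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate
  cohort_args <- config$cohort
  cohort_args$rng_seed <- seed
  cfg <- do.call(cohort_config, cohort_args)
  data_dir <- file.path(run_dir, "spectra")
  sim <- run_stage("simulate", {
    if (config$study == "replicates") {
      generate_replicate_study(cfg, data_dir)
    } else {
      generate_cohort(cfg, data_dir, order_by = config$order_by)
    }
  })
  add_output("metadata", file.path(data_dir, "metadata.tsv"))

  # build matrix
  raw <- run_stage("build_matrix",
                   build_feature_matrix(sim$files, sim$metadata))
  raw_path <- file.path(run_dir, "matrix_raw_nonzero.tsv")
  run_stage("build_matrix", {
    nz <- Matrix::rowSums(raw$values) > 0
    write_feature_matrix(
      feature_matrix(as.matrix(raw$values[nz, , drop = FALSE]),
                     raw$bin_edges[nz], raw$sample_ids, "raw"),
      raw_path)
  })
  add_output("matrix_raw_nonzero", raw_path)

  # normalize
  ncfg <- config$normalize
  chain <- run_stage("normalize", {
    batch <- if (identical(ncfg$batch_mode, "blocks")) {
      assign_batches(sim$metadata, "consecutive_blocks",
                     block_size = ncfg$block_size)
    } else {
      assign_batches(sim$metadata, "explicit")
    }
    normalize_matrix(raw, batch,
                     min_nonzero_fraction = ncfg$min_nonzero_fraction,
                     epsilon = ncfg$epsilon, n_keep = ncfg$n_keep,
                     keep_fraction = ncfg$keep_fraction)
  })
  norm_path <- file.path(run_dir, "matrix_processed.tsv")
  write_feature_matrix(chain$top_selected, norm_path)
  add_output("matrix_processed", norm_path)

  # reproducibility
  if (!is.null(config$rsd)) {
    res <- run_stage("rsd", {
      do.call(rbind, lapply(config$rsd$regions, function(rg) {
        data.frame(
          region = rg,
          intrabatch = intrabatch_rsd(chain, sim$metadata, rg,
                                      scale = config$rsd$scale)$median_percent_rsd,
          interbatch = interbatch_rsd(chain, sim$metadata, rg,
                                      scale = config$rsd$scale)$median_percent_rsd)
      }))
    })
    rsd_path <- file.path(run_dir, "rsd_medians.tsv")
    utils::write.table(res, rsd_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_output("rsd_medians", rsd_path)
  }

  # classification
  for (cmp in config$classify) {
    nm <- run_stage("classify", {
      sub <- classification_subset(chain$top_selected, sim$metadata, cmp)
      cv <- run_cv(sub$matrix, sub$labels, sub$metadata,
                   positive = cmp$positive, seed = seed)
      name <- paste0("classify_", cmp$name)
      jsonlite::write_json(
        list(comparison = cmp$name, positive = cv$positive,
             accuracy_percent = cv$accuracy, auc = cv$auc,
             roc = cv$roc, samples = cv$samples, seed = seed),
        file.path(run_dir, paste0(name, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      name
    })
    add_output(nm, file.path(run_dir, paste0(nm, ".json")))
  }

  # pca
  if (!is.null(config$pca)) {
    run_stage("pca", {
      pc <- pca_projection(chain$top_selected)
      grp <- sim$metadata[[config$pca$group_by]][
        match(chain$top_selected$sample_ids, sim$metadata$sample_id)]
      ell <- group_ellipse(pc$scores, grp, level = config$pca$ellipse_level)
      df <- data.frame(sample_id = chain$top_selected$sample_ids,
                       group = grp, PC1 = pc$scores[, 1], PC2 = pc$scores[, 2])
      utils::write.table(df, file.path(run_dir, "pca_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(var_explained = pc$var_explained[1:2],
             ellipses = lapply(ell, function(e)
               list(center = e$center, semi_axes = e$semi_axes,
                    angle = e$angle, level = e$level))),
        file.path(run_dir, "pca_ellipses.json"), auto_unbox = TRUE, digits = NA)
    })
    add_output("pca_scores", file.path(run_dir, "pca_scores.tsv"))
    add_output("pca_ellipses", file.path(run_dir, "pca_ellipses.json"))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# Subset the processed matrix and metadata for one comparison.
classification_subset <- function(m, metadata, cmp) {
  meta <- metadata[match(m$sample_ids, metadata$sample_id), ]
  if (cmp$task == "sex") {
    return(list(matrix = m, labels = meta$sex, metadata = meta))
  }
  keep <- meta$region %in% cmp$regions
  vals <- m$values[, keep, drop = FALSE]
  sub <- feature_matrix(vals, m$bin_edges, m$sample_ids[keep], "top_selected")
  list(matrix = sub, labels = meta$region[keep], metadata = meta[keep, ])
}

# Fill defaults and reject malformed configurations before any computation.
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML file path")
  defaults <- list(seed = 1L, study = "cohort", order_by = "region",
                   cohort = list(),
                   normalize = list(min_nonzero_fraction = 0.01,
                                    epsilon = 1e-10, n_keep = NULL,
                                    keep_fraction = 0.10,
                                    batch_mode = "explicit", block_size = 30),
                   rsd = NULL, classify = list(), pca = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (k %in% c("normalize") && is.list(config[[k]])) {
      defaults[[k]][names(config[[k]])] <- config[[k]]
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  config <- defaults
  if (!config$study %in% c("cohort", "replicates")) {
    stop("study must be 'cohort' or 'replicates'")
  }
  if (!config$order_by %in% c("region", "sex")) {
    stop("order_by must be 'region' or 'sex'")
  }
  if (!is.null(config$rsd)) {
    if (config$study != "replicates") {
      stop("rsd analysis requires study: replicates")
    }
    if (is.null(config$rsd$regions)) config$rsd$regions <- region_vocabulary
    if (is.null(config$rsd$scale)) config$rsd$scale <- "tic"
    bad <- setdiff(config$rsd$regions, region_vocabulary)
    if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  config$classify <- lapply(config$classify, function(cmp) {
    if (is.null(cmp$task) || !cmp$task %in% c("sex", "region")) {
      stop("each comparison needs task 'sex' or 'region'")
    }
    if (cmp$task == "region") {
      if (length(cmp$regions) != 2) stop("region comparisons need exactly 2 regions")
      bad <- setdiff(cmp$regions, region_vocabulary)
      if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
      if (is.null(cmp$positive)) cmp$positive <- cmp$regions[2]
      if (is.null(cmp$name)) cmp$name <- paste(cmp$regions, collapse = "_vs_")
    } else {
      if (is.null(cmp$positive)) cmp$positive <- "M"
      if (is.null(cmp$name)) cmp$name <- "sex"
    }
    cmp
  })
  if (!is.null(config$pca)) {
    if (is.null(config$pca$group_by)) config$pca$group_by <- "region"
    if (!config$pca$group_by %in% c("sex", "region")) {
      stop("pca group_by must be 'sex' or 'region'")
    }
    if (is.null(config$pca$ellipse_level)) config$pca$ellipse_level <- 0.95
  }
  config$seed <- as.integer(config$seed)
  config
}
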