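test_that("percent RSD has the textbook closed forms", {
  expect_equal(percent_rsd(c(9, 10, 11)), 10)
  expect_equal(percent_rsd(c(5, 5, 5, 5)), 0)
  expect_error(percent_rsd(7), "at least 2")
  expect_true(is.nan(percent_rsd(c(-1, 1))))
})

test_that("percent RSD is scale invariant and concentrates at the noise CV", {
  set.seed(55)
  for (i in 1:20) {
    x <- rexp(5, 1 / 50)
    k <- runif(1, 0.1, 100)
    expect_equal(percent_rsd(k * x), percent_rsd(x), tolerance = 1e-10)
  }
  draws <- rnorm(1000, mean = 100, sd = 3)
  expect_gt(percent_rsd(draws), 2.5)
  expect_lt(percent_rsd(draws), 3.5)
})

test_that("intrabatch medians match a hand computation on a toy design", {
  # 2 bins, 2 batches x 3 replicates of one region, linear intensities
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     region = "neck", replicate = rep(1:3, 2),
                     batch = rep(1:2, each = 3), injection_order = 1:6)
  v <- rbind(c(9, 10, 11, 18, 20, 22),
             c(5, 5, 5, 7, 7, 13))
  m <- toy_matrix(v, "tic_normalized", ids = meta$sample_id)
  res <- intrabatch_rsd(m, meta, "neck")
  hand <- c(percent_rsd(c(9, 10, 11)), percent_rsd(c(5, 5, 5)),
            percent_rsd(c(18, 20, 22)), percent_rsd(c(7, 7, 13)))
  expect_equal(sort(as.numeric(res$values)), sort(hand))
  expect_equal(res$median_percent_rsd, median(hand))
})

test_that("noise-free replicate study has zero intrabatch RSD even with batch effects", {
  cfg <- cohort_config(n_lipid_peaks = 30, technical_cv = 0, donor_sd = 0,
                       tic_sd = 0, batch_peak_cv = 0.05,
                       batch_multipliers = c(1, 1.2, 0.9, 1.05, 0.95),
                       rng_seed = 13)
  sim <- generate_replicate_study(cfg, withr::local_tempdir())
  raw <- build_feature_matrix(sim$files, sim$metadata)
  chain <- normalize_matrix(raw, assign_batches(sim$metadata, "explicit"))
  res <- intrabatch_rsd(chain, sim$metadata, "cheek")
  expect_equal(res$median_percent_rsd, 0, tolerance = 1e-6)
})

test_that("scalar batch multipliers give the closed-form interbatch RSD on raw intensities", {
  mult <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  cfg <- cohort_config(n_lipid_peaks = 30, technical_cv = 0, donor_sd = 0,
                       tic_sd = 0, batch_peak_cv = 0,
                       batch_multipliers = mult, rng_seed = 13)
  sim <- generate_replicate_study(cfg, withr::local_tempdir())
  raw <- build_feature_matrix(sim$files, sim$metadata)
  chain <- normalize_matrix(raw, assign_batches(sim$metadata, "explicit"))
  res <- interbatch_rsd(chain, sim$metadata, "forehead", scale = "raw")
  want <- 100 * sd(mult) / mean(mult)
  vals <- as.numeric(res$values)
  expect_equal(max(abs(vals - want)), 0, tolerance = 1e-4)
  expect_equal(res$median_percent_rsd, want, tolerance = 1e-4)
  # and multipliers all 1, cv 0 -> interbatch RSD identically 0
  cfg0 <- cohort_config(n_lipid_peaks = 30, technical_cv = 0, donor_sd = 0,
                        tic_sd = 0, batch_peak_cv = 0, rng_seed = 13)
  sim0 <- generate_replicate_study(cfg0, withr::local_tempdir())
  chain0 <- normalize_matrix(build_feature_matrix(sim0$files, sim0$metadata),
                             assign_batches(sim0$metadata, "explicit"))
  res0 <- interbatch_rsd(chain0, sim0$metadata, "forehead")
  expect_equal(res0$median_percent_rsd, 0, tolerance = 1e-6)
})

test_that("medians are invariant to replicate labeling and bin order", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:10), region = "cheek",
                     replicate = rep(1:2, each = 5), batch = rep(1:5, 2),
                     injection_order = 1:10)
  set.seed(8)
  v <- matrix(rexp(40, 1 / 10), 4, 10)
  m <- toy_matrix(v, "tic_normalized", ids = meta$sample_id)
  base <- interbatch_rsd(m, meta, "cheek")$median_percent_rsd
  # permute bins
  mp <- toy_matrix(v[c(3, 1, 4, 2), ], "tic_normalized", ids = meta$sample_id)
  expect_equal(interbatch_rsd(mp, meta, "cheek")$median_percent_rsd, base)
  # relabel replicates (swap 1 <-> 2)
  meta2 <- meta
  meta2$replicate <- 3 - meta$replicate
  expect_equal(interbatch_rsd(m, meta2, "cheek")$median_percent_rsd, base)
})

test_that("incomplete replicate-by-batch designs are rejected with gaps listed", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:9), region = "neck",
                     replicate = c(rep(1:2, each = 4), 1),
                     batch = c(1:4, 1:4, 5), injection_order = 1:9)
  m <- toy_matrix(matrix(1, 2, 9), "tic_normalized", ids = meta$sample_id)
  expect_error(interbatch_rsd(m, meta, "neck"), "incomplete")
  # intrabatch with a single replicate in a batch
  meta1 <- data.frame(sample_id = c("a", "b", "c"), region = "neck",
                      replicate = c(1, 2, 1), batch = c(1, 1, 2),
                      injection_order = 1:3)
  m1 <- toy_matrix(matrix(1, 2, 3), "tic_normalized", ids = meta1$sample_id)
  expect_error(intrabatch_rsd(m1, meta1, "neck"), "fewer than 2")
})
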