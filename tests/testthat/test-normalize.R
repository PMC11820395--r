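test_that("sparse filter uses an inclusive >= threshold on the nonzero fraction", {
  set.seed(1)
  v <- matrix(0, 3, 200)
  v[1, 1] <- 5          # 0.5% nonzero -> dropped
  v[2, 1:2] <- 5        # 1.0% nonzero -> kept
  v[3, 1:50] <- 5
  m <- toy_matrix(v, "raw")
  out <- filter_sparse_bins(m, 0.01)
  expect_equal(out$bin_edges, m$bin_edges[2:3])
  expect_equal(out$stage, "sparse_filtered")
})

test_that("filtering an all-zero matrix errors with advice", {
  m <- toy_matrix(matrix(0, 4, 10), "raw")
  expect_error(filter_sparse_bins(m), "min_nonzero_fraction")
})

test_that("sparse filter agrees with a brute-force per-row count", {
  set.seed(33)
  v <- matrix(rbinom(80 * 50, 1, 0.05) * runif(80 * 50), 80, 50)
  m <- toy_matrix(v, "raw")
  out <- filter_sparse_bins(m, 0.04)
  manual <- which(vapply(seq_len(80), function(i) sum(v[i, ] > 0), 0) / 50 >= 0.04)
  expect_equal(out$bin_edges, m$bin_edges[manual])
})

test_that("TIC normalization yields unit column sums and scale invariance", {
  v <- cbind(c(2, 3, 5), c(1, 0, 3))
  m <- toy_matrix(v, "sparse_filtered")
  out <- tic_normalize(m)
  expect_equal(out$values[, 1], c(0.2, 0.3, 0.5))
  expect_lt(max(abs(colSums(out$values) - 1)), 1e-9)
  # scaling a sample's raw intensities is a no-op after normalization
  m2 <- toy_matrix(cbind(v[, 1] * 17.3, v[, 2]), "sparse_filtered")
  expect_equal(tic_normalize(m2)$values, out$values, tolerance = 1e-12)
})

test_that("zero-total samples are named in the TIC error", {
  m <- toy_matrix(cbind(c(1, 2), c(0, 0)), "sparse_filtered",
                  ids = c("good", "empty"))
  expect_error(tic_normalize(m), "empty")
})

test_that("per-sample load variation vanishes after TIC normalization", {
  base <- noise_free_config(rng_seed = 9)
  loaded <- noise_free_config(rng_seed = 9, tic_sd = 0.4)
  s1 <- generate_cohort(base, withr::local_tempdir())
  s2 <- generate_cohort(loaded, withr::local_tempdir())
  t1 <- tic_normalize(filter_sparse_bins(build_feature_matrix(s1$files, s1$metadata)))
  t2 <- tic_normalize(filter_sparse_bins(build_feature_matrix(s2$files, s2$metadata)))
  expect_equal(t1$values, t2$values, tolerance = 1e-6)
})

test_that("shifted log2 transform has the documented closed forms", {
  m <- toy_matrix(cbind(c(0, 1 - 1e-10, 0.5)), "tic_normalized")
  out <- log_transform(m, 1e-10)
  expect_equal(out$values[1, 1], -10 * log2(10), tolerance = 1e-12)
  expect_equal(out$values[2, 1], 0, tolerance = 1e-9)
  # strictly increasing in v
  grid <- sort(runif(100))
  lg <- log2(grid + 1e-10)
  expect_true(all(diff(lg) > 0))
  expect_error(log_transform(toy_matrix(cbind(-0.1), "tic_normalized")),
               "negative")
})

test_that("balanced constant batch shift cancels to the midline", {
  set.seed(4)
  base <- matrix(rnorm(5 * 4), 5, 4)
  shifted <- cbind(base, base + 2.5)   # batch 2 = batch 1 + c per sample
  m <- toy_matrix(shifted, "log2")
  out <- remove_batch_effects(m, rep(1:2, each = 4))
  expect_equal(out$values[, 1:4], out$values[, 5:8], tolerance = 1e-10)
  expect_equal(out$values[, 1:4], base + 1.25, tolerance = 1e-10)
})

test_that("single-batch correction is the identity with a warning", {
  m <- toy_matrix(matrix(rnorm(12), 3, 4), "log2")
  expect_warning(out <- remove_batch_effects(m, rep(1, 4)), "single batch")
  expect_equal(out$values, m$values)
  expect_equal(out$stage, "batch_corrected")
})

test_that("batch correction matches the per-feature least-squares oracle", {
  set.seed(77)
  v <- matrix(rnorm(50 * 24), 50, 24)
  batch <- rep(1:4, each = 6)
  out <- remove_batch_effects(toy_matrix(v, "log2"), batch)
  expect_equal(out$values, batch_correct_oracle(v, batch), tolerance = 1e-10,
               ignore_attr = TRUE)
  # balanced closed form: subtract batch mean, restore grand mean of batch means
  for (i in 1:5) {
    bm <- tapply(v[i, ], batch, mean)
    closed <- as.numeric(v[i, ] - bm[batch] + mean(bm))
    expect_equal(unname(out$values[i, ]), closed, tolerance = 1e-10)
  }
  # unbalanced design: per-feature intercept (sum-to-zero fit) is preserved
  batch_u <- rep(1:3, c(4, 9, 11))
  out_u <- remove_batch_effects(toy_matrix(v, "log2"), batch_u)
  fb <- factor(batch_u)
  for (i in 1:10) {
    b0 <- coef(lm(v[i, ] ~ fb, contrasts = list(fb = "contr.sum")))[1]
    a0 <- coef(lm(out_u$values[i, ] ~ fb, contrasts = list(fb = "contr.sum")))[1]
    expect_equal(unname(a0), unname(b0), tolerance = 1e-8)
  }
  expect_equal(out_u$values, batch_correct_oracle(v, batch_u),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("top-median selection keeps exactly n_keep bins in original order", {
  med_target <- c(5, 9, 1, 9, 7, 3, 8, 2, 6, 4)
  v <- sapply(seq_len(12), function(j) med_target)  # constant rows
  m <- toy_matrix(v, "batch_corrected")
  out <- select_top_median_bins(m, 3)
  # medians 9, 9, 8 -> rows 2, 4, 7; tie between rows 2 and 4 is moot (both in)
  expect_equal(out$bin_edges, m$bin_edges[c(2, 4, 7)])
  out2 <- select_top_median_bins(m, 4)   # next is median 7 -> row 5
  expect_equal(out2$bin_edges, m$bin_edges[c(2, 4, 5, 7)])
  # ties at the cutoff break toward the lower m/z edge
  vt <- matrix(rep(c(3, 5, 5, 5, 1), 4), 5, 4)
  mt <- toy_matrix(vt, "batch_corrected")
  expect_equal(select_top_median_bins(mt, 2)$bin_edges, mt$bin_edges[2:3])
  # identity case and value preservation
  all_kept <- select_top_median_bins(m, 10)
  expect_equal(all_kept$values, m$values)
  expect_error(select_top_median_bins(m, 0), "positive")
  expect_error(select_top_median_bins(m, 11), "exceeds")
})

test_that("consecutive-block batch assignment follows the injection layout", {
  meta <- data.frame(sample_id = sprintf("s%03d", 1:180),
                     injection_order = sample(1:180))
  b <- assign_batches(meta, "consecutive_blocks", block_size = 30)
  expect_equal(sort(unique(b)), 1:6)
  expect_equal(as.integer(table(b)), rep(30L, 6))
  # batch index tracks injection order, not row order
  expect_equal(unname(b[order(meta$injection_order)]), rep(1:6, each = 30))
  meta179 <- meta[1:179, ]
  meta179$injection_order <- 1:179
  expect_error(assign_batches(meta179, "consecutive_blocks", 30),
               "does not divide")
})

test_that("explicit batch assignment passes through and renumbers contiguously", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     injection_order = 1:4, batch = c(2, 2, 5, 5))
  b <- assign_batches(meta, "explicit")
  expect_equal(unname(b), c(1L, 1L, 2L, 2L))
})

test_that("stage transitions are enforced in the documented order", {
  v <- matrix(runif(20), 5, 4)
  expect_error(tic_normalize(toy_matrix(v, "raw")), "stage")
  expect_error(log_transform(toy_matrix(v, "raw")), "stage")
  expect_error(remove_batch_effects(toy_matrix(v, "tic_normalized"), rep(1:2, 2)),
               "stage")
  expect_error(select_top_median_bins(toy_matrix(v, "log2"), 2), "stage")
  expect_error(filter_sparse_bins(toy_matrix(v, "log2")), "stage")
})

test_that("the full chain is deterministic for identical inputs", {
  cfg <- small_cohort_config(rng_seed = 21)
  sim <- generate_cohort(cfg, withr::local_tempdir())
  raw <- build_feature_matrix(sim$files, sim$metadata)
  batch <- assign_batches(sim$metadata, "consecutive_blocks", block_size = 6)
  c1 <- normalize_matrix(raw, batch)
  c2 <- normalize_matrix(raw, batch)
  expect_identical(c1$top_selected$values, c2$top_selected$values)
})
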