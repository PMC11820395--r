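test_that("donor-exclusion splits partition samples and block donor leakage", {
  meta <- data.frame(sample_id = sprintf("s%03d", 1:180),
                     donor_id = rep(sprintf("D%02d", 1:30), each = 6))
  splits <- leave_one_donor_out_splits(meta)
  expect_length(splits, 180)
  expect_equal(sort(vapply(splits, `[[`, 0L, "test")), 1:180)
  for (sp in splits) {
    expect_length(sp$train, 174)
    expect_false(meta$donor_id[sp$test] %in% meta$donor_id[sp$train])
  }
  # two donors, one sample each: each trains on the other
  meta2 <- data.frame(sample_id = c("a", "b"), donor_id = c("d1", "d2"))
  sp2 <- leave_one_donor_out_splits(meta2)
  expect_equal(sp2[[1]]$train, 2L)
  expect_equal(sp2[[2]]$train, 1L)
  expect_error(leave_one_donor_out_splits(data.frame(sample_id = "a")),
               "donor_id")
})

test_that("ROC/AUC handles the canonical hand cases", {
  # positives {0.9, 0.4}, negatives {0.6, 0.1}: 3 of 4 pairs correct
  res <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$auc, 0.75)
  # all scores equal -> chance
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # perfect separation
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "negative")
  # curve starts at (0,0) and ends at (1,1), monotone
  expect_equal(unlist(res$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(res$roc[nrow(res$roc), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(res$roc$fpr) >= 0) && all(diff(res$roc$tpr) >= 0))
})

test_that("trapezoidal AUC agrees with pROC on tied and untied scores", {
  set.seed(12)
  for (i in 1:5) {
    scores <- round(runif(40), 2)   # rounding forces ties
    labels <- rbinom(40, 1, 0.5) == 1
    if (!any(labels) || all(labels)) next
    ours <- roc_auc(scores, labels)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      labels, scores, levels = c(FALSE, TRUE), direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("a perfectly separating feature yields 100% accuracy and AUC 1", {
  set.seed(3)
  n <- 24
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     donor_id = rep(sprintf("d%d", 1:8), each = 3))
  labels <- rep(rep(c("A", "B"), each = 3), 4)[1:n]
  v <- matrix(rnorm(5 * n), 5, n)
  v[3, ] <- ifelse(labels == "B", 10, -10)
  m <- toy_matrix(v, "top_selected", ids = meta$sample_id)
  cv <- run_cv(m, labels, meta, positive = "B", seed = 1)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$auc, 1)
  expect_equal(classification_accuracy(cv), 100)
})

test_that("repeated runs on identical input are identical", {
  set.seed(14)
  n <- 18
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     donor_id = rep(sprintf("d%d", 1:6), each = 3))
  labels <- rep(c("x", "y"), 9)
  m <- toy_matrix(matrix(rnorm(8 * n), 8, n), "top_selected",
                  ids = meta$sample_id)
  cv1 <- run_cv(m, labels, meta, seed = 5)
  cv2 <- run_cv(m, labels, meta, seed = 5)
  expect_identical(cv1$samples$prob, cv2$samples$prob)
  expect_identical(cv1$auc, cv2$auc)
})

test_that("degenerate classification inputs are rejected", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     donor_id = c("d1", "d1", "d2", "d2"))
  m <- toy_matrix(matrix(rnorm(8), 2, 4), "top_selected", ids = meta$sample_id)
  expect_error(run_cv(m, c("x", "y", "z", "x"), meta), "2 classes")
  # labels perfectly aligned with donors -> single-class training folds
  expect_error(run_cv(m, c("x", "x", "y", "y"), meta), "single class")
  expect_error(run_cv(toy_matrix(matrix(1, 2, 4), "log2", ids = meta$sample_id),
                      c("x", "y", "x", "y"), meta), "stage")
})
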