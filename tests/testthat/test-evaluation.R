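test_that("confusion counts match hand tallies", {
  c1 <- confusion(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(5, 5)))
  expect_equal(unclass(c1)[c("tp", "tn", "fp", "fn")],
               list(tp = 5L, tn = 5L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  c2 <- confusion(rep(c(1, 0), c(3, 7)), rep(1, 10))
  expect_equal(unclass(c2)[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 7L, tn = 0L, fn = 0L), ignore_attr = TRUE)
  c3 <- confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unclass(c3)[c("tp", "fn", "tn", "fp")],
               list(tp = 2L, fn = 1L, tn = 1L, fp = 1L), ignore_attr = TRUE)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
})

test_that("metric ratios and their complementarity identities are exact", {
  m <- metrics_from_counts(list(tp = 68, fn = 2, tn = 57, fp = 13))
  expect_equal(round(100 * m$sensitivity, 2), 97.14)
  expect_equal(round(100 * m$fnr, 2), 2.86)
  expect_equal(round(100 * m$specificity, 2), 81.43)
  expect_equal(round(100 * m$fpr, 2), 18.57)
  expect_identical(m$sensitivity + m$fnr, 1)
  expect_identical(m$specificity + m$fpr, 1)

  p <- metrics_from_counts(list(tp = 7, fn = 0, tn = 9, fp = 0))
  expect_equal(unlist(p), c(accuracy = 1, sensitivity = 1, specificity = 1,
                            fnr = 0, fpr = 0))
  q <- metrics_from_counts(list(tp = 3, fn = 2, tn = 4, fp = 1))
  expect_equal(q$accuracy, 0.7)
  expect_equal(q$sensitivity, 0.6)
  expect_equal(q$specificity, 0.8)
  expect_error(metrics_from_counts(list(tp = 0, fn = 0, tn = 3, fp = 1)),
               "positives")
})

test_that("ROC-AUC equals the concordant-pair oracle, ties at half credit", {
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(4:30, 1)
    y <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("the 16:4:5 split is subject-grouped and largest-remainder sized", {
  tab25 <- noise_table(25, 3, reps = 3, seed = 1)
  tab25$label <- 1L  # single stratum of 25 subjects splits exactly 16/4/5
  tab25 <- feature_table(as.data.frame(tab25), canonical = FALSE)
  sp <- split_grouped(tab25, seed = 3)
  n_subj <- function(idx) length(unique(tab25$subject_id[idx]))
  expect_equal(c(n_subj(sp$train), n_subj(sp$validation), n_subj(sp$test)),
               c(16, 4, 5))

  tab <- noise_table(179, 3, reps = 3, seed = 2)
  tab$label <- rep(rep(c(1L, 0L), c(109, 70)), each = 3)
  tab <- feature_table(as.data.frame(tab), canonical = FALSE)
  for (seed in 1:5) {
    sp <- split_grouped(tab, seed = seed)
    ids <- lapply(sp, function(i) unique(tab$subject_id[i]))
    expect_equal(length(Reduce(intersect, ids)), 0)
    expect_equal(sort(unname(unlist(sp))), seq_len(nrow(tab)))
    sizes <- vapply(sp, function(i) length(unique(tab$subject_id[i])),
                    numeric(1))
    expect_true(all(abs(sizes - c(114.6, 28.6, 35.8)) <= 1.5))
  }
})

test_that("grouped cross-validation covers all subjects without leakage", {
  tab <- noise_table(30, 12, reps = 3, seed = 6, informative = 1:2, shift = 3)
  cv <- cross_validate(tab, k = 5, seed = 4, select = FALSE,
                       gbrt_args = list(n_trees = 40L))
  expect_equal(nrow(cv$folds), 5)
  expect_gt(cv$mean$auc, 0.9)
  expect_equal(cv$mean$sensitivity + cv$mean$fnr, 1, tolerance = 1e-12)
  expect_equal(cv$mean$specificity + cv$mean$fpr, 1, tolerance = 1e-12)

  # selection re-run inside folds does not fabricate signal from pure noise
  null_tab <- noise_table(30, 60, reps = 3, seed = 7)
  cv0 <- cross_validate(null_tab, k = 5, seed = 8, select = TRUE,
                        select_args = list(k = 3, patience = 2, max_iter = 8),
                        gbrt_args = list(n_trees = 40L))
  expect_gte(cv0$mean$auc, 0.3)
  expect_lte(cv0$mean$auc, 0.7)
})

test_that("the label screen calibrates under the null and flags constants", {
  tab <- noise_table(10, 3, reps = 1, seed = 9)
  tab$F0001 <- as.numeric(tab$label)
  tab$F0003 <- 5
  sc <- pearson_screen(tab)
  expect_equal(sc$results$r[1], 1, tolerance = 1e-12)
  expect_true(sc$results$constant[3])
  expect_false(1 %in% which(sc$results$constant))

  fracs <- vapply(1:20, function(seed) {
    nt <- noise_table(100, 1000, reps = 1, seed = 100 + seed)
    pearson_screen(nt)$n_significant / 1000
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("muscle x movement aggregation partitions the selected set", {
  feats <- c("A1_M3_TF_01", "A1_M3_FF_02", "A1_M4_EY_01", "A7_M2_WL_03",
             "A1_FRR_1", "A3_DU_02")
  sel <- structure(list(final_features = feats), class = "selection_result")
  model <- structure(list(importance = c(A1_M3_TF_01 = 2, A1_M3_FF_02 = 1,
                                         A1_M4_EY_01 = 4, A7_M2_WL_03 = 0.5,
                                         A1_FRR_1 = 3, A3_DU_02 = 0)),
                     class = "gbrt_model")
  agg <- aggregate_muscle_movement(sel, model)
  expect_equal(sum(agg$counts) + sum(agg$movement_counts), length(feats))
  expect_equal(agg$counts["A1", "M3"], 2, ignore_attr = TRUE)
  expect_equal(agg$importance["A1", "M3"], 3, ignore_attr = TRUE)
  expect_equal(agg$importance["A2", "M1"], 0, ignore_attr = TRUE)
  expect_equal(unname(agg$movement_importance["A1"]), 3)
  expect_equal(unname(agg$row_marginals["A1"]), 3)
})
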