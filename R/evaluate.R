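# ---- evaluation: confusion metrics, ROC-AUC, grouped splits, CV, screen,
#      muscle x movement aggregation

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred equal-length binary vectors (1 = CS, 0 = healthy).
#' @return object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("entries must be binary 0/1")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP + TN) / (P + N); sensitivity = TP / P;
#' specificity = TN / N; FNR = FN / P; FPR = FP / N. The complementarity
#' identities sensitivity + FNR = 1 and specificity + FPR = 1 hold exactly.
#'
#' @param counts a `confusion_counts` object.
#' @return named list with `accuracy`, `sensitivity`, `specificity`, `fnr`,
#'   `fpr` (each in \[0, 1\]).
#' @export
metrics_from_counts <- function(counts) {
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  if (pos == 0) stop("zero positives: sensitivity/FNR undefined")
  if (neg == 0) stop("zero negatives: specificity/FPR undefined")
  list(accuracy = (counts$tp + counts$tn) / (pos + neg),
       sensitivity = counts$tp / pos,
       specificity = counts$tn / neg,
       fnr = counts$fn / pos,
       fpr = counts$fp / neg)
}

#' ROC-AUC
#'
#' Area under the ROC curve (trapezoidal over the threshold sweep), equal to
#' the Mann-Whitney concordance probability with half credit for ties.
#'
#' @param scores numeric classifier scores (higher = more CS-like).
#' @param y_true binary labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true) {
  if (length(unique(y_true)) < 2) stop("both classes required for AUC")
  r <- pROC::roc(response = y_true, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Subject-grouped 16:4:5 train/validation/test split
#'
#' Subjects (never rows) are allocated to the three strata in the given
#' proportions via largest-remainder rounding, separately per class; all
#' repetitions follow their subject.
#'
#' @param table a `feature_table`.
#' @param ratios three positive weights (default `c(16, 4, 5)`).
#' @param seed integer seed.
#' @return list of row-index vectors `train`, `validation`, `test`.
#' @export
split_grouped <- function(table, ratios = c(16, 4, 5), seed) {
  stopifnot(inherits(table, "feature_table"), length(ratios) == 3)
  subj <- unique(data.frame(subject_id = table$subject_id,
                            label = table$label))
  if (nrow(subj) < sum(ratios))
    stop("need at least ", sum(ratios), " subjects")
  set.seed(seed %% .Machine$integer.max)
  alloc <- list(train = character(0), validation = character(0),
                test = character(0))
  for (cl in unique(subj$label)) {
    ids <- sample(subj$subject_id[subj$label == cl])
    sizes <- largest_remainder(length(ids), ratios)
    alloc$train <- c(alloc$train, ids[seq_len(sizes[1])])
    alloc$validation <- c(alloc$validation,
                          ids[sizes[1] + seq_len(sizes[2])])
    alloc$test <- c(alloc$test, ids[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  lapply(alloc, function(ids) which(table$subject_id %in% ids))
}

# subject-grouped, class-stratified k folds (round-robin after shuffle)
grouped_folds <- function(table, k, seed) {
  subj <- unique(data.frame(subject_id = table$subject_id,
                            label = table$label))
  set.seed(seed %% .Machine$integer.max)
  fold_of <- character(0)
  folds <- rep(list(character(0)), k)
  for (cl in unique(subj$label)) {
    ids <- sample(subj$subject_id[subj$label == cl])
    for (i in seq_along(ids)) {
      g <- ((i - 1L) %% k) + 1L
      folds[[g]] <- c(folds[[g]], ids[i])
    }
  }
  lapply(folds, function(ids) which(table$subject_id %in% ids))
}

#' Subject-grouped k-fold cross-validation of the full pipeline
#'
#' For each fold, using the training part only: missing cells are imputed
#' class-conditionally, feature selection is re-run (no selection leakage),
#' and the boosted-trees classifier is fitted on the selected features. The
#' held-out part is imputed with training-set global means and scored.
#'
#' @param table a labeled canonical-or-reduced `feature_table` (may contain
#'   missing cells).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param select run feature selection inside folds (default TRUE).
#' @param select_args list of arguments for [rf_union_select()].
#' @param gbrt_args list of arguments for [gbrt_fit()].
#' @return object of class `metrics_report`: per-fold data.frame `folds`
#'   (accuracy, sensitivity, specificity, fnr, fpr, auc, n_selected) and
#'   `mean` (column means).
#' @export
cross_validate <- function(table, k = 5L, seed, select = TRUE,
                           select_args = list(), gbrt_args = list()) {
  stopifnot(inherits(table, "feature_table"))
  folds <- grouped_folds(table, k, seed)
  rows <- lapply(seq_len(k), function(fi) {
    test_idx <- folds[[fi]]
    train <- table[-test_idx, , drop = FALSE]
    test <- table[test_idx, , drop = FALSE]
    train <- impute_missing(train, "class_mean")
    train_means <- colMeans(feature_matrix(train))
    test <- impute_missing(test, "global_mean", means = train_means)
    if (select) {
      sel <- do.call(rf_union_select,
                     c(list(table = train, seed = seed + 17L * fi),
                       select_args))
      keep <- c("subject_id", "label", "repetition", sel$final_features)
      train <- feature_table(as.data.frame(train)[, keep], canonical = FALSE)
      test <- feature_table(as.data.frame(test)[, keep], canonical = FALSE)
      n_sel <- length(sel$final_features)
    } else n_sel <- length(feature_cols(train))
    model <- do.call(gbrt_fit,
                     c(list(table = train, seed = seed + 29L * fi),
                       gbrt_args))
    scores <- gbrt_predict_score(model, test)
    labels <- as.integer(plogis(scores) >= 0.5)
    m <- metrics_from_counts(confusion(test$label, labels))
    data.frame(fold = fi, accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, fnr = m$fnr, fpr = m$fpr,
               auc = roc_auc(scores, test$label), n_selected = n_sel)
  })
  per_fold <- do.call(rbind, rows)
  means <- colMeans(per_fold[, -1])
  structure(list(folds = per_fold, mean = as.list(means)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$mean
  cat(sprintf(paste0("<metrics_report> %d folds | mean accuracy %.2f%% ",
                     "sensitivity %.2f%% specificity %.2f%% FNR %.2f%% ",
                     "FPR %.2f%% AUC %.3f\n"),
              nrow(x$folds), 100 * m$accuracy, 100 * m$sensitivity,
              100 * m$specificity, 100 * m$fnr, 100 * m$fpr, m$auc))
  invisible(x)
}

#' Point-biserial Pearson screen of every feature against the label
#'
#' Two-sided p-values from the t transform of the Pearson correlation
#' between each feature column and the binary label. Constant columns are
#' flagged and excluded from the significance count rather than tested.
#'
#' @param table a labeled `feature_table` (complete columns are screened;
#'   missing cells are dropped pairwise).
#' @param alpha significance level for the reported count (default 0.05).
#' @return list with `results` (data.frame: `feature`, `r`, `p`,
#'   `constant`) and `n_significant` (count with `p <= alpha`).
#' @export
pearson_screen <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$label
  X <- feature_matrix(table)
  if (nrow(X) < 3) stop("need at least 3 rows")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  r <- rep(NA_real_, ncol(X))
  p <- rep(NA_real_, ncol(X))
  ok <- which(!const)
  if (length(ok)) {
    r[ok] <- suppressWarnings(as.numeric(cor(X[, ok, drop = FALSE], y,
                                             use = "pairwise.complete.obs")))
    n <- nrow(X)
    tt <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, 1e-300))
    p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  }
  res <- data.frame(feature = colnames(X), r = r, p = p, constant = const,
                    stringsAsFactors = FALSE)
  list(results = res, n_significant = sum(res$p <= alpha, na.rm = TRUE))
}

#' Aggregate selected features and model importance over muscles x movements
#'
#' Counts of selected channel-scope features and summed model importance
#' (total split gain) per (movement, muscle) cell, as in the heat-map view
#' of which muscle-movement combinations drive the classification;
#' movement-scope features aggregate into per-movement marginal vectors.
#'
#' @param selection a `selection_result`.
#' @param model a fitted `gbrt_model` over the selected features.
#' @return list with `counts` and `importance` (7 x 6 matrices, rows A1..A7,
#'   columns M1..M6), `movement_counts` and `movement_importance` (length-7
#'   marginals of the movement-scope features), plus `row_marginals` /
#'   `col_marginals` of the counts matrix.
#' @export
aggregate_muscle_movement <- function(selection, model) {
  feats <- selection$final_features
  info <- parse_feature_names(feats)
  imp <- model$importance[feats]
  imp[is.na(imp)] <- 0
  counts <- matrix(0L, 7, 6, dimnames = list(MOVEMENTS, MUSCLES))
  impm <- matrix(0, 7, 6, dimnames = list(MOVEMENTS, MUSCLES))
  mov_counts <- setNames(integer(7), MOVEMENTS)
  mov_imp <- setNames(numeric(7), MOVEMENTS)
  for (i in seq_len(nrow(info))) {
    mv <- info$movement[i]
    if (info$scope[i] == "channel") {
      ms <- info$muscle[i]
      counts[mv, ms] <- counts[mv, ms] + 1L
      impm[mv, ms] <- impm[mv, ms] + imp[[i]]
    } else {
      mov_counts[mv] <- mov_counts[mv] + 1L
      mov_imp[mv] <- mov_imp[mv] + imp[[i]]
    }
  }
  list(counts = counts, importance = impm,
       movement_counts = mov_counts, movement_importance = mov_imp,
       row_marginals = rowSums(counts), col_marginals = colSums(counts))
}
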