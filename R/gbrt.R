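# ---- gradient-boosted regression trees with logistic loss (from scratch)

logloss <- function(y, score) {
  # numerically stable binary logistic loss on log-odds scores
  mean(ifelse(y == 1, log1p(exp(-score)), log1p(exp(score))))
}

grow_tree <- function(X, g, h, rows, depth, params, gain_acc) {
  G <- sum(g[rows]); H <- sum(h[rows])
  leaf <- function() list(leaf = TRUE, weight = -G / (H + params$reg_lambda))
  if (depth >= params$max_depth || length(rows) < 2 * params$min_leaf)
    return(leaf())
  sp <- best_split_cpp(X, g, h, rows - 1L, params$reg_lambda, params$gamma,
                       params$min_leaf)
  if (!sp$found) return(leaf())
  xj <- X[rows, sp$feature]
  left <- rows[xj < sp$threshold]
  right <- rows[xj >= sp$threshold]
  gain_acc$gain[sp$feature] <- gain_acc$gain[sp$feature] + sp$gain
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain,
       left = grow_tree(X, g, h, left, depth + 1L, params, gain_acc),
       right = grow_tree(X, g, h, right, depth + 1L, params, gain_acc))
}

predict_tree <- function(node, X, rows = seq_len(nrow(X))) {
  out <- numeric(nrow(X))
  rec <- function(nd, rr) {
    if (length(rr) == 0) return()
    if (isTRUE(nd$leaf)) {
      out[rr] <<- nd$weight
      return()
    }
    go_left <- X[rr, nd$feature] < nd$threshold
    rec(nd$left, rr[go_left])
    rec(nd$right, rr[!go_left])
  }
  rec(node, rows)
  out
}

tree_depth <- function(node) {
  if (isTRUE(node$leaf)) 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Fit a gradient-boosted regression-tree binary classifier
#'
#' Stagewise additive model on log-odds scores with binary logistic loss:
#' each stage grows one regression tree greedily on the first- and
#' second-order loss gradients, with leaf weight `-G/(H + lambda)` and split
#' gain `0.5 (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)) - gamma`
#' (the per-tree complexity penalty is `gamma` per leaf plus
#' `lambda/2 * sum(weights^2)`). The initial score is the log-odds of the
#' training prevalence. Training log-loss is recorded after every stage.
#'
#' @param table a labeled, fully observed `feature_table`.
#' @param n_trees number of boosting stages.
#' @param learning_rate shrinkage in (0, 1].
#' @param max_depth maximum tree depth (1 = stumps).
#' @param min_leaf minimum rows per leaf.
#' @param reg_lambda L2 leaf-weight regularization.
#' @param gamma minimum split gain / per-leaf penalty.
#' @param seed integer seed (fitting is deterministic; kept for the model
#'   record).
#' @return an object of class `gbrt_model`: `trees`, `base_score`,
#'   `learning_rate`, `params`, `feature_names`, `train_logloss` (one value
#'   per stage), `importance` (total split gain per feature).
#' @export
gbrt_fit <- function(table, n_trees = 100L, learning_rate = 0.1,
                     max_depth = 3L, min_leaf = 1L, reg_lambda = 1,
                     gamma = 0, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$label
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  X <- feature_matrix(table)
  if (anyNA(X) || !all(is.finite(X))) stop("non-finite feature values")
  stopifnot(learning_rate > 0, learning_rate <= 1, n_trees >= 1)
  n <- nrow(X)
  params <- list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), reg_lambda = reg_lambda,
                 gamma = gamma)
  prev <- mean(y)
  base_score <- qlogis(min(max(prev, 1e-6), 1 - 1e-6))
  score <- rep(base_score, n)
  trees <- vector("list", n_trees)
  train_ll <- numeric(n_trees)
  gain_acc <- new.env()
  gain_acc$gain <- setNames(numeric(ncol(X)), colnames(X))
  for (t in seq_len(n_trees)) {
    p <- plogis(score)
    g <- p - y
    h <- p * (1 - p)
    tree <- grow_tree(X, g, h, seq_len(n), 0L, params, gain_acc)
    trees[[t]] <- tree
    score <- score + learning_rate * predict_tree(tree, X)
    train_ll[t] <- logloss(y, score)
  }
  structure(list(trees = trees, base_score = base_score,
                 learning_rate = learning_rate, params = params,
                 feature_names = colnames(X), train_logloss = train_ll,
                 importance = gain_acc$gain, seed = as.integer(seed)),
            class = "gbrt_model")
}

#' @export
print.gbrt_model <- function(x, ...) {
  cat(sprintf("<gbrt_model> %d trees, depth <= %d, lr %g, %d features; final train log-loss %.4f\n",
              length(x$trees), x$params$max_depth, x$learning_rate,
              length(x$feature_names), tail(x$train_logloss, 1)))
  invisible(x)
}

model_matrix <- function(model, rows) {
  if (inherits(rows, "feature_table")) rows <- feature_matrix(rows)
  rows <- as.matrix(rows)
  missing_feats <- setdiff(model$feature_names, colnames(rows))
  if (length(missing_feats))
    stop("missing referenced feature(s): ",
         paste(head(missing_feats, 3), collapse = ", "))
  rows[, model$feature_names, drop = FALSE]
}

#' Predict with a fitted boosted-trees model
#'
#' `gbrt_predict_score` returns log-odds, `gbrt_predict_proba` the logistic
#' probabilities (strictly in (0, 1)), `gbrt_predict_label` binary labels at
#' a probability threshold, and `gbrt_staged_scores` the score after each
#' prefix of trees (rows x stages matrix).
#'
#' @param model a `gbrt_model`.
#' @param rows a `feature_table` or numeric matrix carrying every feature
#'   the model references.
#' @param n_trees optional prefix length (use only the first trees).
#' @param threshold probability threshold for labels (default 0.5; label 1
#'   iff probability >= threshold).
#' @return numeric vector (scores, probabilities, 0/1 labels) or matrix
#'   (staged scores).
#' @export
gbrt_predict_score <- function(model, rows, n_trees = NULL) {
  X <- model_matrix(model, rows)
  use <- if (is.null(n_trees)) length(model$trees)
         else min(n_trees, length(model$trees))
  score <- rep(model$base_score, nrow(X))
  for (t in seq_len(use))
    score <- score + model$learning_rate * predict_tree(model$trees[[t]], X)
  score
}

#' @rdname gbrt_predict_score
#' @export
gbrt_predict_proba <- function(model, rows, n_trees = NULL) {
  plogis(gbrt_predict_score(model, rows, n_trees))
}

#' @rdname gbrt_predict_score
#' @export
gbrt_predict_label <- function(model, rows, threshold = 0.5, n_trees = NULL) {
  as.integer(gbrt_predict_proba(model, rows, n_trees) >= threshold)
}

#' @rdname gbrt_predict_score
#' @export
gbrt_staged_scores <- function(model, rows) {
  X <- model_matrix(model, rows)
  nt <- length(model$trees)
  out <- matrix(0, nrow = nrow(X), ncol = nt)
  score <- rep(model$base_score, nrow(X))
  for (t in seq_len(nt)) {
    score <- score + model$learning_rate * predict_tree(model$trees[[t]], X)
    out[, t] <- score
  }
  out
}

#' Pick the tree count maximizing validation AUC
#'
#' Sweeps the staged scores of a fitted model over a validation table and
#' returns the smallest prefix attaining the maximal AUC.
#'
#' @param model a `gbrt_model`.
#' @param val_table labeled validation `feature_table`.
#' @return list with `n_trees` and `auc`.
#' @export
gbrt_tune_trees <- function(model, val_table) {
  staged <- gbrt_staged_scores(model, val_table)
  aucs <- apply(staged, 2, function(s) roc_auc(s, val_table$label))
  best <- which.max(aucs)
  list(n_trees = as.integer(best), auc = aucs[[best]])
}

tree_to_list <- function(node) {
  if (isTRUE(node$leaf)) list(leaf = TRUE, weight = node$weight)
  else list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
            gain = node$gain, left = tree_to_list(node$left),
            right = tree_to_list(node$right))
}

list_to_tree <- function(lst) {
  if (isTRUE(lst$leaf)) list(leaf = TRUE, weight = lst$weight)
  else list(leaf = FALSE, feature = as.integer(lst$feature),
            threshold = lst$threshold, gain = lst$gain,
            left = list_to_tree(lst$left), right = list_to_tree(lst$right))
}

#' Serialize / deserialize a boosted-trees model as JSON
#'
#' The JSON carries trees, parameters, feature names and seed at full double
#' precision, so a reloaded model predicts bit-identically.
#'
#' @param model a `gbrt_model`.
#' @param path JSON file path.
#' @return `read_gbrt_model`: a `gbrt_model`.
#' @export
write_gbrt_model <- function(model, path) {
  obj <- unclass(model)
  obj$trees <- lapply(obj$trees, tree_to_list)
  obj$importance <- as.list(obj$importance)
  # I(17) significant digits: doubles reload bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_gbrt_model
#' @export
read_gbrt_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- list(
    trees = lapply(obj$trees, list_to_tree),
    base_score = obj$base_score,
    learning_rate = obj$learning_rate,
    params = lapply(obj$params, function(v) v),
    feature_names = vapply(obj$feature_names, identity, character(1)),
    train_logloss = vapply(obj$train_logloss, as.numeric, numeric(1)),
    importance = unlist(lapply(obj$importance, as.numeric)),
    seed = as.integer(obj$seed))
  names(model$importance) <- names(obj$importance)
  structure(model, class = "gbrt_model")
}
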