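# ---- iterative random-forest top-k union feature selection

#' Partition samples into subject-grouped, class-stratified subsets
#'
#' All repetitions of one subject land in the same subset; subjects of each
#' class are spread across subsets as evenly as subject granularity allows.
#'
#' @param table a `feature_table` (labels and subject ids required).
#' @param k number of subsets (default 7).
#' @param seed integer seed.
#' @return list of `k` integer row-index vectors (disjoint, exhaustive).
#' @export
partition_subsets <- function(table, k = 7L, seed) {
  stopifnot(inherits(table, "feature_table"))
  subj <- unique(data.frame(subject_id = table$subject_id,
                            label = table$label))
  for (cl in unique(subj$label)) {
    if (sum(subj$label == cl) < k)
      stop("need at least ", k, " subjects per class; class ", cl,
           " has ", sum(subj$label == cl))
  }
  set.seed(seed %% .Machine$integer.max)
  assign <- character(0)
  groups <- rep(list(character(0)), k)
  for (cl in unique(subj$label)) {
    ids <- sample(subj$subject_id[subj$label == cl])
    for (i in seq_along(ids)) {
      g <- ((i - 1L) %% k) + 1L
      groups[[g]] <- c(groups[[g]], ids[i])
    }
  }
  lapply(groups, function(ids) which(table$subject_id %in% ids))
}

#' Rank all features by random-forest impurity importance
#'
#' Mean impurity-decrease importance of a single random-forest fit; ties
#' broken by column (canonical) order so the ranking is stable.
#'
#' @param subtable a labeled, fully observed `feature_table`.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return character vector: all feature names, most important first.
#' @export
rank_features <- function(subtable, n_trees, seed) {
  y <- subtable$label
  if (length(unique(y)) < 2) stop("subset contains a single class")
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  x <- feature_matrix(subtable)
  if (anyNA(x)) stop("rank_features needs an imputed (complete) table")
  fit <- ranger::ranger(x = x, y = factor(y), num.trees = n_trees,
                        importance = "impurity", seed = seed %% 2147483647L,
                        num.threads = 1L, classification = TRUE)
  imp <- fit$variable.importance
  ord <- order(-imp, seq_along(imp))
  colnames(x)[ord]
}

#' One subset's iterative top-k union selection
#'
#' Iteration `t` fits a forest with `tree_schedule(t)` trees, takes its top
#' `top_k` features and unions them into the running set; iteration stops
#' once the set has not grown for `patience` consecutive iterations, or at
#' `max_iter`.
#'
#' @param subtable a labeled, fully observed `feature_table`.
#' @param top_k features taken per iteration (default 25).
#' @param tree_schedule function of the iteration index giving the tree
#'   count (default `50 + 25 t`).
#' @param patience consecutive no-growth iterations before stopping.
#' @param max_iter hard iteration cap.
#' @param seed integer seed.
#' @return list with `features` (selected set, in first-seen order) and
#'   `trace` (set size after each iteration; non-decreasing).
#' @export
select_on_subset <- function(subtable, top_k = 25L,
                             tree_schedule = function(t) 50L + 25L * t,
                             patience = 5L, max_iter = 100L, seed) {
  selected <- character(0)
  trace <- integer(0)
  stall <- 0L
  for (t in seq_len(max_iter)) {
    rk <- rank_features(subtable, n_trees = tree_schedule(t),
                        seed = seed + 131L * t)
    top <- head(rk, top_k)
    new_selected <- union(selected, top)
    if (length(new_selected) == length(selected)) stall <- stall + 1L
    else stall <- 0L
    selected <- new_selected
    trace <- c(trace, length(selected))
    if (stall >= patience) break
  }
  list(features = selected, trace = trace)
}

#' Iterative random-forest union feature selection over grouped subsets
#'
#' Partitions the table into `k` subject-grouped subsets, runs the iterative
#' top-k union selection on each, and merges the per-subset sets into the
#' final feature set.
#'
#' @param table a labeled, fully observed `feature_table`.
#' @param k number of subsets (default 7).
#' @param top_k,tree_schedule,patience,max_iter per-subset selection
#'   controls, see [select_on_subset()].
#' @param seed integer seed.
#' @return an object of class `selection_result`: `subsets` (row-index
#'   sets), `per_subset_features`, `traces`, `final_features` (the union,
#'   canonical order), `seed`.
#' @export
rf_union_select <- function(table, k = 7L, top_k = 25L,
                            tree_schedule = function(t) 50L + 25L * t,
                            patience = 5L, max_iter = 100L, seed) {
  subsets <- partition_subsets(table, k = k, seed = seed)
  runs <- lapply(seq_along(subsets), function(i) {
    sub <- table[subsets[[i]], , drop = FALSE]
    select_on_subset(sub, top_k = top_k, tree_schedule = tree_schedule,
                     patience = patience, max_iter = max_iter,
                     seed = seed + 7001L * i)
  })
  per_set <- lapply(runs, `[[`, "features")
  final <- Reduce(union, per_set)
  fc <- feature_cols(table)
  final <- fc[fc %in% final]   # canonical order
  structure(list(subsets = subsets,
                 per_subset_features = per_set,
                 traces = lapply(runs, `[[`, "trace"),
                 final_features = final,
                 seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d subsets, %s iterations, %d features selected\n",
              length(x$subsets),
              paste(lengths(x$traces), collapse = "/"),
              length(x$final_features)))
  invisible(x)
}

#' Serialize / deserialize a selection result as JSON
#' @param sel a `selection_result`.
#' @param path JSON file path.
#' @return `read_selection`: a `selection_result`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$subsets <- lapply(obj$subsets, as.integer)
  obj$traces <- lapply(obj$traces, as.integer)
  obj$per_subset_features <- lapply(obj$per_subset_features, as.character)
  structure(obj, class = "selection_result")
}
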