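# ---- end-to-end pipeline: simulate -> extract -> select -> train -> evaluate

#' Assemble a validated pipeline configuration
#'
#' A single global seed expands to per-stage seeds by fixed offsets
#' (simulation +0, split +1000, selection +2000, model +3000, CV +4000), so
#' any stage can be re-run independently yet reproducibly.
#'
#' @param out_dir directory for stage artifacts.
#' @param sim list of [simulation_config()] arguments (without `seed`).
#' @param select_args list of [rf_union_select()] arguments.
#' @param gbrt_args list of [gbrt_fit()] arguments.
#' @param cv_k folds for the cross-validation stage.
#' @param ratios train/validation/test subject proportions.
#' @param seed mandatory global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim, select_args = list(),
                            gbrt_args = list(), cv_k = 5L,
                            ratios = c(16, 4, 5), seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  sim_cfg <- do.call(simulation_config, c(sim, list(seed = seed)))
  structure(list(out_dir = out_dir, sim = sim_cfg,
                 select_args = select_args, gbrt_args = gbrt_args,
                 cv_k = as.integer(cv_k), ratios = ratios,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(...) message(sprintf(...))

#' Run the full pipeline
#'
#' Simulates a cohort, extracts the 2949-feature table, imputes missing
#' cells, makes the subject-grouped 16:4:5 split, selects features on the
#' training stratum, fits the boosted-trees classifier, tunes the tree count
#' on validation AUC, evaluates on the test stratum, and runs subject-grouped
#' k-fold cross-validation over the whole table. Artifacts written under
#' `config$out_dir`: `features.csv`, `selection.json`, `model.json`,
#' `metrics.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory artifacts (`table`,
#'   `selection`, `model`, `metrics`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  log_stage("simulate: %d CS + %d healthy subjects x %d reps (seed %d)",
            config$sim$n_cs, config$sim$n_healthy, config$sim$reps, seed)
  cohort <- simulate_cohort(config$sim)

  log_stage("extract: %d samples x 2949 features", length(cohort$samples))
  table <- extract_cohort(cohort$samples, cohort$missing_plan)
  write_feature_table(table, file.path(config$out_dir, "features.csv"))

  split <- split_grouped(table, config$ratios, seed = seed + 1000L)
  train <- impute_missing(table[split$train, , drop = FALSE], "class_mean")
  train_means <- colMeans(feature_matrix(train))
  val <- impute_missing(table[split$validation, , drop = FALSE],
                        "global_mean", means = train_means)
  test <- impute_missing(table[split$test, , drop = FALSE],
                         "global_mean", means = train_means)
  log_stage("split 16:4:5 (subject-grouped): %d/%d/%d rows",
            nrow(train), nrow(val), nrow(test))

  sel <- do.call(rf_union_select,
                 c(list(table = train, seed = seed + 2000L),
                   config$select_args))
  write_selection(sel, file.path(config$out_dir, "selection.json"))
  log_stage("select: %d features after %s iterations",
            length(sel$final_features),
            paste(lengths(sel$traces), collapse = "/"))

  keep <- c("subject_id", "label", "repetition", sel$final_features)
  train_sel <- feature_table(as.data.frame(train)[, keep], canonical = FALSE)
  val_sel <- feature_table(as.data.frame(val)[, keep], canonical = FALSE)
  test_sel <- feature_table(as.data.frame(test)[, keep], canonical = FALSE)
  model <- do.call(gbrt_fit, c(list(table = train_sel, seed = seed + 3000L),
                               config$gbrt_args))
  tuned <- gbrt_tune_trees(model, val_sel)
  log_stage("train: %d trees fitted; validation AUC %.3f at %d trees",
            length(model$trees), tuned$auc, tuned$n_trees)
  write_gbrt_model(model, file.path(config$out_dir, "model.json"))

  scores <- gbrt_predict_score(model, test_sel, n_trees = tuned$n_trees)
  labels <- as.integer(plogis(scores) >= 0.5)
  test_metrics <- metrics_from_counts(confusion(test_sel$label, labels))
  test_metrics$auc <- roc_auc(scores, test_sel$label)
  test_metrics$n_trees <- tuned$n_trees

  cv <- cross_validate(table, k = config$cv_k, seed = seed + 4000L,
                       select = TRUE, select_args = config$select_args,
                       gbrt_args = config$gbrt_args)
  log_stage("evaluate: test accuracy %.2f%%, CV mean AUC %.3f",
            100 * test_metrics$accuracy, cv$mean$auc)

  metrics <- list(test = test_metrics, cv_folds = cv$folds, cv_mean = cv$mean,
                  n_selected = length(sel$final_features), seed = seed)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(table = table, selection = sel, model = model,
                 metrics = metrics))
}
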