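make_tab <- function(X, y) {
  df <- data.frame(subject_id = sprintf("s%02d", seq_along(y)),
                   label = y, repetition = 1L)
  feature_table(cbind(df, as.data.frame(X)), canonical = FALSE)
}

test_that("stumps learn separable data and match the exhaustive split oracle", {
  set.seed(1)
  y <- rep(c(0L, 1L), each = 10)
  X <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1,
              dimnames = list(NULL, "x1"))
  tab <- make_tab(X, y)
  m <- gbrt_fit(tab, n_trees = 50, max_depth = 1)
  expect_equal(mean(gbrt_predict_label(m, tab) == y), 1)

  # single stump vs brute-force best-gain search on random tables
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:50, 1)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    tab <- make_tab(X, y)
    m1 <- gbrt_fit(tab, n_trees = 1, learning_rate = 1, max_depth = 1,
                   reg_lambda = 0, gamma = 0)
    p0 <- mean(y)
    sc0 <- qlogis(min(max(p0, 1e-6), 1 - 1e-6))
    p <- plogis(rep(sc0, n))
    oracle <- stump_oracle(X, p - y, p * (1 - p), lambda = 0, gamma = 0)
    root <- m1$trees[[1]]
    if (is.na(oracle$feature)) {
      expect_true(isTRUE(root$leaf))
    } else {
      expect_equal(colnames(X)[root$feature], colnames(X)[oracle$feature])
      expect_equal(root$threshold, oracle$threshold)
      expect_equal(root$gain, oracle$gain, tolerance = 1e-10)
    }
  }
})

test_that("XOR needs depth 2 and is unlearnable with stumps", {
  # exact two-valued features: a depth-1 ensemble is an additive model
  # f(a) + g(b), which cannot represent XOR; cell counts are slightly
  # unbalanced so the greedy root split has positive gain
  cells <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  reps <- c(12, 10, 10, 8)
  X <- cells[rep(1:4, reps), 1:2, drop = FALSE]
  colnames(X) <- c("a", "b")
  y <- cells[rep(1:4, reps), 3]
  tab <- make_tab(X, as.integer(y))
  deep <- gbrt_fit(tab, n_trees = 200, max_depth = 2, learning_rate = 0.3)
  expect_equal(mean(gbrt_predict_label(deep, tab) == y), 1)
  shallow <- gbrt_fit(tab, n_trees = 200, max_depth = 1, learning_rate = 0.3)
  # additive ceiling: at most 3 of the 4 XOR cells can be classified
  expect_lte(mean(gbrt_predict_label(shallow, tab) == y), 0.85)
})

test_that("vanishing learning rate leaves the prevalence log-odds", {
  set.seed(3)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
  y <- rbinom(30, 1, 0.4); y[1:2] <- c(0L, 1L)
  tab <- make_tab(X, y)
  m <- gbrt_fit(tab, n_trees = 1, learning_rate = 1e-9)
  expect_equal(gbrt_predict_score(m, tab), rep(qlogis(mean(y)), 30),
               tolerance = 1e-6)
  # probabilities strictly inside (0, 1)
  m2 <- gbrt_fit(tab, n_trees = 200, learning_rate = 0.5)
  pr <- gbrt_predict_proba(m2, tab)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("training log-loss is non-increasing stage by stage", {
  set.seed(4)
  tab <- noise_table(20, 10, reps = 2, seed = 4, informative = 1, shift = 1)
  m <- gbrt_fit(tab, n_trees = 120, learning_rate = 0.1, gamma = 0)
  expect_true(all(diff(m$train_logloss) <= 1e-9))
  staged <- gbrt_staged_scores(m, tab)
  expect_equal(ncol(staged), 120)
  expect_equal(staged[, 120], gbrt_predict_score(m, tab))
  expect_equal(staged[, 17], gbrt_predict_score(m, tab, n_trees = 17))
})

test_that("a hand-built stump predicts base + lr * leaf", {
  model <- structure(list(
    trees = list(list(leaf = FALSE, feature = 1L, threshold = 0.5, gain = 1,
                      left = list(leaf = TRUE, weight = -2),
                      right = list(leaf = TRUE, weight = 3))),
    base_score = 0.7, learning_rate = 0.1,
    params = list(max_depth = 1L, min_leaf = 1L, reg_lambda = 1, gamma = 0),
    feature_names = "x", train_logloss = 0.6,
    importance = c(x = 1), seed = 1L), class = "gbrt_model")
  X <- matrix(c(0.2, 0.9), 2, 1, dimnames = list(NULL, "x"))
  expect_equal(gbrt_predict_score(model, X), c(0.7 - 0.2, 0.7 + 0.3))
  expect_equal(gbrt_predict_proba(model, X), plogis(c(0.5, 1.0)))
  # empty ensemble falls back to the base score
  model$trees <- list()
  expect_equal(gbrt_predict_proba(model, X), rep(plogis(0.7), 2))
  expect_error(gbrt_predict_score(model,
                                  matrix(1, 1, 1, dimnames = list(NULL, "z"))),
               "missing referenced feature")
})

test_that("models serialize to JSON and reload bit-identically", {
  set.seed(5)
  tab <- noise_table(16, 6, reps = 2, seed = 5, informative = 1)
  m <- gbrt_fit(tab, n_trees = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_gbrt_model(m, path)
  m2 <- read_gbrt_model(path)
  expect_identical(gbrt_predict_score(m2, tab), gbrt_predict_score(m, tab))
  expect_identical(m2$feature_names, m$feature_names)
  # deterministic refit
  m3 <- gbrt_fit(tab, n_trees = 30)
  expect_identical(gbrt_predict_score(m3, tab), gbrt_predict_score(m, tab))
})
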