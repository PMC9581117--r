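test_that("stratified folds partition the target with balanced classes", {
  labels <- rep(c("a", "b"), each = 25)
  fold <- stratified_folds(labels, n_folds = 5, seed = 1)
  expect_setequal(unique(fold), 1:5)
  for (k in 1:5) {
    expect_equal(sum(fold == k & labels == "a"), 5)
    expect_equal(sum(fold == k & labels == "b"), 5)
  }
  # uneven class sizes: per-class counts differ by at most one across folds
  labels2 <- c(rep("a", 23), rep("b", 11))
  fold2 <- stratified_folds(labels2, n_folds = 4, seed = 2)
  for (cl in c("a", "b")) {
    counts <- table(fold2[labels2 == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_equal(length(fold2), 34)
  # deterministic under seed
  expect_identical(fold, stratified_folds(labels, 5, seed = 1))
  expect_false(identical(fold, stratified_folds(labels, 5, seed = 99)))
  expect_error(stratified_folds(c("a", "a", "b"), n_folds = 3), "smaller")
})

test_that("metrics reproduce hand-computed confusion values", {
  # TP=3, FP=1, FN=1, TN=5 for the positive class
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c(rep("pos", 3), "neg", "pos", rep("neg", 5))
  m <- compute_metrics(truth, pred, c("neg", "pos"))
  expect_equal(m$accuracy, 80)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 75)
  expect_equal(pos$recall, 75)
  expect_equal(pos$f1, 75)
  # perfect predictions
  p <- compute_metrics(truth, truth, c("neg", "pos"))
  expect_equal(unlist(p[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 100, precision = 100, recall = 100, f1 = 100))
  # constant predictor on 3 classes recalls exactly one class
  t3 <- rep(c("x", "y", "z"), times = c(5, 3, 2))
  m3 <- compute_metrics(t3, rep("x", 10), c("x", "y", "z"))
  expect_equal(m3$recall, 100 / 3)
  expect_error(compute_metrics(t3, rep("q", 10), c("x", "y", "z")), "q")
  expect_error(compute_metrics(t3, t3[1:5], c("x", "y", "z")), "length")
})

test_that("metrics agree with the confusion-table oracle", {
  set.seed(123)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    cm <- random_confusion(k)
    lv <- labels_from_confusion(cm)
    got <- compute_metrics(lv$truth, lv$pred, rownames(cm))
    want <- oracle_metrics_from_confusion(cm)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
    }
  }
})

tiny_plan <- function(methods, protocol = "holdout", n_seeds = 2) {
  experiment_plan(methods = methods, protocol = protocol, n_seeds = n_seeds,
                  config = trgb_config(n_iterations = 10))
}

tiny_scenario <- scenario_spec(
  n_features = 5, n_informative = 3, n_source_per_class = 25,
  n_target_labeled_per_class = 10, n_target_test_per_class = 15)

test_that("experiments are deterministic and reject unknown methods", {
  s1 <- run_experiment(tiny_plan(c("trgb", "target_only")), tiny_scenario)
  s2 <- run_experiment(tiny_plan(c("trgb", "target_only")), tiny_scenario)
  expect_identical(s1$summary, s2$summary)
  expect_setequal(unique(s1$detail$method), c("trgb", "target_only"))
  expect_true(all(s1$summary$mean >= 0 & s1$summary$mean <= 100))
  expect_error(experiment_plan(methods = c("trgb", "svm")), "unknown")
})

test_that("cross-validation shares identical folds across methods", {
  sc <- scenario_spec(n_features = 5, n_informative = 3,
                      n_source_per_class = 20,
                      n_target_labeled_per_class = 15,
                      n_target_test_per_class = 5)
  st <- run_experiment(tiny_plan(c("trgb", "pooled"), protocol = "cv"), sc)
  by_rep <- split(st$detail, list(st$detail$replicate, st$detail$fold))
  for (chunk in by_rep) {
    expect_equal(length(unique(chunk$fold_fingerprint)), 1)
  }
  # every fold of every replicate scored for every method
  expect_equal(nrow(st$detail), 2 * 5 * 2)
})

test_that("multiclass experiments run through the one-vs-rest path", {
  sc3 <- scenario_spec(n_features = 5, n_informative = 3,
                       class_labels = c("CN", "MCI", "AD"),
                       class_separation = 3,
                       n_source_per_class = 20,
                       n_target_labeled_per_class = 10,
                       n_target_test_per_class = 10)
  st <- run_experiment(tiny_plan(c("trgb", "target_only"), n_seeds = 1), sc3)
  expect_true(all(is.finite(st$summary$mean)))
  expect_equal(sort(unique(st$detail$method)), c("target_only", "trgb"))
})

test_that("score tables export to CSV, JSON, JSON-lines and a figure", {
  st <- run_experiment(tiny_plan(c("trgb", "target_only"), n_seeds = 1),
                       tiny_scenario)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_score_table(st, csv, js, jl)
  back <- utils::read.csv(csv)
  expect_setequal(unique(back$metric),
                  c("accuracy", "precision", "recall", "f1"))
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
  expect_equal(length(readLines(jl)), nrow(st$detail))
  fig <- plot_score_table(st)
  expect_s3_class(fig, "ggplot")
  expect_equal(sort(names(score_means(st))), c("target_only", "trgb"))
})
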