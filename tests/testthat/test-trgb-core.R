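test_that("the initial score is the log-odds minimizer of the deviance", {
  expect_equal(initialize_score(c(0, 1, 0, 1)), 0)
  expect_equal(initialize_score(c(1, 1, 1, 0)), log(3))
  # brute-force oracle: grid search of the summed deviance over gamma
  y <- c(1, 1, 1, 0)
  grid <- seq(-4, 4, by = 1e-4)
  loss <- vapply(grid, function(g) {
    p <- 1 / (1 + exp(-g))
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  expect_equal(initialize_score(y), grid[which.min(loss)], tolerance = 1e-3)
  expect_error(initialize_score(c(1, 1, 1, 1)), "one class")
  expect_error(initialize_score(numeric(0)), "empty")
})

test_that("pseudo-residuals are y - p with magnitudes at most 1", {
  expect_equal(pseudo_residuals(1, 0.7), 0.3)
  expect_equal(pseudo_residuals(0, 0.7), -0.7)
  expect_error(pseudo_residuals(c(1, 0), 0.5), "length")
  set.seed(11)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.5)
    p <- runif(50, 1e-6, 1 - 1e-6)
    expect_true(all(abs(pseudo_residuals(y, p)) <= 1))
  }
})

test_that("scoring is incremental: T iterations = T-1 iterations + one tree", {
  df <- make_logistic_fixture(n = 120)
  fit <- trgb(NULL, df, config = fast_config())
  x <- df[sample(nrow(df), 30), ]
  # zero iterations returns the initial score everywhere
  expect_equal(predict(fit, x, type = "link", n_iterations = 0),
               rep(fit$init_score, 30))
  for (k in seq_along(fit$iterations)) {
    contrib <- fit$config$learning_rate *
      trgb:::predict_tree_nodes(fit$iterations[[k]]$nodes,
                                trgb:::newdata_matrix(fit, x))
    expect_equal(predict(fit, x, type = "link", n_iterations = k),
                 predict(fit, x, type = "link", n_iterations = k - 1) + contrib)
  }
})

test_that("probabilities are proper: in (0,1), complements summing to 1", {
  df <- make_logistic_fixture(n = 100)
  fit <- trgb(NULL, df, config = fast_config())
  pm <- predict(fit, df, type = "prob")
  expect_true(all(pm > 0 & pm < 1))
  expect_equal(rowSums(pm), rep(1, nrow(df)))
  expect_identical(colnames(pm), c("a", "b"))
})

test_that("sigmoid of score 0 is 0.5 and extreme scores stay clamped", {
  expect_equal(trgb:::sigmoid(0), 0.5)
  expect_lte(trgb:::clamp_prob(trgb:::sigmoid(1e4)), 1 - 1e-12)
  expect_gte(trgb:::clamp_prob(trgb:::sigmoid(-1e4)), 1e-12)
})

test_that("label swap retrains to the complementary probabilities", {
  df <- make_logistic_fixture(n = 150)
  flipped <- df
  flipped$label <- factor(ifelse(df$label == "a", "b", "a"), levels = c("a", "b"))
  f1 <- trgb(NULL, df, config = fast_config())
  f2 <- trgb(NULL, flipped, config = fast_config())
  p1 <- predict(f1, df, type = "prob")[, "b"]
  p2 <- predict(f2, df, type = "prob")[, "b"]
  expect_equal(p1, 1 - p2, tolerance = 1e-12)
})

test_that("fits are deterministic and invariant to instance order", {
  pair <- generate_domain_pair(transfer_scenario(
    seed = 7, n_features = 8, n_informative = 4,
    n_source_per_class = 40, n_target_labeled_per_class = 10,
    n_target_test_per_class = 25))
  f1 <- trgb(pair$source, pair$target_labeled, config = fast_config())
  f2 <- trgb(pair$source, pair$target_labeled, config = fast_config())
  expect_equal(predict(f1, pair$target_test, type = "link"),
               predict(f2, pair$target_test, type = "link"))
  perm_src <- pair$source[sample(nrow(pair$source)), ]
  perm_tgt <- pair$target_labeled[sample(nrow(pair$target_labeled)), ]
  f3 <- trgb(perm_src, perm_tgt, config = fast_config())
  expect_equal(predict(f1, pair$target_test, type = "link"),
               predict(f3, pair$target_test, type = "link"), tolerance = 1e-12)
})

test_that("a target-only fit separates separable blobs within 50 iterations", {
  df <- make_blobs(n_per_class = 25, sep = 4, seed = 2)
  fit <- trgb(NULL, df, config = trgb_config(n_iterations = 50))
  expect_equal(mean(predict(fit, df, type = "class") == df$label), 1)
})

test_that("with an empty source every boosting weight stays at 1", {
  df <- make_logistic_fixture(n = 80)
  fit <- trgb(NULL, df, config = fast_config())
  for (it in fit$iterations) {
    expect_equal(it$weights, rep(1, nrow(df)))
  }
})

test_that("with a source present, weights move and stay positive and clipped", {
  pair <- generate_domain_pair(transfer_scenario(
    seed = 3, n_features = 8, n_informative = 4,
    n_source_per_class = 40, n_target_labeled_per_class = 10,
    n_target_test_per_class = 10))
  cfg <- trgb_config(n_iterations = 25, weight_ceiling = 4)
  fit <- trgb(pair$source, pair$target_labeled, config = cfg)
  last <- fit$iterations[[25]]
  expect_true(all(last$weights > 0))
  expect_true(all(last$weights <= 4))
  expect_true(sd(last$weights) > 0) # the update is actually active
  expect_true(all(last$residual_magnitudes >= 0 & last$residual_magnitudes <= 1))
  # the recorded target summary is recomputable from the history
  n_src <- nrow(pair$source)
  expect_equal(last$target_avg_residual,
               mean(last$residual_magnitudes[-seq_len(n_src)]))
})

test_that("degenerate inputs are refused with diagnostics", {
  df <- make_logistic_fixture(n = 40)
  single <- df[df$label == "a", ]
  expect_error(trgb(NULL, single, config = fast_config()), "single class")
  expect_error(trgb(NULL, df[0, ], config = fast_config()), "empty")
  src <- df
  src$label <- factor("c")
  expect_error(trgb(src, df, config = fast_config()), "label space")
  fit <- trgb(NULL, df, config = fast_config())
  expect_error(predict(fit, df[, 1:3]), "lacks feature columns")
  expect_error(predict(fit, as.matrix(df[, 1:3])), "features")
})

test_that("early stopping respects the loss tolerance", {
  df <- make_blobs(n_per_class = 25, sep = 5, seed = 4)
  fit <- trgb(NULL, df, config = trgb_config(n_iterations = 200,
                                             loss_tolerance = 0.1))
  expect_lt(length(fit$iterations), 200)
  expect_lt(fit$iterations[[length(fit$iterations)]]$train_loss, 0.1)
})

test_that("models survive a JSON round trip", {
  pair <- generate_domain_pair(transfer_scenario(
    seed = 5, n_features = 6, n_informative = 3,
    n_source_per_class = 30, n_target_labeled_per_class = 10,
    n_target_test_per_class = 20))
  fit <- trgb(pair$source, pair$target_labeled, config = fast_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_trgb(fit, path)
  fit2 <- read_trgb(path)
  expect_equal(predict(fit2, pair$target_test, type = "link"),
               predict(fit, pair$target_test, type = "link"),
               tolerance = 1e-12)
  expect_identical(fit2$label_levels, fit$label_levels)
  expect_equal(fit2$config$learning_rate, fit$config$learning_rate)
  # multiclass document
  df3 <- make_blobs3(n_per_class = 20)
  m3 <- trgb_multiclass(NULL, df3, config = fast_config())
  path3 <- withr::local_tempfile(fileext = ".json")
  write_trgb(m3, path3)
  m3b <- read_trgb(path3)
  expect_equal(predict(m3b, df3, type = "prob"),
               predict(m3, df3, type = "prob"), tolerance = 1e-12)
  # wrong document type is refused
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), bad, auto_unbox = TRUE)
  expect_error(read_trgb(bad), "format")
})

test_that("the training log reports one diagnostic row per iteration", {
  pair <- generate_domain_pair(transfer_scenario(
    seed = 9, n_features = 6, n_informative = 3,
    n_source_per_class = 30, n_target_labeled_per_class = 10,
    n_target_test_per_class = 10))
  fit <- trgb(pair$source, pair$target_labeled, config = fast_config())
  log <- training_log(fit)
  expect_equal(nrow(log), 15)
  expect_true(all(c("lambda", "source_w_median", "target_w_max",
                    "train_loss") %in% colnames(log)))
  expect_true(all(is.finite(log$lambda)))
})
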