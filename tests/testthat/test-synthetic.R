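small_spec <- function(...) {
  args <- list(n_features = 6, n_informative = 3,
               n_source_per_class = 25, n_target_labeled_per_class = 8,
               n_target_test_per_class = 12)
  args[names(list(...))] <- list(...)
  do.call(scenario_spec, args)
}

test_that("per-class counts exactly match the spec, with and without priors", {
  pair <- generate_domain_pair(small_spec(seed = 1))
  expect_equal(unname(table(pair$source$label)), c(25L, 25L),
               ignore_attr = TRUE)
  expect_equal(unname(table(pair$target_labeled$label)), c(8L, 8L),
               ignore_attr = TRUE)
  expect_equal(unname(table(pair$target_test$label)), c(12L, 12L),
               ignore_attr = TRUE)
  # imbalanced priors: largest-remainder counts, exact totals
  pair2 <- generate_domain_pair(small_spec(
    seed = 2, class_priors_source = c(0.7, 0.3),
    class_priors_target = c(0.25, 0.75)))
  expect_equal(as.integer(table(pair2$source$label)), c(35L, 15L))
  expect_equal(sum(table(pair2$target_labeled$label)), 16L)
  expect_equal(as.integer(table(pair2$target_test$label)), c(6L, 18L))
})

test_that("generation is a deterministic function of the spec", {
  p1 <- generate_domain_pair(small_spec(seed = 10))
  p2 <- generate_domain_pair(small_spec(seed = 10))
  expect_identical(p1$source, p2$source)
  expect_identical(p1$target_test, p2$target_test)
  p3 <- generate_domain_pair(small_spec(seed = 11))
  expect_false(identical(p1$source$f1, p3$source$f1))
})

test_that("empirical priors and class means recover the generative truth", {
  sp <- scenario_spec(n_features = 4, n_informative = 2,
                      n_source_per_class = 5000,
                      n_target_labeled_per_class = 5000,
                      n_target_test_per_class = 10,
                      class_priors_source = c(0.35, 0.65),
                      covariate_shift = 0.4, seed = 3)
  pair <- generate_domain_pair(sp)
  emp_prior <- as.numeric(table(pair$source$label)) / nrow(pair$source)
  expect_equal(emp_prior, c(0.35, 0.65), tolerance = 0.02)
  # per-class per-domain feature means within 3 standard errors
  for (k in 1:2) {
    for (part in c("source", "target_labeled")) {
      d <- pair[[part]]
      d <- d[as.integer(d$label) == k, paste0("f", 1:4)]
      truth <- if (part == "source") pair$truth$means_source[k, ]
               else pair$truth$means_target[k, ]
      se <- 1 / sqrt(nrow(d))
      expect_true(all(abs(colMeans(d) - truth) < 3 * se),
                  info = paste(part, "class", k))
    }
  }
})

test_that("a fully flipped source teaches the inverted boundary", {
  sp <- scenario_spec(n_features = 6, n_informative = 3,
                      concept_shift_fraction = 1,
                      n_source_per_class = 100,
                      n_target_labeled_per_class = 10,
                      n_target_test_per_class = 100, seed = 5)
  pair <- generate_domain_pair(sp)
  fit <- fit_baseline("source_only", pair$source, NULL,
                      config = trgb_config(n_iterations = 30))
  acc <- mean(predict(fit, pair$target_test, type = "class") ==
                pair$target_test$label)
  expect_lt(acc, 0.5) # systematically anti-predictive
})

test_that("partial concept shift relabels the requested fraction", {
  sp <- small_spec(seed = 6, concept_shift_fraction = 0.4)
  pair <- generate_domain_pair(sp)
  clean <- generate_domain_pair(small_spec(seed = 6))
  # same draws, only labels may differ; roughly the shifted fraction in the
  # half-space far from the boundary actually flips
  expect_identical(pair$source$f1, clean$source$f1)
  frac_changed <- mean(pair$source$label != clean$source$label)
  expect_gt(frac_changed, 0.15)
  expect_lte(frac_changed, 0.4)
})

test_that("the cross-label scenario separates source extremes more than target stages", {
  pair <- make_emci_lmci_scenario(cross_label_scenario(seed = 2))
  expect_identical(levels(pair$target_labeled$label), c("EMCI", "LMCI"))
  expect_identical(levels(pair$source$label), c("CN", "AD"))
  expect_identical(unname(pair$label_map), c("EMCI", "LMCI"))
  b_src <- bayes_accuracy(pair, "source", n_mc = 20000)
  b_tgt <- bayes_accuracy(pair, "target", n_mc = 20000)
  expect_gt(b_src, b_tgt)
  # both class pairs sit on the same discriminative axis
  axis_src <- pair$truth$means_source[2, ] - pair$truth$means_source[1, ]
  axis_tgt <- pair$truth$means_target[2, ] - pair$truth$means_target[1, ]
  expect_gt(sum(axis_src * axis_tgt), 0)
})

test_that("zero target separation drives accuracy to chance", {
  pair <- make_emci_lmci_scenario(cross_label_scenario(
    seed = 4, target_separation = 0, n_features = 8, n_informative = 4,
    n_source_per_class = 50, n_target_labeled_per_class = 15,
    n_target_test_per_class = 200))
  src <- map_label_space(pair$source, pair$label_map)
  fit <- trgb(src, pair$target_labeled, config = trgb_config(n_iterations = 30))
  acc <- mean(predict(fit, pair$target_test, type = "class") ==
                pair$target_test$label)
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("invalid scenario fields are rejected by name", {
  expect_error(scenario_spec(concept_shift_fraction = 1.5),
               "concept_shift_fraction")
  expect_error(scenario_spec(class_priors_source = c(0.5, 0.2)),
               "class_priors_source")
  expect_error(scenario_spec(n_informative = 200), "n_informative")
  expect_error(scenario_spec(feature_covariance = -1), "feature_covariance")
  expect_error(scenario_spec(class_means = matrix(0, 3, 3)), "class_means")
})

test_that("demographic columns appear and carry signal only when asked", {
  sp_sig <- small_spec(seed = 7, demographic_block = TRUE,
                       n_source_per_class = 4000)
  pair <- generate_domain_pair(sp_sig)
  expect_true(all(c("age", "sex", "apoe4", "education") %in%
                    colnames(pair$source)))
  by_class <- tapply(pair$source$age, pair$source$label, mean)
  expect_gt(by_class[["AD"]] - by_class[["CN"]], 0.8) # ~1.6y gap, n=4000
  sp_null <- small_spec(seed = 7, demographic_block = TRUE,
                        demographic_signal = FALSE,
                        n_source_per_class = 4000)
  pair0 <- generate_domain_pair(sp_null)
  by_class0 <- tapply(pair0$source$age, pair0$source$label, mean)
  expect_lt(abs(by_class0[["AD"]] - by_class0[["CN"]]), 0.5)
})
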