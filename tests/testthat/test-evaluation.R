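test_that("balancing undersamples the majority class to equality", {
  d <- data.frame(outcome = c(rep(1, 10), rep(0, 90)), x = rnorm(100))
  b <- balance_classes(d, seed = 50)
  expect_equal(as.numeric(table(b$outcome)), c(10, 10))
  # already balanced input returned unchanged
  d2 <- data.frame(outcome = rep(c(0, 1), 5), x = 1:10)
  expect_identical(balance_classes(d2, seed = 50), d2)
  # determinism
  expect_identical(balance_classes(d, seed = 50), balance_classes(d, seed = 50))
  expect_error(balance_classes(data.frame(outcome = rep(1, 5))), "both classes")
})

test_that("the 8:2 split is stratified, disjoint, and ratio-preserving", {
  # 2 participants x 2 classes x 25 rows: groups divide evenly into 80/20
  d <- data.frame(participant_id = rep(c("A", "B"), each = 50),
                  outcome = rep(c(0, 1, 0, 1), each = 25),
                  x = rnorm(100))
  parts <- split_train_test(d, split_spec(seed = 51))
  expect_equal(nrow(parts$train_val), 80)
  expect_equal(nrow(parts$test_natural), 20)
  expect_length(intersect(parts$train_val$.row, parts$test_natural$.row), 0)
  expect_true(all(parts$test_balanced$.row %in% parts$test_natural$.row))
  # every participant still contributes to training
  expect_setequal(unique(parts$train_val$participant_id), c("A", "B"))

  # skewed cohort: natural test ratio equals the full-data ratio within
  # one row per class
  d3 <- data.frame(participant_id = rep(c("A", "B", "C"), each = 50),
                   outcome = rep(rep(c(1, 0), c(10, 40)), 3),
                   x = rnorm(150))
  p3 <- split_train_test(d3, split_spec(seed = 52))
  full_ratio <- mean(d3$outcome)
  nat <- p3$test_natural
  expect_lte(abs(sum(nat$outcome) - full_ratio * nrow(nat)), 1)
  expect_equal(as.numeric(table(p3$test_balanced$outcome)[1]),
               as.numeric(table(p3$test_balanced$outcome)[2]))

  expect_error(split_train_test(data.frame(participant_id = "A",
                                           outcome = rep(1, 10)),
                                split_spec()), "single class")
})

test_that("classification metrics follow their defining ratios", {
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0)
  pred  <- c(1, 1, 0, 1, 0, 0, 0, 0)
  m <- compute_metrics(pred, truth)
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$specificity, 4 / 5)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_score, 2 * (2/3) * (2/3) / (4/3))

  perfect <- compute_metrics(truth, truth)
  expect_true(all(unlist(perfect) == 1))

  # all-negative predictions: precision undefined, reported 0 with flag
  m0 <- compute_metrics(rep(0, 8), truth)
  expect_equal(m0$precision, 0)
  expect_true("undefined_precision" %in% attr(m0, "flags"))

  expect_error(compute_metrics(c(0, 1), c(0, 1, 1)), "equal length")

  # F is the harmonic-mean recombination of precision and recall
  expect_equal(f_score(m$precision, m$recall), m$f_score)
  expect_equal(f_score(0, 0), 0)
})

test_that("adjusted pseudo-R2 behaves at its boundary cases", {
  y <- rep(c(0, 1), 25)
  expect_equal(adjusted_r2(as.numeric(y), y, n_params = 1), 1)
  r_const <- adjusted_r2(rep(0.4, 50), y, n_params = 1)
  expect_equal(as.numeric(r_const), 0)
  expect_true("constant_fit" %in% attr(r_const, "flags"))
  # adjustment strictly decreases an imperfect raw value
  set.seed(53)
  p <- plogis(y + rnorm(50))
  raw <- cor(y, p)^2
  expect_lt(adjusted_r2(p, y, n_params = 3), raw)
  expect_true(is.na(adjusted_r2(p[1:3], y[1:3], n_params = 3)))
})

test_that("cross-validation partitions rows and averages fold metrics", {
  spec <- multilevel_sim_spec(5, 80, 2, gamma = c(0, 1.2, -0.8),
                              intercept_sd = 0.4, slope_sds = c(0.2, 0.2),
                              seed = 54)
  d <- generate_multilevel_features(spec)$data
  fold <- sibmlr:::assign_folds(d$outcome, 5, seed = 55)
  expect_setequal(unique(fold), 1:5)
  expect_length(fold, nrow(d))             # every row in exactly one fold
  # class-stratified up to rounding
  tab <- table(fold, d$outcome)
  expect_lte(max(tab[, "1"]) - min(tab[, "1"]), 1)

  cv <- cross_validate("decision_tree", d, c("X1", "X2"),
                       split_spec(cv_folds = 5, seed = 56))
  expect_equal(nrow(cv$folds), 5)
  expect_equal(unname(cv$mean["accuracy"]), mean(cv$folds$accuracy),
               tolerance = 1e-12)

  expect_error(cross_validate("decision_tree",
                              data.frame(participant_id = "A",
                                         outcome = c(rep(0, 50), rep(1, 3)),
                                         X1 = rnorm(53)),
                              "X1", split_spec(cv_folds = 10)),
               "minority")
})

test_that("the multilevel model dominates pooled LR under heterogeneity", {
  acc <- vapply(1:5, function(r) {
    spec <- multilevel_sim_spec(8, 120, 2, gamma = c(0, 0.8, -0.5),
                                intercept_sd = 1.2, slope_sds = c(0.8, 0.8),
                                seed = 600 + r)
    d <- generate_multilevel_features(spec)$data
    sp <- split_spec(cv_folds = 5, seed = 700 + r)
    c(cross_validate("mlr", d, c("X1", "X2"), sp)$mean["accuracy"],
      cross_validate("lr_plain", d, c("X1", "X2"), sp)$mean["accuracy"])
  }, numeric(2))
  expect_gte(mean(acc[1, ]), mean(acc[2, ]))
})
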