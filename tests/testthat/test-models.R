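test_that("with no between-participant variance the fit collapses to pooled", {
  spec <- multilevel_sim_spec(8, 250, 2, gamma = c(-0.4, 0.9, -0.6),
                              intercept_sd = 0, slope_sds = c(0, 0), seed = 40)
  sim <- generate_multilevel_features(spec)
  m <- fit_mlr(sim$data, c("X1", "X2"))
  pooled <- stats::glm(outcome ~ X1 + X2, binomial(), data = sim$data)
  ps <- summary(pooled)$coefficients
  # fixed estimates agree with the pooled oracle within 2 SEs
  expect_true(all(abs(m$gamma - coef(pooled)) <= 2 * ps[, 2]))
  # variance components collapse toward zero
  expect_lt(m$sd_alpha, 0.1)
  expect_true(all(m$sd_beta < 0.1))
})

test_that("planted multilevel parameters are recovered", {
  spec <- multilevel_sim_spec(20, 300, 1, gamma = c(-0.5, 1.0),
                              intercept_sd = 0.8, slope_sds = 0.5, seed = 41)
  sim <- generate_multilevel_features(spec)
  m <- fit_mlr(sim$data, "X1", se_variances = TRUE, test_variances = TRUE)
  fx <- m$summary$fixed
  expect_true(all(abs(fx$estimate - c(-0.5, 1.0)) <= 3 * fx$se))
  rd <- m$summary$random
  expect_true(all(abs(rd$sd - c(0.8, 0.5)) <= 3 * rd$se))
  # both variance components are clearly supported by the LRT
  expect_true(all(rd$p < 0.05))
  expect_true(all(rd$p >= 0 & rd$p <= 1))
  # realized participant effects are tracked by the posterior modes
  expect_gt(cor(m$participant_effects$alpha, sim$params$alpha), 0.8)
})

test_that("a single participant falls back to ordinary logistic regression", {
  spec <- multilevel_sim_spec(1, 300, 1, gamma = c(0, 1),
                              intercept_sd = 0, slope_sds = 0, seed = 42)
  sim <- generate_multilevel_features(spec)
  expect_warning(m <- fit_mlr(sim$data, "X1"), "single participant")
  expect_equal(m$type, "pooled")
  oracle <- stats::glm(outcome ~ X1, binomial(), data = sim$data)
  expect_equal(unname(m$gamma), unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(predict_mlr(m, sim$data),
               unname(predict(oracle, sim$data, type = "response")),
               tolerance = 1e-10)
})

test_that("prediction follows the inverse-logit algebra", {
  # hand-built model: intercept 1, zero slope, no random effects
  m <- structure(
    list(type = "multilevel", gamma = c("(Intercept)" = 1, S1 = 0),
         participant_effects = data.frame(participant_id = "A", alpha = 1,
                                          beta_S1 = 0,
                                          check.names = FALSE),
         score_cols = "S1", outcome_col = "outcome",
         id_col = "participant_id"),
    class = "mlr_model")
  names(m$participant_effects) <- c("participant_id", "alpha", "beta_S1")
  nd <- data.frame(S1 = rnorm(20), participant_id = "unseen")
  expect_equal(predict_mlr(m, nd), rep(plogis(1), 20))

  m0 <- m
  m0$gamma <- c("(Intercept)" = 0, S1 = 0)
  expect_equal(predict_mlr(m0, nd), rep(0.5, 20))

  # monotone in a score with positive total slope; unseen ids use gamma only
  m1 <- m
  m1$gamma <- c("(Intercept)" = 0.2, S1 = 1.5)
  s <- seq(-2, 2, length.out = 11)
  p <- predict_mlr(m1, data.frame(S1 = s, participant_id = "unseen"))
  expect_true(all(diff(p) > 0))
  expect_equal(p, plogis(0.2 + 1.5 * s))

  # known participants use their own effects
  m2 <- m
  m2$participant_effects$alpha <- 3
  p_known <- predict_mlr(m2, data.frame(S1 = 0, participant_id = "A"))
  expect_equal(p_known, plogis(3))
})

test_that("the multilevel fit nests the pooled fit in likelihood", {
  spec <- multilevel_sim_spec(10, 150, 2, gamma = c(0, 0.8, -0.5),
                              intercept_sd = 0.7, slope_sds = c(0.4, 0.4),
                              seed = 43)
  sim <- generate_multilevel_features(spec)
  m <- fit_mlr(sim$data, c("X1", "X2"))
  plain <- fit_comparison("lr_plain", sim$data, c("X1", "X2"))
  expect_gte(m$loglik, as.numeric(logLik(plain$fit)) - 1e-6)
})

test_that("recovery bias shrinks as windows per participant grow", {
  err <- function(W) {
    mean(vapply(1:5, function(r) {
      spec <- multilevel_sim_spec(15, W, 1, gamma = c(-0.5, 1.0),
                                  intercept_sd = 0.6, slope_sds = 0.4,
                                  seed = 400 + r)
      sim <- generate_multilevel_features(spec)
      m <- fit_mlr(sim$data, "X1")
      mean(abs(m$gamma - c(-0.5, 1.0)))
    }, numeric(1)))
  }
  expect_lt(err(480), err(60))
})

test_that("the comparison bank exposes one predict-probability interface", {
  spec <- multilevel_sim_spec(6, 120, 2, gamma = c(0, 1, -1),
                              intercept_sd = 0.5, slope_sds = c(0.3, 0.3),
                              seed = 44)
  d <- generate_multilevel_features(spec)$data
  train <- d[1:600, ]; hold <- d[601:720, ]
  for (kind in setdiff(COMPARISON_KINDS, "mlr")) {
    f <- fit_comparison(kind, train, c("X1", "X2"))
    p <- predict(f, hold)
    expect_length(p, 120)
    expect_true(all(p >= 0 & p <= 1), label = kind)
  }
  expect_error(fit_comparison("boosted_stump", train, c("X1", "X2")),
               "arg")
})

test_that("stepwise BIC selection finds a planted interaction", {
  set.seed(45)
  n <- 2000
  d <- data.frame(participant_id = "A",
                  X1 = rnorm(n), X2 = rnorm(n), X3 = rnorm(n))
  d$outcome <- rbinom(n, 1, plogis(1.5 * d$X1 * d$X2))
  f <- fit_comparison("lr_stepwise_bic", d, c("X1", "X2", "X3"))
  expect_true("X1:X2" %in% attr(terms(f$fit), "term.labels"))
})

test_that("degenerate classifiers behave as their definitions force", {
  # perfectly separated 1-D data: plain LR reaches training accuracy 1
  d <- data.frame(participant_id = "A", X1 = c(rnorm(50, -3), rnorm(50, 3)),
                  outcome = rep(c(0, 1), each = 50))
  f <- suppressWarnings(fit_comparison("lr_plain", d, "X1"))
  acc <- mean(as.integer(predict(f, d) >= 0.5) == d$outcome)
  expect_equal(acc, 1)
  expect_true("possible_separation" %in% attr(f$fit, "flags"))

  # 1-NN recalls its own training labels perfectly
  set.seed(46)
  d2 <- data.frame(participant_id = "A", X1 = rnorm(80), X2 = rnorm(80),
                   outcome = rbinom(80, 1, 0.5))
  f1 <- fit_comparison("knn", d2, c("X1", "X2"), k = 1)
  expect_equal(as.integer(predict(f1, d2) >= 0.5), d2$outcome)
})
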