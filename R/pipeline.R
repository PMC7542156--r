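#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis into one (serializable)
#' list. All randomness is derived from the single master `seed`.
#'
#' @param seed Master seed.
#' @param n_participants Synthetic cohort size (ignored when `data_dir` is
#'   given).
#' @param session_duration_s Session length in seconds per participant.
#' @param sampling_rate_hz Sampling rate (default 60).
#' @param data_dir Optional directory with an on-disk cohort (see
#'   [write_cohort()]); when given, the synthetic generator is skipped.
#' @param tau,M Embedding parameters for the nonlinear battery.
#' @param lasso_folds CV folds for the lasso penalty.
#' @param variance_target_pct Cumulative explained-variance target for the
#'   component count.
#' @param n_components Optional fixed component count override.
#' @param models Character vector of group-level model kinds to run.
#' @param train_val_fraction,cv_folds,balance_train Evaluation protocol
#'   (see [split_spec()]).
#' @param run_cv Run tenfold cross-validation per model (the validation
#'   table); disable for a quick train/test-only run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_participants = 6,
                            session_duration_s = 150,
                            sampling_rate_hz = 60,
                            data_dir = NULL,
                            tau = 5, M = 4,
                            lasso_folds = 10,
                            variance_target_pct = 65,
                            n_components = NULL,
                            models = setdiff(COMPARISON_KINDS, "lr_individual"),
                            train_val_fraction = 0.8,
                            cv_folds = 10,
                            balance_train = TRUE,
                            run_cv = TRUE) {
  structure(
    list(seed = as.integer(seed), n_participants = n_participants,
         session_duration_s = session_duration_s,
         sampling_rate_hz = sampling_rate_hz, data_dir = data_dir,
         tau = tau, M = M, lasso_folds = lasso_folds,
         variance_target_pct = variance_target_pct,
         n_components = n_components, models = models,
         train_val_fraction = train_val_fraction, cv_folds = cv_folds,
         balance_train = balance_train, run_cv = isTRUE(run_cv)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys are the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

## Default synthetic cohort: participants vary in burst frequency, amplitude,
## background activity, and episode process, all drawn from realistic ranges
## under a seed derived from the master seed.
default_cohort_spec <- function(config) {
  with_seed(derive_seed(config$seed, 11), {
    profiles <- lapply(seq_len(config$n_participants), function(i) {
      participant_profile(
        participant_id = sprintf("P%02d", i),
        sib_frequency_hz = stats::runif(1, 2, 5),
        sib_amplitude_g = stats::runif(1, 0.5, 1.2),
        baseline_activity_scale = stats::runif(1, 0.1, 0.25),
        episode_rate_per_min = stats::runif(1, 1.5, 3),
        episode_duration_range_s = c(2, 8))
    })
    cohort_spec(profiles, config$session_duration_s,
                config$sampling_rate_hz, seed = derive_seed(config$seed, 12))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, under one master seed: cohort generation (or loading), low-pass
#' filtering and 2-s/1-s windowing, extraction of the 96-feature battery,
#' lasso feature selection (the prompt indicator is included as a candidate),
#' PCA reduction of the selected features, the 8:2 participant-and-class
#' stratified split, tenfold cross-validation of every configured model kind,
#' and evaluation of each kind on the balanced and natural-ratio held-out
#' sets. Re-running with the same configuration reproduces the report
#' exactly.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return A `sib_report`: list with `validation` (per-model CV means,
#'   adjusted pseudo-R-squared, training time per observation), `test`
#'   (per-model metrics on balanced and natural test sets, prediction time
#'   per observation), `n_windows`, `feature_names`, `lasso`, `pca`,
#'   `config`, and `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(cohort = derive_seed(config$seed, 12),
                lasso = derive_seed(config$seed, 21),
                split = derive_seed(config$seed, 31))

  ## 1. data
  cohort <- if (!is.null(config$data_dir)) {
    read_cohort(config$data_dir)
  } else {
    generate_cohort(default_cohort_spec(config))
  }

  ## 2-3. windows + features
  wsets <- lapply(cohort, segment_windows)
  feats <- featurize_windows(wsets, embedding_params(config$tau, config$M))
  feature_names <- attr(feats, "feature_names")

  ## 4. lasso over the 96 features + the prompt indicator
  las <- lasso_select(feats, feature_names = c(feature_names, "prompt"),
                      outcome_col = "outcome", folds = config$lasso_folds,
                      seed = seeds$lasso)
  selected <- las$selected_names
  if (!length(selected)) {
    ## fully-shrunk path (can happen on tiny cohorts): fall back to lambda.min
    las <- lasso_select(feats, feature_names = c(feature_names, "prompt"),
                        outcome_col = "outcome", folds = config$lasso_folds,
                        seed = seeds$lasso, rule = "min")
    selected <- las$selected_names
  }

  ## 5. PCA on the selected features
  pca <- pca_fit(feats, selected,
                 variance_target_pct = config$variance_target_pct,
                 n_components = config$n_components)
  score_cols <- colnames(pca$loadings)
  scores <- data.frame(
    participant_id = feats$participant_id, outcome = feats$outcome,
    pca_transform(pca, feats), check.names = FALSE)

  ## 6. split + per-model CV and test evaluation
  spec <- split_spec(config$train_val_fraction, config$cv_folds,
                     config$balance_train, seed = seeds$split)
  parts <- split_train_test(scores, spec)
  train <- parts$train_val
  train_fit <- if (config$balance_train) {
    balance_classes(train, seed = derive_seed(seeds$split, 2))
  } else train

  validation <- NULL
  test <- NULL
  for (kind in config$models) {
    if (config$run_cv) {
      cv <- cross_validate(kind, train, score_cols, spec)
    }
    t_train <- system.time(
      fitted <- fit_comparison(kind, train_fit, score_cols))["elapsed"]
    if (config$run_cv) {
      probs_val <- predict(fitted, train)
      r2 <- adjusted_r2(probs_val, train$outcome, length(score_cols) + 1)
      validation <- rbind(validation, data.frame(
        model = kind, t(cv$mean),
        adjusted_r2 = if (kind %in% c("mlr", "lr_varying_intercept",
                                      "lr_plain", "lr_stepwise_bic")) {
          as.numeric(r2)
        } else NA_real_,
        train_time_per_obs_s = unname(t_train) / nrow(train_fit)))
    }
    for (tt in c("balanced", "natural")) {
      hold <- parts[[paste0("test_", tt)]]
      t_pred <- system.time(probs <- predict(fitted, hold))["elapsed"]
      m <- compute_metrics(as.integer(probs >= 0.5), hold$outcome)
      test <- rbind(test, data.frame(
        model = kind, test_type = tt, t(unlist(m)),
        predict_time_per_obs_s = unname(t_pred) / nrow(hold)))
    }
  }

  structure(
    list(validation = validation, test = test,
         n_windows = nrow(feats), feature_names = feature_names,
         lasso = las, pca = pca, config = config, seeds = seeds),
    class = "sib_report")
}

#' @export
print.sib_report <- function(x, ...) {
  cat(sprintf("<sib_report> %d windows, %d features -> %d selected -> %d components (%.1f%% variance)\n",
              x$n_windows, length(x$feature_names),
              length(x$lasso$selected_names), x$pca$n_components,
              sum(x$pca$explained_variance_pct[seq_len(x$pca$n_components)])))
  if (!is.null(x$validation)) {
    cat("\nValidation (tenfold CV means):\n")
    print(cbind(x$validation[, "model", drop = FALSE],
                round(x$validation[, c("accuracy", "specificity", "precision",
                                       "recall", "f_score", "adjusted_r2")], 3)),
          row.names = FALSE)
  }
  cat("\nHeld-out test:\n")
  print(cbind(x$test[, c("model", "test_type")],
              round(x$test[, c("accuracy", "specificity", "precision",
                               "recall", "f_score")], 3)),
        row.names = FALSE)
  invisible(x)
}

#' Export report tables as delimited text
#'
#' Writes the validation and test tables of a report as CSV files.
#'
#' @param report A `sib_report`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(report$validation)) {
    p <- file.path(dir, "validation.csv")
    utils::write.csv(report$validation, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "test.csv")
  utils::write.csv(report$test, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "selected_features.csv")
  utils::write.csv(data.frame(feature = report$lasso$selected_names,
                              coefficient = report$lasso$coefficients[report$lasso$selected_names]),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "pca_loadings.csv")
  utils::write.csv(data.frame(feature = rownames(report$pca$loadings),
                              report$pca$loadings, check.names = FALSE),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
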