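#' Train/test split specification
#'
#' @param train_val_fraction Fraction of rows for training/validation
#'   (default 0.8, the 8:2 protocol).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param balance_train Balance classes in training data by undersampling
#'   (default TRUE).
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_val_fraction = 0.8, cv_folds = 10,
                       balance_train = TRUE, seed = 1L) {
  if (train_val_fraction <= 0 || train_val_fraction >= 1) {
    stop("`train_val_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  structure(list(train_val_fraction = train_val_fraction,
                 cv_folds = as.integer(cv_folds),
                 balance_train = isTRUE(balance_train),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Balance classes by random undersampling
#'
#' Randomly undersamples the majority class to the minority-class count
#' (seeded). Already-balanced input is returned unchanged up to row order.
#'
#' @param data Data.frame with a binary outcome column.
#' @param outcome_col Outcome column name.
#' @param seed Integer seed.
#' @return A data.frame with equal class counts.
#' @export
balance_classes <- function(data, outcome_col = "outcome", seed = 1L) {
  y <- data[[outcome_col]]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to balance", call. = FALSE)
  }
  if (n1 == n0) return(data)
  maj <- if (n0 > n1) 0 else 1
  n_min <- min(n0, n1)
  keep_maj <- with_seed(seed, sample(which(y == maj), n_min))
  out <- data[sort(c(which(y != maj), keep_maj)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split rows into training and held-out test sets
#'
#' Performs the 8:2 split stratified by participant and class, so every
#' participant contributes to training (required for participant-level random
#' effects) and the held-out pool preserves the natural SIB:non-SIB ratio.
#' The held-out pool is materialized twice: as-is (`test_natural`) and
#' undersampled to class balance (`test_balanced`), both drawn from the same
#' pool. No row appears in both training and test.
#'
#' @param data Data.frame with outcome and participant columns.
#' @param spec A [split_spec()].
#' @param outcome_col,id_col Column names.
#' @return List with `train_val`, `test_balanced`, `test_natural`
#'   (data.frames with a `.row` column recording source row indices).
#' @export
split_train_test <- function(data, spec = split_spec(),
                             outcome_col = "outcome",
                             id_col = "participant_id") {
  y <- data[[outcome_col]]
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  data$.row <- seq_len(nrow(data))
  groups <- split(seq_len(nrow(data)),
                  list(data[[id_col]], y), drop = TRUE)
  test_idx <- with_seed(spec$seed, {
    unlist(lapply(groups, function(g) {
      n_test <- round(length(g) * (1 - spec$train_val_fraction))
      if (n_test == 0) return(integer(0))
      sample(g, n_test)
    }), use.names = FALSE)
  })
  train <- data[-test_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  counts <- table(factor(test[[outcome_col]], levels = c(0, 1)))
  if (any(counts == 0)) {
    stop(sprintf(
      "held-out pool lacks a class (test counts: %d non-SIB, %d SIB); use more data or a different fraction",
      counts[1], counts[2]), call. = FALSE)
  }
  rownames(train) <- rownames(test) <- NULL
  list(train_val = train,
       test_balanced = balance_classes(test, outcome_col,
                                       seed = derive_seed(spec$seed, 1)),
       test_natural = test)
}

#' F-score from precision and recall
#'
#' The harmonic-mean recombination `2 P R / (P + R)`, 0 when both are 0.
#' Useful for re-deriving F-scores from reported precision/recall pairs.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return Scalar F-score.
#' @export
f_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Classification metrics of binary predictions
#'
#' Accuracy, specificity, precision, recall, and F-score with the SIB class
#' (1) as positive. Ratios with a zero denominator are reported as 0 and the
#' result is flagged.
#'
#' @param predicted 0/1 vector of predicted labels.
#' @param truth 0/1 vector of true labels (same length).
#' @return An `eval_report`: named list of the five metrics.
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length", call. = FALSE)
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  flags <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "undefined_precision")
  recall <- safe(tp, tp + fn, "undefined_recall")
  if (precision + recall == 0) flags <- c(flags, "undefined_f_score")
  out <- structure(
    list(accuracy = (tp + tn) / length(truth),
         specificity = safe(tn, tn + fp, "undefined_specificity"),
         precision = precision,
         recall = recall,
         f_score = f_score(precision, recall)),
    class = "eval_report")
  if (length(flags)) out <- set_flag(out, flags)
  out
}

#' Adjusted pseudo-R-squared of a probabilistic classifier
#'
#' The squared Pearson correlation between the binary outcome and the fitted
#' probabilities, adjusted for model size:
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`. A constant fitted probability
#' yields 0 (flagged, no adjustment); fewer rows than parameters yields a
#' flagged NA.
#'
#' @param probs Fitted probabilities.
#' @param outcome 0/1 outcomes.
#' @param n_params Number of estimated parameters p.
#' @return Scalar adjusted pseudo-R-squared.
#' @export
adjusted_r2 <- function(probs, outcome, n_params) {
  n <- length(outcome)
  if (n <= n_params + 1) return(set_flag(NA_real_, "too_few_rows"))
  if (stats::sd(probs) == 0 || stats::sd(outcome) == 0) {
    return(set_flag(0, "constant_fit"))
  }
  r2 <- stats::cor(outcome, probs)^2
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

## Stratified fold assignment: within each class, rows are dealt to folds in
## a seeded random order, so each row is out-of-fold exactly once and folds
## are class-balanced up to rounding.
assign_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validate one classifier kind
#'
#' Stratified k-fold cross-validation (default tenfold): per fold, the
#' classifier is trained on the remaining folds (class-balanced first when
#' `spec$balance_train`), out-of-fold probabilities are thresholded at 0.5,
#' and the five classification metrics are computed. Returns per-fold metrics
#' and their mean.
#'
#' @param kind Classifier kind (see [fit_comparison()]).
#' @param data Training/validation data.
#' @param score_cols Predictor columns.
#' @param spec A [split_spec()]; `cv_folds` and `balance_train` are used.
#' @param outcome_col,id_col Column names.
#' @param k Passed to [fit_comparison()] for kNN.
#' @return List with `folds` (data.frame of per-fold metrics) and `mean`
#'   (named numeric vector).
#' @export
cross_validate <- function(kind, data, score_cols, spec = split_spec(),
                           outcome_col = "outcome",
                           id_col = "participant_id", k = 11) {
  y <- data[[outcome_col]]
  if (min(table(y)) < spec$cv_folds) {
    stop(sprintf("minority class (%d rows) smaller than fold count (%d)",
                 min(table(y)), spec$cv_folds), call. = FALSE)
  }
  fold <- assign_folds(y, spec$cv_folds, derive_seed(spec$seed, 7))
  per_fold <- lapply(seq_len(spec$cv_folds), function(f) {
    train <- data[fold != f, , drop = FALSE]
    hold <- data[fold == f, , drop = FALSE]
    if (spec$balance_train) {
      train <- balance_classes(train, outcome_col,
                               seed = derive_seed(spec$seed, 100 + f))
    }
    fitted <- fit_comparison(kind, train, score_cols, outcome_col, id_col, k = k)
    probs <- predict(fitted, hold)
    m <- compute_metrics(as.integer(probs >= 0.5), hold[[outcome_col]])
    unlist(m)
  })
  folds <- as.data.frame(do.call(rbind, per_fold))
  folds$fold <- seq_len(spec$cv_folds)
  list(folds = folds,
       mean = colMeans(folds[, c("accuracy", "specificity", "precision",
                                 "recall", "f_score")]))
}
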