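#' Lasso-based feature selection
#'
#' Fits an L1-penalized (binomial) logistic regression path over the feature
#' columns with [glmnet::cv.glmnet()] and keeps the features with nonzero
#' coefficients at the cross-validated penalty. The default penalty rule is
#' `"1se"` (largest lambda within one standard error of the minimum CV
#' deviance), which operationalizes "the sparsest model"; `"min"` is also
#' available, as is a fixed `lambda` override (with `lambda = 0` the fit
#' matches an unpenalized logistic regression).
#'
#' @param features Data.frame with an outcome column and numeric feature
#'   columns (features are standardized internally by glmnet).
#' @param feature_names Character vector of candidate columns (default: all
#'   numeric columns except `outcome_col` and the identifier columns).
#' @param outcome_col Name of the binary outcome column (default "outcome").
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the CV fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @param lambda Optional fixed penalty overriding cross-validation.
#' @return A `lasso_result`: list with `selected_names`, `coefficients`
#'   (named full vector at the chosen penalty, intercept first), `lambda`,
#'   and `cv_curve` (lambda/deviance/sd, NULL when `lambda` is fixed).
#' @export
lasso_select <- function(features, feature_names = NULL,
                         outcome_col = "outcome", folds = 10, seed = 1L,
                         rule = c("1se", "min"), lambda = NULL) {
  rule <- match.arg(rule)
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                             c(outcome_col, "start_s"))
  }
  y <- features[[outcome_col]]
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; lasso selection needs both", call. = FALSE)
  }
  X <- as.matrix(features[, feature_names, drop = FALSE])

  if (!is.null(lambda)) {
    ## descend the path to the requested lambda for a warm-started exact fit
    lam_seq <- sort(unique(c(exp(seq(log(max(abs(crossprod(scale(X), y - mean(y)))) /
                                           length(y) + 1e-6), log(1e-4), length.out = 50)),
                             lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lam_seq,
                          thresh = 1e-12)
    co <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y))
    cv_curve <- NULL
    lam <- lambda
  } else {
    cv <- with_seed(seed,
      glmnet::cv.glmnet(X, y, family = "binomial", nfolds = folds,
                        type.measure = "deviance"))
    lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    co <- as.numeric(stats::coef(cv, s = lam))
    cv_curve <- data.frame(lambda = cv$lambda, deviance = cv$cvm, sd = cv$cvsd)
  }
  names(co) <- c("(Intercept)", feature_names)
  selected <- feature_names[co[-1] != 0]
  structure(
    list(selected_names = selected, coefficients = co, lambda = lam,
         cv_curve = cv_curve),
    class = "lasso_result"
  )
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> %d features selected at lambda = %.4g\n",
              length(x$selected_names), x$lambda))
  invisible(x)
}

#' Fit a PCA on (selected) features
#'
#' Standardized-feature principal component analysis. The number of retained
#' components is the smallest count whose cumulative explained variance
#' reaches `variance_target_pct` (default 65%), unless a fixed
#' `n_components` is given. Zero-variance features are dropped with a
#' warning. Loadings carry a deterministic sign convention: each column is
#' flipped so its largest-magnitude entry is positive.
#'
#' @param features Data.frame containing the feature columns.
#' @param feature_names Columns to use.
#' @param variance_target_pct Cumulative explained-variance target (percent).
#' @param n_components Optional fixed component count.
#' @return A `pca_model`: list with `loadings` (S x P), `explained_variance_pct`
#'   (all S components), `n_components`, `means`, `sds`, `feature_names`,
#'   `scores` (training scores, rows x P).
#' @export
pca_fit <- function(features, feature_names, variance_target_pct = 65,
                    n_components = NULL) {
  X <- as.matrix(features[, feature_names, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(feature_names[sds == 0], collapse = ", ")))
    feature_names <- feature_names[sds > 0]
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!length(feature_names)) stop("no non-constant features left", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  p <- if (!is.null(n_components)) {
    min(n_components, ncol(pc$rotation))
  } else {
    which(cumsum(expl) >= variance_target_pct)[1]
  }
  if (is.na(p)) p <- ncol(pc$rotation)
  load <- pc$rotation[, seq_len(p), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(p), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(p))
  structure(
    list(loadings = load, explained_variance_pct = expl,
         n_components = p, means = pc$center, sds = pc$scale,
         feature_names = feature_names, scores = scores),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features (%.1f%% of variance)\n",
              x$n_components, length(x$feature_names),
              sum(x$explained_variance_pct[seq_len(x$n_components)])))
  invisible(x)
}

#' Project features onto fitted principal components
#'
#' @param model A `pca_model`.
#' @param features Data.frame containing all of the model's feature columns.
#' @return Numeric matrix of component scores (rows x components).
#' @export
pca_transform <- function(model, features) {
  stopifnot(inherits(model, "pca_model"))
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$means, `-`), 2, model$sds, `/`)
  Xs %*% model$loadings
}
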