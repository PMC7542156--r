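#' Fit the multilevel logistic regression with varying intercepts and slopes
#'
#' Fits `outcome ~ scores` with a participant-level random intercept and one
#' independent random slope per score (diagonal random-effect covariance: one
#' variance per component), by Laplace-approximated maximum marginal
#' likelihood via [lme4::glmer()]. Per-participant effects are the posterior
#' modes (fixed effect + conditional mode). Fixed-effect p-values are Wald
#' tests; variance components can be tested by a likelihood-ratio test
#' against the model with that component removed, referred to the boundary
#' mixture `0.5 chi^2_0 + 0.5 chi^2_1` (`test_variances = TRUE`; off by
#' default as each test refits the model).
#'
#' With a single participant the multilevel structure is unidentifiable and
#' the fit falls back to an ordinary pooled logistic regression, with a
#' warning.
#'
#' @param data Data.frame with the outcome, score, and id columns.
#' @param score_cols Character vector of predictor columns.
#' @param outcome_col Binary outcome column (default "outcome").
#' @param id_col Participant identifier column (default "participant_id").
#' @param test_variances Compute boundary-corrected LRT p-values for each
#'   variance component (default FALSE).
#' @param se_variances Compute Wald standard errors for the random-effect SDs
#'   from the numerical Hessian of the Laplace deviance (default FALSE).
#' @return An `mlr_model`: list with `type` ("multilevel" or "pooled"),
#'   `fit`, `gamma` (fixed coefficients), `sd_alpha`, `sd_beta`,
#'   `participant_effects` (per-participant realized intercept/slopes),
#'   `loglik`, and `summary` (`$fixed`, `$random` data.frames).
#' @export
fit_mlr <- function(data, score_cols, outcome_col = "outcome",
                    id_col = "participant_id", test_variances = FALSE,
                    se_variances = FALSE) {
  y <- data[[outcome_col]]
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  ids <- as.factor(data[[id_col]])
  if (nlevels(ids) < 2) {
    warning("single participant: falling back to ordinary logistic regression")
    fit <- stats::glm(stats::reformulate(score_cols, outcome_col),
                      family = stats::binomial(), data = data)
    sm <- summary(fit)$coefficients
    return(structure(
      list(type = "pooled", fit = fit, gamma = stats::coef(fit),
           sd_alpha = 0, sd_beta = stats::setNames(rep(0, length(score_cols)), score_cols),
           participant_effects = NULL,
           loglik = as.numeric(stats::logLik(fit)),
           summary = list(
             fixed = data.frame(term = rownames(sm), estimate = sm[, 1],
                                se = sm[, 2], p = sm[, 4], row.names = NULL),
             random = NULL),
           score_cols = score_cols, outcome_col = outcome_col, id_col = id_col),
      class = "mlr_model"))
  }

  data <- data.frame(data)
  data[[id_col]] <- ids
  re_terms <- c(sprintf("(1 | %s)", id_col),
                sprintf("(0 + %s | %s)", score_cols, id_col))
  fml <- stats::as.formula(paste(
    outcome_col, "~", paste(score_cols, collapse = " + "), "+",
    paste(re_terms, collapse = " + ")))
  ## Laplace fit; on numerically degenerate data (e.g. a separable fold) the
  ## PIRLS iterations can fail, so retry with the faster nAGQ = 0
  ## approximation and, as a last resort, fall back to the pooled fit.
  fit <- tryCatch(
    lme4::glmer(fml, data = data, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) tryCatch(
      lme4::glmer(fml, data = data, family = stats::binomial(), nAGQ = 0,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e2) NULL))
  if (is.null(fit)) {
    warning("multilevel fit failed to converge; falling back to pooled logistic regression")
    out <- fit_mlr(data[, setdiff(names(data), id_col)], score_cols,
                   outcome_col, id_col = ".none")
    return(out)
  }

  gamma <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  sds <- stats::setNames(
    vapply(vc, function(v) attr(v, "stddev"), numeric(1)),
    vapply(vc, function(v) colnames(v), character(1)))
  sd_alpha <- unname(sds[["(Intercept)"]])
  sd_beta <- sds[score_cols]

  ## per-participant realized effects: fixed part + conditional modes
  re <- lme4::ranef(fit)
  eff <- Reduce(function(a, b) cbind(a, b), re)   # one column per term
  eff <- eff[, c("(Intercept)", score_cols), drop = FALSE]
  effects <- sweep(as.matrix(eff), 2, gamma[c("(Intercept)", score_cols)], `+`)
  participant_effects <- data.frame(participant_id = rownames(eff),
                                    effects, check.names = FALSE,
                                    row.names = NULL)
  names(participant_effects) <- c(id_col, "alpha", paste0("beta_", score_cols))

  sm <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL)

  random <- data.frame(term = c("(Intercept)", score_cols),
                       sd = c(sd_alpha, unname(sd_beta)),
                       se = NA_real_, p = NA_real_)
  if (se_variances) {
    random$se <- mlr_theta_se(fit)
  }
  if (test_variances) {
    ll_full <- as.numeric(stats::logLik(fit))
    random$p <- vapply(seq_along(re_terms), function(i) {
      fml_red <- stats::as.formula(paste(
        outcome_col, "~", paste(score_cols, collapse = " + "), "+",
        paste(re_terms[-i], collapse = " + ")))
      red <- lme4::glmer(fml_red, data = data, family = stats::binomial(),
                         control = lme4::glmerControl(calc.derivs = FALSE))
      lrt <- 2 * (ll_full - as.numeric(stats::logLik(red)))
      if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    }, numeric(1))
  }

  structure(
    list(type = "multilevel", fit = fit, gamma = gamma,
         sd_alpha = sd_alpha, sd_beta = sd_beta,
         participant_effects = participant_effects,
         loglik = as.numeric(stats::logLik(fit)),
         summary = list(fixed = fixed, random = random),
         score_cols = score_cols, outcome_col = outcome_col, id_col = id_col),
    class = "mlr_model")
}

## Wald SEs for the random-effect SDs (theta) from the numerical Hessian of
## the Laplace deviance as a function of (theta, beta).
mlr_theta_se <- function(fit) {
  devfun <- stats::update(fit, devFunOnly = TRUE)
  theta <- lme4::getME(fit, "theta")
  beta <- lme4::fixef(fit)
  pars <- c(theta, beta)
  H <- pracma::hessian(function(p) devfun(p), pars)
  V <- tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, length(pars), length(pars)))
  sqrt(pmax(0, diag(V)))[seq_along(theta)]
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %s fit: %d fixed coefficients, logLik = %.2f\n",
              x$type, length(x$gamma), x$loglik))
  if (x$type == "multilevel") {
    cat(sprintf("  random-effect SDs: intercept %.3f; slopes %s\n",
                x$sd_alpha, paste(sprintf("%.3f", x$sd_beta), collapse = ", ")))
  }
  invisible(x)
}

#' Predict SIB probabilities from a multilevel model
#'
#' Rows belonging to a participant seen in training use that participant's
#' realized intercept and slopes (posterior modes); rows from unseen
#' participants use the fixed coefficients only.
#'
#' @param model An `mlr_model`.
#' @param newdata Data.frame with the score columns (and the id column, used
#'   when present).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_mlr <- function(model, newdata) {
  stopifnot(inherits(model, "mlr_model"))
  if (model$type == "pooled") {
    return(as.numeric(stats::predict(model$fit, newdata = newdata,
                                     type = "response")))
  }
  X <- as.matrix(newdata[, model$score_cols, drop = FALSE])
  gamma <- model$gamma
  alpha <- rep(unname(gamma["(Intercept)"]), nrow(X))
  B <- matrix(rep(gamma[model$score_cols], each = nrow(X)), nrow = nrow(X))
  if (model$id_col %in% names(newdata)) {
    pe <- model$participant_effects
    m <- match(as.character(newdata[[model$id_col]]), pe[[model$id_col]])
    known <- !is.na(m)
    if (any(known)) {
      alpha[known] <- pe$alpha[m[known]]
      B[known, ] <- as.matrix(pe[m[known], paste0("beta_", model$score_cols),
                                 drop = FALSE])
    }
  }
  as.numeric(stats::plogis(alpha + rowSums(X * B)))
}

#' @export
predict.mlr_model <- function(object, newdata, ...) predict_mlr(object, newdata)

## Forward-only stepwise logistic regression from the intercept, minimizing
## BIC over main effects and two-way interactions. Unlike stats::step, the
## candidate set is not restricted by marginality, so a pure interaction can
## enter without its main effects.
stepwise_bic_forward <- function(data, score_cols, outcome_col) {
  candidates <- score_cols
  if (length(score_cols) >= 2) {
    candidates <- c(candidates,
                    utils::combn(score_cols, 2, paste, collapse = ":"))
  }
  terms_in <- character(0)
  fit <- stats::glm(stats::reformulate("1", outcome_col), stats::binomial(),
                    data = data)
  best_bic <- stats::BIC(fit)
  repeat {
    remaining <- setdiff(candidates, terms_in)
    if (!length(remaining)) break
    trials <- vapply(remaining, function(tm) {
      f <- stats::glm(stats::reformulate(c(terms_in, tm), outcome_col),
                      stats::binomial(), data = data)
      stats::BIC(f)
    }, numeric(1))
    if (min(trials) >= best_bic) break
    terms_in <- c(terms_in, remaining[which.min(trials)])
    best_bic <- min(trials)
    fit <- stats::glm(stats::reformulate(terms_in, outcome_col),
                      stats::binomial(), data = data)
  }
  fit
}

COMPARISON_KINDS <- c("mlr", "lr_varying_intercept", "lr_plain",
                      "lr_stepwise_bic", "lr_individual", "knn",
                      "svm_linear", "svm_cubic", "svm_gaussian",
                      "decision_tree")

#' Fit a comparison classifier
#'
#' A uniform predict-probability interface over the model bank used to
#' benchmark the multilevel regression: logistic regression with a varying
#' intercept only, plain pooled logistic regression, forward-stepwise
#' logistic regression over main effects and two-way interactions selected by
#' BIC, per-participant logistic models, k-nearest neighbors (default
#' k = 11), support vector machines (linear, cubic-polynomial, and Gaussian
#' kernels), and a decision tree. `kind = "mlr"` delegates to [fit_mlr()] so
#' the whole bank shares one interface.
#'
#' SVM scores are reported as a logistic transform of the signed margin;
#' they are monotone in the decision value (thresholding at 0.5 reproduces
#' the SVM's class decision) but are not calibrated probabilities.
#'
#' @param kind One of `r paste0('"', COMPARISON_KINDS, '"', collapse = ", ")`.
#' @param data Training data.frame.
#' @param score_cols Predictor columns.
#' @param outcome_col,id_col Column names.
#' @param k Neighbor count for kNN (default 11).
#' @return A `sib_classifier` with a [predict()] method returning
#'   probabilities for the positive class.
#' @export
fit_comparison <- function(kind, data, score_cols, outcome_col = "outcome",
                           id_col = "participant_id", k = 11) {
  kind <- match.arg(kind, COMPARISON_KINDS)
  y <- data[[outcome_col]]
  data <- data.frame(data)
  data[[id_col]] <- as.factor(data[[id_col]])
  fml <- stats::reformulate(score_cols, outcome_col)
  X <- as.matrix(data[, score_cols, drop = FALSE])

  fit <- switch(
    kind,
    mlr = fit_mlr(data, score_cols, outcome_col, id_col),
    lr_varying_intercept = {
      if (nlevels(data[[id_col]]) < 2) {
        stats::glm(fml, stats::binomial(), data = data)
      } else {
        f <- stats::as.formula(paste(
          outcome_col, "~", paste(score_cols, collapse = " + "),
          sprintf("+ (1 | %s)", id_col)))
        tryCatch(
          lme4::glmer(f, data = data, family = stats::binomial(),
                      control = lme4::glmerControl(calc.derivs = FALSE)),
          error = function(e) stats::glm(fml, stats::binomial(), data = data))
      }
    },
    lr_plain = {
      f <- stats::glm(fml, stats::binomial(), data = data)
      if (!f$converged || any(abs(stats::coef(f)) > 1e3, na.rm = TRUE)) {
        f <- set_flag(f, "possible_separation")
      }
      f
    },
    lr_stepwise_bic = stepwise_bic_forward(data, score_cols, outcome_col),
    lr_individual = {
      pooled <- stats::glm(fml, stats::binomial(), data = data)
      per_id <- lapply(split(data, data[[id_col]], drop = TRUE), function(d) {
        if (length(unique(d[[outcome_col]])) < 2) return(NULL)
        stats::glm(fml, stats::binomial(), data = d)
      })
      list(per_id = per_id, pooled = pooled)
    },
    knn = list(train = X, labels = factor(y, levels = c(0, 1)), k = k),
    svm_linear = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear"),
    svm_cubic = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "polynomial",
                           degree = 3),
    svm_gaussian = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial"),
    decision_tree = rpart::rpart(fml, data = data, method = "class")
  )
  structure(
    list(kind = kind, fit = fit, score_cols = score_cols,
         outcome_col = outcome_col, id_col = id_col),
    class = "sib_classifier")
}

#' Predict positive-class scores from a fitted comparison classifier
#'
#' @param object A `sib_classifier`.
#' @param newdata Data.frame with the score columns.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities (scores in (0, 1)).
#' @export
predict.sib_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$score_cols, drop = FALSE])
  switch(
    object$kind,
    mlr = predict_mlr(object$fit, newdata),
    lr_varying_intercept = {
      if (inherits(object$fit, "glm")) {
        as.numeric(stats::predict(object$fit, newdata, type = "response"))
      } else {
        nd <- data.frame(newdata)
        nd[[object$id_col]] <- as.character(nd[[object$id_col]] %||% NA)
        as.numeric(stats::predict(object$fit, newdata = nd, type = "response",
                                  allow.new.levels = TRUE))
      }
    },
    lr_plain = ,
    lr_stepwise_bic = as.numeric(stats::predict(object$fit, newdata,
                                                type = "response")),
    lr_individual = {
      ids <- as.character(newdata[[object$id_col]] %||% rep(NA, nrow(newdata)))
      p <- as.numeric(stats::predict(object$fit$pooled, newdata,
                                     type = "response"))
      for (id in unique(stats::na.omit(ids))) {
        f <- object$fit$per_id[[id]]
        if (!is.null(f)) {
          rows <- which(ids == id)
          p[rows] <- as.numeric(stats::predict(
            f, newdata[rows, , drop = FALSE], type = "response"))
        }
      }
      p
    },
    knn = {
      pred <- class::knn(object$fit$train, X, object$fit$labels,
                         k = object$fit$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    svm_linear = ,
    svm_cubic = ,
    svm_gaussian = {
      dv <- attr(stats::predict(object$fit, X, decision.values = TRUE),
                 "decision.values")
      ## orient the margin toward the positive class
      sign_to_1 <- if (colnames(dv)[1] == "0/1") -1 else 1
      as.numeric(stats::plogis(sign_to_1 * dv[, 1]))
    },
    decision_tree = {
      pr <- stats::predict(object$fit, data.frame(newdata), type = "prob")
      if ("1" %in% colnames(pr)) as.numeric(pr[, "1"]) else rep(0, nrow(newdata))
    }
  )
}

#' @export
print.sib_classifier <- function(x, ...) {
  cat(sprintf("<sib_classifier> kind = %s over %d scores\n",
              x$kind, length(x$score_cols)))
  invisible(x)
}
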