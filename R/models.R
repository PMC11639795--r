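## Affinity regression models behind a single interface. Ridge is solved in
## closed form (intercept unpenalised, scikit-learn parameterisation of
## alpha); the tree ensembles (random forest, gradient boosting and an
## XGBoost-style second-order booster) run on the package's own Rcpp tree
## engine since no external learner is assumed to be installed.

#' Model configuration
#'
#' Defaults follow the reference hyperparameters: 100 estimators and random
#' state 42 for the ensemble models, alpha = 1 for ridge.
#'
#' @param kind one of `"ridge"`, `"random_forest"`, `"gradient_boosting"`,
#'   `"xgboost"`.
#' @param n_estimators trees in ensemble models.
#' @param alpha ridge L2 penalty.
#' @param learning_rate boosting shrinkage (0.1 for gradient boosting,
#'   0.3 for the XGBoost-style model, their usual defaults).
#' @param max_depth tree depth (3 for gradient boosting, 6 for XGBoost
#'   style, 12 for forests).
#' @param random_state RNG seed for bootstrap/feature sampling.
#' @return a `model_config` list.
#' @export
model_config <- function(kind = c("ridge", "random_forest",
                                  "gradient_boosting", "xgboost"),
                         n_estimators = 100, alpha = 1.0,
                         learning_rate = NULL, max_depth = NULL,
                         random_state = 42) {
  kind <- match.arg(kind)
  if (is.null(learning_rate))
    learning_rate <- switch(kind, gradient_boosting = 0.1, xgboost = 0.3, 0)
  if (is.null(max_depth))
    max_depth <- switch(kind, gradient_boosting = 3, xgboost = 6,
                        random_forest = 12, 0)
  structure(list(kind = kind, n_estimators = as.integer(n_estimators),
                 alpha = alpha, learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 random_state = as.integer(random_state)),
            class = "model_config")
}

#' Train an affinity regression model
#'
#' @param cfg a [model_config()] (or a kind string, which is promoted to
#'   one with default parameters).
#' @param X feature matrix (rows = samples).
#' @param y affinity values (lower = stronger binding).
#' @return fitted `affinity_model`, usable with [predict()] and
#'   [rank_variants()]. A constant `y` yields a constant predictor with a
#'   warning.
#' @export
train_model <- function(cfg, X, y) {
  if (is.character(cfg)) cfg <- model_config(cfg)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < 2) stop("need at least 2 training samples")
  if (stats::sd(y) == 0)
    warning("constant response: fitted model predicts a constant")
  fit <- switch(cfg$kind,
    ridge = ridge_fit(X, y, cfg$alpha),
    random_forest = {
      mtry <- max(1L, as.integer(ncol(X) / 3))
      trees <- .fit_forest_cpp(X, y, cfg$n_estimators, cfg$max_depth,
                               5L, mtry, cfg$random_state)
      list(trees = trees, scale = 1 / cfg$n_estimators, base = 0)
    },
    gradient_boosting = {
      base <- mean(y)
      trees <- .fit_boosted_cpp(X, y, cfg$n_estimators, cfg$max_depth,
                                cfg$learning_rate, 0.0, 1e-9, base,
                                cfg$random_state)
      list(trees = trees, scale = cfg$learning_rate, base = base)
    },
    xgboost = {
      base <- mean(y)
      trees <- .fit_boosted_cpp(X, y, cfg$n_estimators, cfg$max_depth,
                                cfg$learning_rate, 1.0, 1.0, base,
                                cfg$random_state)
      list(trees = trees, scale = cfg$learning_rate, base = base)
    })
  structure(list(kind = cfg$kind, config = cfg, fit = fit,
                 n_features = ncol(X)),
            class = "affinity_model")
}

## Closed-form ridge: minimise ||y - Xw - b||^2 + alpha ||w||^2 with the
## intercept b unpenalised. Columns are standardised before penalisation
## (the glmnet convention) so the penalty strength does not depend on the
## feature scale; coefficients are mapped back to the original scale.
## Zero-variance columns are left untouched (their centred values vanish).
ridge_fit <- function(X, y, alpha) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sds <- sqrt(colMeans(Xc^2))
  sds[sds == 0] <- 1
  Xs <- sweep(Xc, 2, sds, "/")
  A <- crossprod(Xs)
  diag(A) <- diag(A) + alpha
  ws <- drop(solve(A, crossprod(Xs, y - ym)))
  w <- ws / sds
  list(weights = w, intercept = ym - sum(xm * w))
}

#' @export
predict.affinity_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature count mismatch: model expects ", object$n_features)
  if (object$kind == "ridge") {
    drop(X %*% object$fit$weights) + object$fit$intercept
  } else {
    .predict_ensemble_cpp(object$fit$trees, X, object$fit$scale,
                          object$fit$base)
  }
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model> kind=%s, %d features\n", x$kind,
              x$n_features))
  invisible(x)
}

#' Train and evaluate a model on an affinity table
#'
#' Convenience harness: encodes the peptide/target pairs, splits 80:20,
#' fits the configured model and reports train/test metrics.
#'
#' @param records data.frame with `peptide_seq`, `target_seq`, `affinity`.
#' @param cfg [model_config()] or kind string.
#' @param train_fraction,seed passed to [split_dataset()].
#' @inheritParams conjoint_triad
#' @return list with `model`, `metrics` and the `split`.
#' @export
screen_affinity_table <- function(records, cfg = "ridge",
                                  train_fraction = 0.8, seed = 42,
                                  normalize = "frequency") {
  split <- split_dataset(records, train_fraction, seed)
  X_train <- encode_pairs(split$train$peptide_seq, split$train$target_seq,
                          normalize)
  X_test <- encode_pairs(split$test$peptide_seq, split$test$target_seq,
                         normalize)
  model <- train_model(cfg, X_train, split$train$affinity)
  metrics <- evaluate_model(model, X_train, split$train$affinity,
                            X_test, split$test$affinity)
  list(model = model, metrics = metrics, split = split)
}
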