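ALGORITHMS <- c("RF", "SVM", "DT", "LR", "KNN", "GNB")

#' Default hyperparameter grids
#'
#' One data frame row per candidate configuration.  RF: number of trees and
#' the mtry rule; SVM: RBF cost and gamma (`"scale"` maps to
#' `1 / (p * var(x))`); KNN: neighbor count; LR: ridge-penalized logistic
#' regression with loss weight C (lambda = 1 / (n * C)); DT: maximum depth;
#' GNB: a single Gaussian naive Bayes configuration.
#'
#' @param algorithm One of `"RF"`, `"SVM"`, `"DT"`, `"LR"`, `"KNN"`,
#'   `"GNB"`.
#' @return A data frame of candidate hyperparameter settings.
#' @export
default_grid <- function(algorithm) {
  switch(match.arg(algorithm, ALGORITHMS),
         RF = expand.grid(ntree = c(100L, 500L),
                          mtry_rule = c("sqrt", "log2"),
                          stringsAsFactors = FALSE),
         SVM = expand.grid(cost = c(0.1, 1, 10, 100),
                           gamma = c("scale", "0.01", "0.001"),
                           stringsAsFactors = FALSE),
         DT = data.frame(maxdepth = c(3L, 5L, 10L, 30L)),
         LR = data.frame(C = c(0.01, 0.1, 1, 10)),
         KNN = data.frame(k = c(3L, 5L, 7L, 9L)),
         GNB = data.frame(model = "gaussian", stringsAsFactors = FALSE))
}

#' Model specification
#'
#' @param algorithm One of the six supported families: `"RF"`, `"SVM"`,
#'   `"DT"`, `"LR"`, `"KNN"`, `"GNB"`.
#' @param grid Hyperparameter candidates (data frame, one row per
#'   configuration); defaults to [default_grid()].
#' @param cv_folds Stratified folds for tuning (default 5).
#' @param tuning_metric `"accuracy"` (default) or `"auc"`.
#' @param seed Integer seed.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(algorithm, grid = NULL, cv_folds = 5L,
                       tuning_metric = c("accuracy", "auc"), seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (is.null(grid)) grid <- default_grid(algorithm)
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds),
                 tuning_metric = match.arg(tuning_metric),
                 seed = as.integer(seed)),
            class = "model_spec")
}

svm_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- var(as.vector(x))
    if (v == 0) v <- 1
    1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

# Fit one classifier at fixed hyperparameters on standardized data.
fit_classifier <- function(algorithm, x, y, params, seed) {
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(algorithm,
    RF = {
      mtry <- switch(params$mtry_rule,
                     sqrt = max(1L, floor(sqrt(ncol(x)))),
                     log2 = max(1L, floor(log2(ncol(x)))))
      with_local_seed(seed, randomForest::randomForest(
        x, yf, ntree = params$ntree, mtry = mtry))
    },
    SVM = with_local_seed(seed, e1071::svm(
      x, yf, kernel = "radial", cost = params$cost,
      gamma = svm_gamma(params$gamma, x), probability = TRUE,
      scale = FALSE)),
    DT = {
      df <- data.frame(.label = yf, x, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, xval = 0))
    },
    LR = {
      lambda <- 1 / (nrow(x) * params$C)
      glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                     lambda = lambda)
    },
    KNN = list(x_train = x, y_train = yf, k = params$k),
    GNB = e1071::naiveBayes(x, yf))
  list(algorithm = algorithm, params = params, fit = fit, seed = seed)
}

# Positive-class probability of a fitted classifier on standardized data.
predict_prob_classifier <- function(model, x) {
  switch(model$algorithm,
    RF = predict(model$fit, x, type = "prob")[, "1"],
    SVM = {
      pr <- attr(predict(model$fit, x, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    DT = predict(model$fit, data.frame(x, check.names = FALSE),
                 type = "prob")[, "1"],
    LR = drop(predict(model$fit, x, type = "response")),
    KNN = {
      pred <- with_local_seed(model$seed, class::knn(
        model$fit$x_train, x, model$fit$y_train, k = model$fit$k,
        prob = TRUE))
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    GNB = predict(model$fit, x, type = "raw")[, "1"])
}

#' Train and tune a classifier on a selected feature set
#'
#' Restricts the training matrix to the selected features, runs a stratified
#' k-fold cross-validated grid search (z-score standardization refit inside
#' each training fold), picks the configuration with the best tuning metric
#' (first in grid order on ties) and refits it on the full training data
#' with a scaler fit on the full training data.  Deterministic for a fixed
#' seed.
#'
#' @param fm Training `feature_matrix` with labels (or matrix + `labels`).
#' @param labels Binary labels (unused when `fm` carries labels).
#' @param selection A `selection_result` (or character vector of feature
#'   names) restricting the model's inputs.
#' @param spec A [model_spec()].
#' @return An object of class `tuned_model`: algorithm, chosen
#'   hyperparameters, scaler, fitted classifier, feature schema and the CV
#'   tuning table.
#' @export
train_model <- function(fm, labels = NULL, selection, spec) {
  x_all <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (is.null(labels) && is(fm, "feature_matrix")) labels <- fm$labels
  y <- as.integer(labels)
  feats <- if (is(selection, "selection_result")) selection$selected
           else as.character(selection)
  if (length(feats) == 0L)
    stop("empty feature selection: nothing to train on", call. = FALSE)
  missing <- setdiff(feats, colnames(x_all))
  if (length(missing))
    stop("selected feature(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- x_all[, feats, drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < spec$cv_folds)
    stop("degenerate folds: need at least cv_folds samples per class",
         call. = FALSE)

  folds <- make_stratified_folds(y, spec$cv_folds, spec$seed)
  scores <- vapply(seq_len(nrow(spec$grid)), function(gi) {
    params <- as.list(spec$grid[gi, , drop = FALSE])
    mean(vapply(seq_along(folds), function(f) {
      test_idx <- folds[[f]]
      sc <- fit_scaler(x[-test_idx, , drop = FALSE])
      xtr <- apply_scaler(sc, x[-test_idx, , drop = FALSE])
      xte <- apply_scaler(sc, x[test_idx, , drop = FALSE])
      fit <- fit_classifier(spec$algorithm, xtr, y[-test_idx], params,
                            spec$seed + f)
      prob <- predict_prob_classifier(fit, xte)
      if (spec$tuning_metric == "accuracy") {
        mean(as.integer(prob >= 0.5) == y[test_idx])
      } else {
        roc_auc(y[test_idx], prob)
      }
    }, numeric(1)))
  }, numeric(1))
  best_gi <- which.max(scores)
  best_params <- as.list(spec$grid[best_gi, , drop = FALSE])
  scaler <- fit_scaler(x)
  final <- fit_classifier(spec$algorithm, apply_scaler(scaler, x), y,
                          best_params, spec$seed)
  structure(list(algorithm = spec$algorithm, params = best_params,
                 scaler = scaler, fit = final, features = feats,
                 cv_table = cbind(spec$grid, score = scores),
                 cv_score = scores[best_gi], spec = spec),
            class = "tuned_model")
}

fit_scaler <- function(x) {
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0] <- 1
  list(mu = colMeans(x), sigma = sigma)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sigma, "/")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf("tuned_model (%s) on %d feature(s); CV %s %.4f\n",
              x$algorithm, length(x$features), x$spec$tuning_metric,
              x$cv_score))
  cat("  chosen:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Predict labels and probabilities from a tuned model
#'
#' @param model A [train_model()] result.
#' @param fm A `feature_matrix` (or matrix) containing at least the model's
#'   features.
#' @return A data frame with columns `id`, `label` (probability >= 0.5) and
#'   `probability` (positive class), in input row order.
#' @export
predict_model <- function(model, fm) {
  stopifnot(is(model, "tuned_model"))
  x <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop("input is missing model feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  xs <- apply_scaler(model$scaler, x[, model$features, drop = FALSE])
  prob <- unname(predict_prob_classifier(model$fit, xs))
  data.frame(id = rownames(x), label = as.integer(prob >= 0.5),
             probability = prob)
}

#' Evaluate a tuned model on labeled data
#'
#' @param model A [train_model()] result.
#' @param fm A labeled `feature_matrix` (or matrix plus `labels`).
#' @param labels Binary labels (unused when `fm` carries labels).
#' @return An [eval_report()].
#' @export
evaluate_model <- function(model, fm, labels = NULL) {
  if (is.null(labels) && is(fm, "feature_matrix")) labels <- fm$labels
  pred <- predict_model(model, fm)
  eval_report(labels, pred$label, pred$probability, ids = pred$id)
}

#' Save a tuned model bundle
#'
#' Writes `model.rds` (the fitted estimator) and `metadata.json` (algorithm,
#' hyperparameters, feature schema) under `dir`.
#'
#' @param model A `tuned_model`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  stopifnot(is(model, "tuned_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(algorithm = model$algorithm, params = model$params,
         features = model$features, cv_score = model$cv_score,
         tuning_metric = model$spec$tuning_metric),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a tuned model bundle
#'
#' @param dir Directory written by [save_model()].
#' @return The `tuned_model`.
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
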