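test_that("confusion counts follow the standard definitions", {
  expect_equal(confusion(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0)),
               c(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(confusion(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1)),
               c(TP = 0L, TN = 0L, FP = 2L, FN = 3L))
  expect_equal(confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1)),
               c(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("metric formulas reproduce the published worked example", {
  m <- classification_metrics(56, 55, 1, 0)
  expect_equal(round(m$accuracy, 4), 0.9911)
  expect_equal(round(m$mcc, 4), 0.9823)
  expect_equal(round(m$precision, 4), 0.9825)
  expect_equal(m$recall, 1)
  expect_equal(round(m$f1, 4), 0.9912)

  chance <- classification_metrics(25, 25, 25, 25)
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)

  perfect <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(perfect[c("accuracy", "mcc", "recall", "precision",
                                "f1")]), rep(1, 5), ignore_attr = TRUE)

  degen <- classification_metrics(0, 5, 0, 5)
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
})

test_that("MCC stays in [-1,1] and negates when predictions flip", {
  set.seed(81)
  for (i in 1:20) {
    truth <- sample(c(0, 1), 30, TRUE)
    pred <- sample(c(0, 1), 30, TRUE)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    cm <- confusion(truth, pred)
    m <- classification_metrics(cm["TP"], cm["TN"], cm["FP"], cm["FN"])
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    cm_flip <- confusion(truth, 1 - pred)
    m_flip <- classification_metrics(cm_flip["TP"], cm_flip["TN"],
                                     cm_flip["FP"], cm_flip["FN"])
    expect_equal(m_flip$mcc, -m$mcc, tolerance = 1e-12)
  }
})

test_that("the exact binomial interval matches its Beta definition", {
  ci <- accuracy_ci(111, 112)
  expect_equal(round(unname(ci), 4), c(0.9513, 0.9998))
  # independent oracle: binom.test's exact interval
  bt <- binom.test(111, 112)$conf.int
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-10)

  expect_equal(unname(accuracy_ci(10, 10)[2]), 1)
  expect_equal(unname(accuracy_ci(0, 10)[1]), 0)
  expect_error(accuracy_ci(11, 10), "correct")

  # brackets the estimate and narrows with n at fixed proportion
  ci_small <- accuracy_ci(8, 10)
  ci_large <- accuracy_ci(80, 100)
  expect_true(ci_small["low"] < 0.8 && 0.8 < ci_small["high"])
  expect_lt(diff(ci_large), diff(ci_small))
})

test_that("ROC AUC equals the pair-counting probability", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)

  set.seed(82)
  for (i in 1:10) {
    truth <- sample(c(0, 1), 20, TRUE)
    if (length(unique(truth)) < 2) next
    s <- rnorm(20)
    # exhaustive pair enumeration oracle
    pos <- s[truth == 1]; neg <- s[truth == 0]
    pairs <- outer(pos, neg, function(a, b)
      ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
    expect_equal(roc_auc(truth, s), mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(truth, s) + roc_auc(truth, -s), 1,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  truth <- sample(c(0, 1), 50, TRUE)
  s <- rnorm(50) + truth
  ref <- as.numeric(pROC::auc(pROC::roc(truth, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(truth, s), ref, tolerance = 1e-12)
})

make_toy_features <- function(n = 60, seed = 84) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(paste0("s", seq_len(n)), paste0("f", 1:6)))
    y <- as.integer(x[, 1] - x[, 2] > 0)
    x[, 1] <- x[, 1] + y * 2  # widen the margin: cleanly separable signal
    feature_matrix(x, y)
  })
}

test_that("every algorithm trains, tunes and predicts deterministically", {
  fm <- make_toy_features()
  sel <- c("f1", "f2", "f3")
  for (algorithm in c("RF", "SVM", "DT", "LR", "KNN", "GNB")) {
    spec <- model_spec(algorithm, cv_folds = 3, seed = 11)
    model <- train_model(fm, selection = sel, spec = spec)
    pred <- predict_model(model, fm)
    expect_true(all(pred$probability >= 0 & pred$probability <= 1))
    expect_identical(pred$label, as.integer(pred$probability >= 0.5))
    expect_gte(mean(pred$label == fm$labels), 0.85)
    # determinism: identical refit and identical predictions
    model2 <- train_model(fm, selection = sel, spec = spec)
    expect_identical(model2$params, model$params)
    expect_identical(predict_model(model2, fm), pred)
  }
})

test_that("training validates selections and schemas", {
  fm <- make_toy_features()
  spec <- model_spec("SVM", cv_folds = 3, seed = 1)
  expect_error(train_model(fm, selection = character(0), spec = spec),
               "empty")
  expect_error(train_model(fm, selection = "ghost", spec = spec), "ghost")
  model <- train_model(fm, selection = c("f1", "f2"), spec = spec)
  reduced <- feature_matrix(fm$x[, c("f3", "f4")], fm$labels)
  expect_error(predict_model(model, reduced), "f1")
})

test_that("evaluation reports reproduce from their own counts", {
  fm <- make_toy_features()
  model <- train_model(fm, selection = c("f1", "f2"),
                       spec = model_spec("LR", cv_folds = 3, seed = 2))
  rep <- evaluate_model(model, fm)
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, nrow(fm$x))
  m <- classification_metrics(rep$TP, rep$TN, rep$FP, rep$FN)
  expect_equal(rep$accuracy, m$accuracy)
  expect_equal(rep$mcc, m$mcc)
  expect_equal(rep$f1, m$f1)
  ci <- accuracy_ci(rep$TP + rep$TN, nrow(fm$x))
  expect_equal(rep$ci_low, unname(ci["low"]))
  expect_equal(rep$ci_high, unname(ci["high"]))
  expect_equal(nrow(rep$per_sample), nrow(fm$x))

  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  payload <- jsonlite::fromJSON(path)
  expect_equal(payload$accuracy, rep$accuracy)
})

test_that("model bundles round-trip through disk", {
  fm <- make_toy_features()
  model <- train_model(fm, selection = c("f1", "f2"),
                       spec = model_spec("RF", cv_folds = 3, seed = 3))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_identical(predict_model(back, fm), predict_model(model, fm))
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  expect_identical(meta$algorithm, "RF")
  expect_identical(meta$features, model$features)
})
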