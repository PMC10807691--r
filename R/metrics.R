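#' Confusion counts for binary predictions
#'
#' @param truth Binary 0/1 vector of true labels (1 = positive).
#' @param predicted Binary 0/1 vector of predicted labels.
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  c(TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and the F1 harmonic mean.  A zero
#' denominator yields 0 for that metric, with `degenerate = TRUE` flagged in
#' the result.
#'
#' @param TP,TN,FP,FN Nonnegative confusion counts.
#' @return Named list: `accuracy`, `mcc`, `recall`, `precision`, `f1`,
#'   `degenerate`.
#' @export
#' @examples
#' classification_metrics(56, 55, 1, 0)
classification_metrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  n <- TP + TN + FP + FN
  if (n < 1L) stop("at least one evaluated sample required", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(accuracy = (TP + TN) / n,
       mcc = safe_div(TP * TN - FP * FN, mcc_den),
       recall = safe_div(TP, TP + FN),
       precision = safe_div(TP, TP + FP),
       f1 = {
         prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
         rec <- if (TP + FN == 0) 0 else TP / (TP + FN)
         if (prec + rec == 0) {
           degenerate <- TRUE
           0
         } else 2 * prec * rec / (prec + rec)
       },
       degenerate = degenerate)
}

#' Exact (Clopper-Pearson) binomial confidence interval on accuracy
#'
#' Two-sided exact interval from the Beta quantile definition:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 when x = 0) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param correct Number of correct predictions.
#' @param n Number of evaluated samples.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' accuracy_ci(111, 112)  # (0.9513, 0.9998) at 4 decimals
accuracy_ci <- function(correct, n, level = 0.95) {
  if (n < 1L || correct < 0L || correct > n)
    stop("need 0 <= correct <= n with n >= 1", call. = FALSE)
  alpha <- 1 - level
  low <- if (correct == 0) 0 else qbeta(alpha / 2, correct, n - correct + 1)
  high <- if (correct == n) 1 else
    qbeta(1 - alpha / 2, correct + 1, n - correct)
  c(low = low, high = high)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank handling of tied scores:
#' the probability that a randomly chosen positive is scored above a
#' randomly chosen negative (ties counted half).
#'
#' @param truth Binary 0/1 vector of true labels; both classes must be
#'   present.
#' @param scores Numeric scores (higher = more positive).
#' @return The AUC in [0, 1].
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report for binary predictions
#'
#' @param truth Binary 0/1 true labels.
#' @param predicted Binary 0/1 predicted labels.
#' @param scores Positive-class probabilities or scores (for AUC).
#' @param ids Optional sample ids for the per-sample table.
#' @param level Confidence level for the accuracy interval (default 0.95).
#' @return An object of class `eval_report`: confusion counts, the
#'   metrics of [classification_metrics()], `ci_low`/`ci_high`, `auc` and a
#'   `per_sample` data frame (id, truth, predicted, probability).
#' @export
eval_report <- function(truth, predicted, scores, ids = NULL,
                        level = 0.95) {
  cm <- confusion(truth, predicted)
  met <- classification_metrics(cm["TP"], cm["TN"], cm["FP"], cm["FN"])
  ci <- accuracy_ci(unname(cm["TP"] + cm["TN"]), sum(cm), level)
  if (is.null(ids)) ids <- paste0("s", seq_along(truth))
  structure(list(TP = unname(cm["TP"]), TN = unname(cm["TN"]),
                 FP = unname(cm["FP"]), FN = unname(cm["FN"]),
                 accuracy = met$accuracy, mcc = met$mcc,
                 recall = met$recall, precision = met$precision,
                 f1 = met$f1, ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]),
                 auc = roc_auc(truth, scores),
                 per_sample = data.frame(id = ids,
                                         truth = as.integer(truth),
                                         predicted = as.integer(predicted),
                                         probability = as.numeric(scores))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report on %d samples\n", x$TP + x$TN + x$FP + x$FN))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy %.4f (95%% CI %.4f-%.4f)  MCC %.4f\n",
              x$accuracy, x$ci_low, x$ci_high, x$mcc))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  AUC %.4f\n",
              x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An [eval_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(is(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

# Stratified fold assignment: returns a list of k test-index vectors whose
# union is seq_along(y), each with near-equal class proportions.
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  folds <- vector("list", k)
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign_to <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}
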