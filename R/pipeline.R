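#' Correlation pruning, feature selection, tuning and evaluation
#'
#' The core training workflow on pre-extracted features: prune the training
#' matrix by Pearson correlation, run the chosen selector on the pruned
#' training matrix, tune the chosen classifier on the selected features and
#' evaluate on the held-out matrix.  Correlation filtering and selection see
#' only the training data; the test matrix is merely projected onto the
#' selected columns, so no information leaks from test to train.
#'
#' @param train_fm Labeled training `feature_matrix`.
#' @param test_fm Labeled held-out `feature_matrix` (NULL to skip
#'   evaluation).
#' @param method Selector: `"adtree"`, `"ga"` or `"l1svc"`.
#' @param algorithm Classifier family (default `"SVM"`).
#' @param cor_threshold Absolute-correlation pruning threshold (default
#'   0.9).
#' @param selector_args Named list of extra arguments for the selector
#'   ([select_adtree()], [select_ga()], [select_l1svc()]).
#' @param spec A [model_spec()]; defaults to `model_spec(algorithm,
#'   seed = seed)`.
#' @param seed Integer seed.
#' @return A list of class `pipeline_result`: `filter_report`, `selection`,
#'   `model`, `report` (NULL without `test_fm`) and `seed`.
#' @export
run_pipeline <- function(train_fm, test_fm = NULL,
                         method = c("adtree", "ga", "l1svc"),
                         algorithm = "SVM", cor_threshold = 0.9,
                         selector_args = list(), spec = NULL,
                         seed = 1L) {
  method <- match.arg(method)
  stopifnot(is(train_fm, "feature_matrix"), !is.null(train_fm$labels))
  filtered <- correlation_filter(train_fm, cor_threshold)
  selector <- switch(method, adtree = select_adtree, ga = select_ga,
                     l1svc = select_l1svc)
  if (method == "ga" && is.null(selector_args$config))
    selector_args$config <- ga_config(seed = seed)
  if (method == "adtree" && is.null(selector_args$seed))
    selector_args$seed <- seed
  selection <- do.call(selector, c(list(filtered$matrix), selector_args))
  if (length(selection$selected) == 0L)
    stop("the ", method, " selector returned no features; ",
         "weaken its regularization or lower the signal threshold",
         call. = FALSE)
  if (is.null(spec)) spec <- model_spec(algorithm, seed = seed)
  model <- train_model(filtered$matrix, selection = selection, spec = spec)
  report <- NULL
  if (!is.null(test_fm)) report <- evaluate_model(model, test_fm)
  structure(list(filter_report = filtered$report, selection = selection,
                 model = model, report = report, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$filter_report)
  print(x$selection)
  print(x$model)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' End-to-end workflow from sequences to an evaluated model
#'
#' Splits a labeled dataset, assembles the 1,103-column descriptor matrix
#' for both partitions, and runs [run_pipeline()] on them.
#'
#' @param dataset A [labeled_dataset()].
#' @param ss Named character vector of secondary-structure strings.
#' @param pssm Named list of [pssm_profile()] objects.
#' @param train_fraction Training fraction for the stratified split
#'   (default 0.8).
#' @param config A [descriptor_config()].
#' @param ... Passed to [run_pipeline()] (`method`, `algorithm`,
#'   `selector_args`, `spec`, `cor_threshold`).
#' @param seed Integer seed for the split and the pipeline.
#' @return A `pipeline_result` (see [run_pipeline()]) with the split
#'   attached as attribute `split`.
#' @export
run_workflow <- function(dataset, ss, pssm, train_fraction = 0.8,
                         config = descriptor_config(), ..., seed = 1L) {
  parts <- split_dataset(dataset, train_fraction, seed = seed)
  train_fm <- assemble_features(parts$train, ss, pssm, config)
  test_fm <- assemble_features(parts$test, ss, pssm, config)
  res <- run_pipeline(train_fm, test_fm, ..., seed = seed)
  attr(res, "split") <- parts
  res
}
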