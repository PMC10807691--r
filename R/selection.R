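#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two numeric vectors.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return The correlation in [-1, 1].
#' @export
pearson_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant feature: correlation undefined for zero variance",
         call. = FALSE)
  cor(x, y)
}

#' Prune highly correlated features
#'
#' Greedy pairwise elimination: compute the absolute Pearson correlation for
#' all feature pairs, then repeatedly take the pair with the largest
#' absolute correlation at or above `threshold` and drop the member with the
#' larger mean absolute correlation to all remaining features (ties drop the
#' later column).  Zero-variance features are removed first with a warning,
#' since the correlation is undefined for them.  Every surviving pair has
#' absolute correlation below `threshold`.
#'
#' @param fm A `feature_matrix` (or plain numeric matrix with column names).
#' @param threshold Absolute-correlation threshold in (0, 1]; default 0.9.
#' @return A list with `matrix` (the pruned `feature_matrix`) and `report`
#'   (class `correlation_report`: `pairs` data frame of removal-causing
#'   pairs with their correlations, `removed`, `threshold`).
#' @export
correlation_filter <- function(fm, threshold = 0.9) {
  x <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  labels <- if (is(fm, "feature_matrix")) fm$labels else NULL
  if (nrow(x) < 2L)
    stop("correlation filtering needs at least 2 samples", call. = FALSE)
  sds <- apply(x, 2, sd)
  constant <- colnames(x)[sds == 0]
  if (length(constant)) {
    warning("dropping ", length(constant),
            " constant feature(s) before correlation analysis")
    x <- x[, sds > 0, drop = FALSE]
  }
  cm <- abs(cor(x))
  diag(cm) <- 0
  pairs <- data.frame(feature_a = character(0), feature_b = character(0),
                      rho = numeric(0))
  removed <- character(0)
  while (ncol(cm) > 1L && max(cm) >= threshold) {
    hit <- which(cm == max(cm), arr.ind = TRUE)
    # deterministic pair choice: smallest row index, then column index
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- min(hit); j <- max(hit)
    mean_i <- mean(cm[i, -i]); mean_j <- mean(cm[j, -j])
    drop_idx <- if (mean_j >= mean_i) j else i
    pairs <- rbind(pairs, data.frame(
      feature_a = colnames(cm)[i], feature_b = colnames(cm)[j],
      rho = unname(cor(x[, colnames(cm)[i]], x[, colnames(cm)[j]]))))
    removed <- c(removed, colnames(cm)[drop_idx])
    cm <- cm[-drop_idx, -drop_idx, drop = FALSE]
  }
  keep <- setdiff(colnames(x), removed)
  out <- feature_matrix(x[, keep, drop = FALSE], labels)
  report <- structure(list(pairs = pairs,
                           removed = c(constant, removed),
                           constant = constant,
                           threshold = threshold),
                      class = "correlation_report")
  list(matrix = out, report = report)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d feature(s) removed at |rho| >= %.2f",
              length(x$removed), x$threshold))
  if (length(x$constant))
    cat(sprintf(" (%d constant)", length(x$constant)))
  cat("\n")
  invisible(x)
}

selection_result <- function(method, selected, provenance, config) {
  stopifnot(!anyDuplicated(selected))
  structure(list(method = method, selected = selected,
                 provenance = provenance, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d feature(s)\n", x$method,
              length(x$selected)))
  if (length(x$selected))
    cat(" ", paste(head(x$selected, 12), collapse = ", "),
        if (length(x$selected) > 12) "..." else "", "\n")
  invisible(x)
}

#' Write a selection result to disk
#'
#' Writes a JSON file with method, features, provenance and config, plus a
#' plain one-feature-per-line text file.
#'
#' @param result A `selection_result`.
#' @param json_path Path for the JSON file (NULL to skip).
#' @param txt_path Path for the feature-name list (NULL to skip).
#' @return Invisibly, `result`.
#' @export
write_selection <- function(result, json_path = NULL, txt_path = NULL) {
  stopifnot(is(result, "selection_result"))
  if (!is.null(json_path))
    jsonlite::write_json(list(method = result$method,
                              selected = result$selected,
                              provenance = result$provenance,
                              config = result$config),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(txt_path)) writeLines(result$selected, txt_path)
  invisible(result)
}

#' Feature selection via an alternating decision tree
#'
#' Fits an ADTree on the (already correlation-pruned) training matrix and
#' returns the unique features used in its rule conditions, in first-use
#' order.  With `tune_b = TRUE` the number of boosting rounds is chosen by
#' the cross-validated search of [adtree_tune_b()]; otherwise a fixed `B` is
#' used.
#'
#' @param fm A `feature_matrix` with labels, or a matrix plus `labels`.
#' @param labels Binary labels (unused when `fm` carries labels).
#' @param B Boosting rounds when `tune_b = FALSE` (default 15).
#' @param epsilon Score smoothing (default 1).
#' @param tune_b Search over B by cross-validation (default FALSE).
#' @param seed Integer seed (used by the B search).
#' @param ... Passed to [adtree_tune_b()] when `tune_b = TRUE`.
#' @return A `selection_result` with method `"adtree"`; provenance maps each
#'   selected feature to the index of the first rule using it.  The fitted
#'   model is attached as attribute `model`.
#' @export
select_adtree <- function(fm, labels = NULL, B = 15L, epsilon = 1,
                          tune_b = FALSE, seed = 1L, ...) {
  x <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (is.null(labels) && is(fm, "feature_matrix")) labels <- fm$labels
  model <- if (tune_b) {
    adtree_tune_b(x, labels, epsilon = epsilon, seed = seed, ...)
  } else {
    adtree_fit(x, labels, B = B, epsilon = epsilon)
  }
  feats <- adtree_used_features(model)
  rule_feats <- vapply(model$rules, `[[`, character(1), "feature")
  provenance <- lapply(feats, function(f)
    list(first_rule = unname(which(rule_feats == f)[1])))
  names(provenance) <- feats
  res <- selection_result("adtree", feats, provenance,
                          list(B = model$B, epsilon = epsilon,
                               tune_b = tune_b, seed = seed))
  attr(res, "model") <- model
  res
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size (default 50).
#' @param max_iter Number of generations (default 50).
#' @param p_mutation Per-bit mutation probability (default 0.03).
#' @param elitism_count Chromosomes carried over unchanged each generation
#'   (default ~5% of the population, at least 1).
#' @param cv_folds Folds of the cross-validated fitness (default 5).
#' @param rf_ntree Trees of the random-forest fitness model (default 100).
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, max_iter = 50L, p_mutation = 0.03,
                      elitism_count = max(1L, round(0.05 * pop_size)),
                      cv_folds = 5L, rf_ntree = 100L, seed = 1L) {
  stopifnot(pop_size >= 2L, max_iter >= 1L,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 p_mutation = p_mutation,
                 elitism_count = as.integer(elitism_count),
                 cv_folds = as.integer(cv_folds),
                 rf_ntree = as.integer(rf_ntree),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Cross-validated random-forest AUC of a feature subset: the GA fitness.
rf_cv_auc <- function(x, y, bits, config) {
  sel <- which(bits == 1L)
  if (length(sel) == 0L) return(0.5)  # random-classifier AUC, never fitted
  folds <- make_stratified_folds(y, config$cv_folds, config$seed)
  aucs <- vapply(seq_along(folds), function(f) {
    test_idx <- folds[[f]]
    fit <- with_local_seed(config$seed + 7919L * f,
      randomForest::randomForest(
        x[-test_idx, sel, drop = FALSE],
        factor(y[-test_idx], levels = c(0, 1)),
        ntree = config$rf_ntree,
        mtry = max(1L, floor(sqrt(length(sel))))))
    prob <- predict(fit, x[test_idx, sel, drop = FALSE],
                    type = "prob")[, "1"]
    roc_auc(y[test_idx], prob)
  }, numeric(1))
  mean(aucs)
}

#' Genetic-algorithm wrapper feature selection
#'
#' Binary-chromosome genetic algorithm: each chromosome encodes a feature
#' subset; fitness is the mean stratified k-fold cross-validated ROC AUC of
#' a random forest restricted to that subset (`mtry = floor(sqrt(#selected))`).
#' Rank-based parent selection, uniform crossover, per-bit mutation and
#' elitism; the best-ever chromosome's features are returned after
#' `max_iter` generations.  Fitness values are cached by chromosome, which
#' does not alter results.
#'
#' @param fm A `feature_matrix` with labels, or a matrix plus `labels`.
#' @param labels Binary labels (unused when `fm` carries labels).
#' @param config A [ga_config()].
#' @return A `selection_result` with method `"ga"`; provenance records the
#'   best fitness and the per-generation best-ever fitness trace
#'   (`fitness_history`, non-decreasing by elitism).
#' @export
select_ga <- function(fm, labels = NULL, config = ga_config()) {
  x <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (is.null(labels) && is(fm, "feature_matrix")) labels <- fm$labels
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < config$cv_folds)
    stop("need at least cv_folds samples per class", call. = FALSE)
  p <- ncol(x)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- rf_cv_auc(x, y, bits, config)
    cache[[key]] <- f
    f
  }
  result <- with_local_seed(config$seed, {
    pop <- matrix(rbinom(config$pop_size * p, 1L, 0.5),
                  nrow = config$pop_size)
    best_bits <- NULL
    best_fit <- -Inf
    history <- numeric(config$max_iter)
    for (gen in seq_len(config$max_iter)) {
      fit <- apply(pop, 1, fitness_of)
      top <- which.max(fit)
      if (fit[top] > best_fit) {
        best_fit <- fit[top]
        best_bits <- pop[top, ]
      }
      history[gen] <- best_fit
      # rank-based parent selection probabilities (best rank = highest)
      pr <- rank(fit, ties.method = "first")
      pr <- pr / sum(pr)
      elite <- pop[order(-fit)[seq_len(config$elitism_count)], ,
                   drop = FALSE]
      n_off <- config$pop_size - config$elitism_count
      offspring <- matrix(0L, n_off, p)
      for (k in seq_len(n_off)) {
        parents <- sample(config$pop_size, 2L, prob = pr)
        take1 <- runif(p) < 0.5
        child <- ifelse(take1, pop[parents[1], ], pop[parents[2], ])
        flip <- runif(p) < config$p_mutation
        child[flip] <- 1L - child[flip]
        offspring[k, ] <- child
      }
      pop <- rbind(elite, offspring)
    }
    list(bits = best_bits, fitness = best_fit, history = history)
  })
  feats <- colnames(x)[result$bits == 1L]
  selection_result("ga", feats,
                   list(best_fitness = result$fitness,
                        fitness_history = result$history),
                   unclass(config))
}

#' L1-penalized linear support vector classifier feature selection
#'
#' Fits a linear classifier minimizing
#' `C * sum(max(0, 1 - y * (x w + b))^2) + ||w||_1` (squared hinge loss,
#' L1 penalty, unpenalized intercept) by accelerated proximal gradient
#' descent on internally standardized features.  Features with nonzero
#' coefficients are selected; small `C` forces sparsity.
#'
#' @param fm A `feature_matrix` with labels, or a matrix plus `labels`.
#' @param labels Binary labels (unused when `fm` carries labels).
#' @param C Loss weight (regularization is relatively stronger for smaller
#'   `C`); default 0.01.
#' @param max_iter Maximum optimizer iterations (default 5000).
#' @param tol Convergence tolerance on the coefficient update (default 1e-7).
#' @return A `selection_result` with method `"l1svc"`; provenance carries
#'   the nonzero coefficients (on the standardized scale).
#' @export
select_l1svc <- function(fm, labels = NULL, C = 0.01, max_iter = 20000L,
                         tol = 1e-7) {
  x <- if (is(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (is.null(labels) && is(fm, "feature_matrix")) labels <- fm$labels
  y <- as_pm1(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  n <- nrow(xs); p <- ncol(xs)

  # Lipschitz constant of the smooth part: 2C * smax([X 1])^2,
  # estimated by power iteration.
  v <- rep(1 / sqrt(p + 1), p + 1)
  for (it in 1:30) {
    u <- cbind(xs, 1) %*% v
    v <- crossprod(cbind(xs, 1), u)
    v <- v / sqrt(sum(v^2))
  }
  smax2 <- sum((cbind(xs, 1) %*% v)^2)
  step <- 1 / (2 * C * smax2)

  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  objective <- function(w, b) {
    margin <- pmax(0, 1 - y * (drop(xs %*% w) + b))
    C * sum(margin^2) + sum(abs(w))
  }
  w <- rep(0, p); b <- 0
  zw <- w; zb <- b; t_acc <- 1
  obj_prev <- objective(w, b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- drop(xs %*% zw) + zb
    margin <- pmax(0, 1 - y * f)
    g <- -2 * C * y * margin
    grad_w <- drop(crossprod(xs, g))
    grad_b <- sum(g)
    w_new <- soft(zw - step * grad_w, step)
    b_new <- zb - step * grad_b
    obj_new <- objective(w_new, b_new)
    if (obj_new > obj_prev) {
      # adaptive restart: drop momentum when the objective rises
      t_acc <- 1
      zw <- w; zb <- b
      obj_prev <- objective(w, b)
      next
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    zw <- w_new + ((t_acc - 1) / t_new) * (w_new - w)
    zb <- b_new + ((t_acc - 1) / t_new) * (b_new - b)
    delta <- max(abs(c(w_new - w, b_new - b)))
    rel_obj <- abs(obj_prev - obj_new) / max(1, abs(obj_prev))
    w <- w_new; b <- b_new; t_acc <- t_new
    obj_prev <- obj_new
    if (delta < tol * max(1, max(abs(w))) || rel_obj < 1e-12) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("L1-SVC optimizer did not converge in ", max_iter,
         " iterations; increase max_iter or loosen tol", call. = FALSE)
  nz <- which(abs(w) > 1e-8)
  coefs <- as.list(w[nz])
  names(coefs) <- colnames(x)[nz]
  res <- selection_result("l1svc", colnames(x)[nz], coefs,
                          list(C = C, max_iter = max_iter, tol = tol))
  attr(res, "intercept") <- b
  res
}
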