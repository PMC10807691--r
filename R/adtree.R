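#' Alternating decision tree learner
#'
#' A boosted rule model in the Freund-Mason style.  The model is an ordered
#' list of rules, each with a precondition (a conjunction of path
#' predicates), a condition (`feature < threshold`) and two scores.  The
#' prediction for an instance is the root score plus, for every rule whose
#' precondition the instance satisfies, the true-branch score if the
#' condition holds and the false-branch score otherwise; the class is the
#' sign of this margin.  Each boosting round adds the rule minimizing the
#' splitting criterion
#' `Z = 2 * (sqrt(W+(p&c) W-(p&c)) + sqrt(W+(p&!c) W-(p&!c))) + W(!p)`
#' over all candidate preconditions (TRUE plus every prediction-node path of
#' the current tree) and all candidate thresholds (midpoints between
#' consecutive sorted unique values of each feature).
#'
#' @name adtree
NULL

# Z splitting criterion from summed class weights.
z_from_weights <- function(wp_c, wn_c, wp_nc, wn_nc, w_out) {
  2 * (sqrt(wp_c * wn_c) + sqrt(wp_nc * wn_nc)) + w_out
}

#' Z splitting criterion for a candidate rule
#'
#' @param w Positive instance weights.
#' @param y Labels in \{-1, +1\}.
#' @param precondition Logical vector: instances satisfying the precondition.
#' @param condition Logical vector: instances satisfying the condition.
#' @return The Z value (lower is better; 0 for a pure split).
#' @export
z_value <- function(w, y, precondition, condition) {
  if (length(w) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(all(w > 0), all(y %in% c(-1, 1)),
            length(precondition) == length(w),
            length(condition) == length(w))
  pc <- precondition & condition
  pnc <- precondition & !condition
  z_from_weights(sum(w[pc & y == 1]), sum(w[pc & y == -1]),
                 sum(w[pnc & y == 1]), sum(w[pnc & y == -1]),
                 sum(w[!precondition]))
}

as_pm1 <- function(labels) {
  if (all(labels %in% c(0, 1))) return(ifelse(labels == 1, 1, -1))
  if (all(labels %in% c(-1, 1))) return(as.numeric(labels))
  stop("labels must be binary (0/1 or -1/+1)", call. = FALSE)
}

# Candidate key comparison for deterministic tie-breaking: earlier feature,
# then smaller threshold, then precondition with fewer conjuncts.
candidate_beats <- function(cand, best, tol = 1e-12) {
  if (is.null(best)) return(TRUE)
  if (cand$z < best$z - tol) return(TRUE)
  if (cand$z > best$z + tol) return(FALSE)
  if (cand$feature_idx != best$feature_idx)
    return(cand$feature_idx < best$feature_idx)
  if (cand$threshold != best$threshold)
    return(cand$threshold < best$threshold)
  cand$n_conj < best$n_conj
}

#' Fit an alternating decision tree
#'
#' @param x Numeric matrix (samples x named features).
#' @param y Binary labels (0/1 or -1/+1), one per row.
#' @param B Number of boosting rounds (rules beyond the root); default 15.
#' @param epsilon Score-smoothing constant in
#'   `0.5 * log((W+ + epsilon) / (W- + epsilon))`; default 1.
#' @return An object of class `adtree` with elements `root_score`, `rules`
#'   (each rule: `precondition` — list of conjuncts `(feature, threshold,
#'   sense)` where sense TRUE means `feature < threshold` — plus `feature`,
#'   `threshold`, `score_true`, `score_false`, `z`), `epsilon`, `B` and
#'   `feature_names`.
#' @export
adtree_fit <- function(x, y, B = 15L, epsilon = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have column names", call. = FALSE)
  y <- as_pm1(y)
  if (length(y) != nrow(x))
    stop("labels must align with rows of x", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  w <- rep(1 / n, n)
  pos <- y == 1

  root_score <- 0.5 * log((sum(w[pos]) + epsilon) / (sum(w[!pos]) + epsilon))
  w <- w * exp(-y * root_score)

  # Prediction-node paths usable as preconditions; element 1 is TRUE.
  preconds <- list(list(mask = rep(TRUE, n), conjuncts = list()))
  orders <- lapply(seq_len(p), function(j) order(x[, j]))
  rules <- vector("list", B)

  for (round in seq_len(B)) {
    wp <- w * pos
    wn <- w * !pos
    best <- NULL
    for (pi in seq_along(preconds)) {
      m <- preconds[[pi]]$mask
      if (!any(m)) next
      w_out <- sum(w[!m])
      if (!is.null(best) && w_out > best$z + 1e-12) next  # Z >= W(!p)
      n_conj <- length(preconds[[pi]]$conjuncts)
      wp_tot <- sum(wp[m])
      wn_tot <- sum(wn[m])
      for (j in seq_len(p)) {
        o <- orders[[j]][m[orders[[j]]]]
        xv <- x[o, j]
        k_max <- length(xv)
        if (k_max < 2L) next
        boundary <- which(xv[-k_max] < xv[-1L])
        if (length(boundary) == 0L) next
        cwp <- cumsum(wp[o])[boundary]
        cwn <- cumsum(wn[o])[boundary]
        z <- z_from_weights(cwp, cwn, wp_tot - cwp, wn_tot - cwn, w_out)
        k <- which.min(z)  # first minimum = smallest threshold
        cand <- list(z = z[k], feature_idx = j,
                     threshold = (xv[boundary[k]] + xv[boundary[k] + 1L]) / 2,
                     n_conj = n_conj, precond_idx = pi)
        if (candidate_beats(cand, best)) best <- cand
      }
    }
    if (is.null(best)) {
      rules <- rules[seq_len(round - 1L)]
      warning("no splittable candidate left after ", round - 1L,
              " rounds; stopping early")
      break
    }
    m <- preconds[[best$precond_idx]]$mask
    cond <- x[, best$feature_idx] < best$threshold
    mc <- m & cond
    mnc <- m & !cond
    a <- 0.5 * log((sum(w[mc & pos]) + epsilon) /
                     (sum(w[mc & !pos]) + epsilon))
    b <- 0.5 * log((sum(w[mnc & pos]) + epsilon) /
                     (sum(w[mnc & !pos]) + epsilon))
    w[mc] <- w[mc] * exp(-y[mc] * a)
    w[mnc] <- w[mnc] * exp(-y[mnc] * b)
    parent_conj <- preconds[[best$precond_idx]]$conjuncts
    feat_name <- colnames(x)[best$feature_idx]
    rules[[round]] <- list(
      precondition = parent_conj,
      feature = feat_name, threshold = best$threshold,
      score_true = a, score_false = b, z = best$z)
    preconds <- c(preconds,
                  list(list(mask = mc,
                            conjuncts = c(parent_conj,
                                          list(list(feature = feat_name,
                                                    threshold = best$threshold,
                                                    sense = TRUE)))),
                       list(mask = mnc,
                            conjuncts = c(parent_conj,
                                          list(list(feature = feat_name,
                                                    threshold = best$threshold,
                                                    sense = FALSE))))))
  }
  structure(list(root_score = root_score,
                 rules = rules[!vapply(rules, is.null, logical(1))],
                 epsilon = epsilon, B = as.integer(B),
                 feature_names = colnames(x)),
            class = "adtree")
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("adtree: root score %.4f, %d rule(s), epsilon %.3g\n",
              x$root_score, length(x$rules), x$epsilon))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    pre <- if (length(r$precondition) == 0L) "TRUE" else
      paste(vapply(r$precondition, function(cj)
        sprintf("%s %s %.4g", cj$feature, if (cj$sense) "<" else ">=",
                cj$threshold), character(1)), collapse = " & ")
    cat(sprintf("  [%d] if (%s): %s < %.4g ? %+.4f : %+.4f\n",
                i, pre, r$feature, r$threshold, r$score_true, r$score_false))
  }
  invisible(x)
}

conjuncts_hold <- function(conjuncts, x) {
  if (length(conjuncts) == 0L) return(rep(TRUE, nrow(x)))
  m <- rep(TRUE, nrow(x))
  for (cj in conjuncts) {
    v <- x[, cj$feature] < cj$threshold
    m <- m & (if (cj$sense) v else !v)
  }
  m
}

#' Prediction margin of an alternating decision tree
#'
#' @param model An [adtree_fit()] model.
#' @param x Numeric matrix (or single named numeric vector) with all the
#'   features the model references.
#' @return Numeric vector of margins (root score plus satisfied-rule
#'   scores); the predicted class is 1 when the margin is >= 0.
#' @export
adtree_margin <- function(model, x) {
  stopifnot(is(model, "adtree"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  needed <- unique(unlist(lapply(model$rules, function(r)
    c(r$feature, vapply(r$precondition, `[[`, character(1), "feature")))))
  missing <- setdiff(needed, colnames(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  margin <- rep(model$root_score, nrow(x))
  for (r in model$rules) {
    pm <- conjuncts_hold(r$precondition, x)
    cm <- x[, r$feature] < r$threshold
    margin <- margin + ifelse(pm & cm, r$score_true,
                              ifelse(pm, r$score_false, 0))
  }
  margin
}

#' Predict classes from an alternating decision tree
#'
#' @inheritParams adtree_margin
#' @return Integer vector of 0/1 labels (margin 0 predicts positive).
#' @export
adtree_predict <- function(model, x) {
  as.integer(adtree_margin(model, x) >= 0)
}

#' Features used by an alternating decision tree
#'
#' @param model An [adtree_fit()] model.
#' @return Character vector of the unique feature names appearing in rule
#'   conditions, in first-use order (empty for a root-only model).
#' @export
adtree_used_features <- function(model) {
  stopifnot(is(model, "adtree"))
  unique(vapply(model$rules, `[[`, character(1), "feature"))
}

#' Tune the number of boosting rounds by cross-validation
#'
#' Samples `n_candidates` values of B uniformly from `b_range` (without
#' replacement where possible), scores each by stratified k-fold
#' cross-validated accuracy, and refits on the full data with the winner
#' (ties go to the smaller B).
#'
#' @inheritParams adtree_fit
#' @param n_candidates Number of candidate B values to sample (default 50).
#' @param b_range Inclusive range to sample from (default c(1, 100)).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed for sampling and fold assignment.
#' @return The fitted `adtree` for the selected B, with attributes
#'   `chosen_B` and `cv_accuracy`.
#' @export
adtree_tune_b <- function(x, y, n_candidates = 50L, b_range = c(1L, 100L),
                          cv_folds = 5L, epsilon = 1, seed = 1L) {
  y01 <- as.integer(as_pm1(y) == 1)
  candidates <- with_local_seed(seed, {
    pool <- seq(b_range[1], b_range[2])
    sort(unique(sample(pool, min(n_candidates, length(pool)))))
  })
  folds <- make_stratified_folds(y01, cv_folds, seed)
  cv_acc <- vapply(candidates, function(b) {
    mean(vapply(folds, function(test_idx) {
      fit <- adtree_fit(x[-test_idx, , drop = FALSE], y01[-test_idx],
                        B = b, epsilon = epsilon)
      mean(adtree_predict(fit, x[test_idx, , drop = FALSE]) ==
             y01[test_idx])
    }, numeric(1)))
  }, numeric(1))
  best_b <- candidates[which.max(cv_acc)]
  model <- adtree_fit(x, y01, B = best_b, epsilon = epsilon)
  attr(model, "chosen_B") <- best_b
  attr(model, "cv_accuracy") <- max(cv_acc)
  model
}

#' Serialize an alternating decision tree to JSON
#'
#' @param model An [adtree_fit()] model.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
adtree_to_json <- function(model, path = NULL) {
  stopifnot(is(model, "adtree"))
  payload <- list(root_score = model$root_score, epsilon = model$epsilon,
                  B = model$B, feature_names = model$feature_names,
                  rules = lapply(model$rules, function(r) {
                    list(precondition = lapply(r$precondition, function(cj)
                      list(feature = cj$feature, threshold = cj$threshold,
                           sense = cj$sense)),
                      feature = r$feature, threshold = r$threshold,
                      score_true = r$score_true,
                      score_false = r$score_false, z = r$z)
                  }))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize an alternating decision tree from JSON
#'
#' @param json A JSON string or a path to a JSON file produced by
#'   [adtree_to_json()].
#' @return An `adtree` model.
#' @export
adtree_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(root_score = payload$root_score,
                 rules = lapply(payload$rules, function(r) {
                   list(precondition = lapply(r$precondition, function(cj)
                     list(feature = cj$feature, threshold = cj$threshold,
                          sense = cj$sense)),
                     feature = r$feature, threshold = r$threshold,
                     score_true = r$score_true,
                     score_false = r$score_false, z = r$z)
                 }),
                 epsilon = payload$epsilon, B = as.integer(payload$B),
                 feature_names = unlist(payload$feature_names)),
            class = "adtree")
}
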