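test_that("Pearson correlation matches its defining formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_rho(x, 2 * x + 3), 1)
  expect_equal(pearson_rho(x, -x), -1)
  expect_equal(pearson_rho(x, c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_rho(c(5, 1, 9), c(2, 8, 3)),
               pearson_rho(c(2, 8, 3), c(5, 1, 9)))
  # affine invariance (sign flips with negative scale)
  set.seed(61)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_rho(3 * a - 1, b), pearson_rho(a, b))
  expect_equal(pearson_rho(-2 * a, b), -pearson_rho(a, b))
  expect_error(pearson_rho(rep(1, 5), 1:5), "constant")
})

test_that("correlation filtering removes exactly the redundant members", {
  set.seed(62)
  base <- matrix(rnorm(40 * 4), 40, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  dup <- cbind(base, f1_copy = base[, "f1"], f3_near = base[, "f3"] +
                 rnorm(40, sd = 1e-4))
  out <- correlation_filter(feature_matrix(
    `rownames<-`(dup, paste0("s", 1:40))), threshold = 0.9)
  expect_length(out$report$removed, 2L)
  expect_equal(ncol(out$matrix$x), 4L)
  # exactly one member of each planted pair was dropped
  expect_equal(sum(c("f1", "f1_copy") %in% colnames(out$matrix$x)), 1L)
  expect_equal(sum(c("f3", "f3_near") %in% colnames(out$matrix$x)), 1L)
  expect_true(all(abs(out$report$pairs$rho) >= 0.9))

  # orthogonal columns survive untouched
  ortho <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(ortho) <- paste0("o", 1:5)
  rownames(ortho) <- paste0("s", 1:20)
  out2 <- correlation_filter(feature_matrix(ortho), threshold = 0.9)
  expect_length(out2$report$removed, 0L)
})

test_that("filtered matrices satisfy the pairwise post-condition", {
  set.seed(63)
  for (case in 1:3) {
    x <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(paste0("s", 1:30),
                                                      paste0("v", 1:6)))
    x[, 5] <- x[, 1] * 1.01 + rnorm(30, sd = 0.01)
    x[, 6] <- -x[, 2] + rnorm(30, sd = 0.01)
    out <- correlation_filter(feature_matrix(x), threshold = 0.9)
    surv <- out$matrix$x
    cm <- abs(cor(surv))
    diag(cm) <- 0
    expect_lt(max(cm), 0.9)
    expect_true(all(out$report$removed %in% colnames(x)))
  }
})

test_that("the greedy drop policy agrees with caret's findCorrelation", {
  skip_if_not_installed("caret")
  set.seed(64)
  x <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("c", 1:8)))
  x[, 7] <- x[, 2] + rnorm(50, sd = 0.05)
  x[, 8] <- x[, 4] + rnorm(50, sd = 0.05)
  ours <- correlation_filter(feature_matrix(
    `rownames<-`(x, paste0("s", 1:50))), threshold = 0.9)
  caret_drop <- caret::findCorrelation(cor(x), cutoff = 0.9, exact = TRUE,
                                       names = TRUE)
  expect_setequal(ours$report$removed, caret_drop)
})

test_that("constant features are dropped with a warning before correlation", {
  set.seed(65)
  x <- cbind(matrix(rnorm(40), 20, 2), const = 1)
  colnames(x)[1:2] <- c("a", "b")
  rownames(x) <- paste0("s", 1:20)
  expect_warning(out <- correlation_filter(feature_matrix(x)), "constant")
  expect_false("const" %in% colnames(out$matrix$x))
  expect_true("const" %in% out$report$removed)
})

test_that("ADTree selection recovers a separable feature exactly", {
  set.seed(66)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(paste0("s", 1:60),
                                                    paste0("f", 1:5)))
  y <- as.integer(x[, 4] > 0)
  sel <- select_adtree(feature_matrix(x, y), B = 3)
  expect_identical(sel$selected[1], "f4")
  expect_lte(length(sel$selected), 3L)
  expect_equal(sel$provenance[["f4"]]$first_rule, 1L)
})

test_that("ADTree selection recovers planted informative features", {
  set.seed(67)
  hits <- 0L
  for (seed in 1:10) {
    with_seed_x <- withr::with_seed(seed, {
      x <- matrix(rnorm(50 * 25), 50, 25,
                  dimnames = list(paste0("s", 1:50), paste0("f", 1:25)))
      beta <- c(rep(2, 5), rep(0, 20))
      y <- as.integer(drop(x %*% beta) + rnorm(50, sd = 0.5) > 0)
      list(x = x, y = y)
    })
    sel <- select_adtree(feature_matrix(with_seed_x$x, with_seed_x$y),
                         B = 10)
    found <- sum(paste0("f", 1:5) %in% sel$selected)
    if (found >= 3) hits <- hits + 1L
  }
  expect_gte(hits, 6L)  # majority of seeds recover >= 3/5 informative
})

test_that("GA fitness definition and elitism hold on a small problem", {
  set.seed(68)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(paste0("s", 1:50),
                                                    paste0("f", 1:6)))
  y <- as.integer(x[, 2] > 0)
  cfg <- ga_config(pop_size = 10, max_iter = 5, rf_ntree = 40, seed = 3)
  sel <- select_ga(feature_matrix(x, y), config = cfg)
  hist <- sel$provenance$fitness_history
  expect_true(all(diff(hist) >= 0))  # elitism: best-ever never degrades
  expect_equal(max(hist), sel$provenance$best_fitness)
  expect_true(all(sel$selected %in% colnames(x)))
  # the all-ones chromosome's fitness is the full-feature CV AUC by definition
  full <- bactipred:::rf_cv_auc(x, y, rep(1L, 6), cfg)
  expect_gte(full, 0.5)
  expect_equal(bactipred:::rf_cv_auc(x, y, rep(1L, 6), cfg), full)
  # the empty chromosome is scored as a random classifier, never fitted
  expect_equal(bactipred:::rf_cv_auc(x, y, rep(0L, 6), cfg), 0.5)
})

test_that("GA reproduces identically under a fixed seed", {
  set.seed(69)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(paste0("s", 1:40),
                                                    paste0("f", 1:8)))
  y <- as.integer(x[, 1] > 0)
  cfg <- ga_config(pop_size = 8, max_iter = 3, rf_ntree = 30, seed = 9)
  s1 <- select_ga(feature_matrix(x, y), config = cfg)
  s2 <- select_ga(feature_matrix(x, y), config = cfg)
  expect_identical(s1$selected, s2$selected)
  expect_equal(s1$provenance$fitness_history, s2$provenance$fitness_history)
})

test_that("L1-SVC selection spans the regularization limits", {
  set.seed(70)
  x <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("s", 1:100), paste0("f", 1:10)))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  weak <- select_l1svc(feature_matrix(x, y), C = 10)
  expect_true(all(c("f1", "f2") %in% weak$selected))
  strong <- select_l1svc(feature_matrix(x, y), C = 1e-6)
  expect_length(strong$selected, 0L)
  # selected-set size is non-decreasing in C (<= 1 violation tolerated)
  sizes <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1),
                  function(C) length(select_l1svc(
                    feature_matrix(x, y), C = C)$selected), numeric(1))
  expect_lte(sum(diff(sizes) < 0), 1L)
  # provenance carries the nonzero coefficients
  expect_setequal(names(weak$provenance), weak$selected)
})

test_that("selection results serialize to JSON and plain lists", {
  set.seed(71)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(paste0("s", 1:40),
                                                    paste0("f", 1:4)))
  y <- as.integer(x[, 2] > 0)
  sel <- select_adtree(feature_matrix(x, y), B = 2)
  js <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_selection(sel, js, txt)
  expect_identical(readLines(txt), sel$selected)
  payload <- jsonlite::fromJSON(js)
  expect_identical(payload$method, "adtree")
  expect_identical(payload$selected, sel$selected)
})
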