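# Labeling schemes, metric panel, and stratified cross-validation.

test_that("condition-to-label mappings follow the stable/unstable grouping", {
  conds <- c("NW", "COM", "STROOP", "MLP")
  expect_equal(make_labels(conds, "two_class"),
               c("stable", "stable", "unstable", "unstable"))
  expect_equal(make_labels(conds, "four_class"), conds)
  three <- make_labels(conds, "three_class")
  expect_equal(three, c("NW", "COM", "STROOP", NA))
  expect_warning(make_labels(c("MLP", "MLP"), "three_class"), "no cycles")
  expect_error(make_labels(c("NW", "JOG"), "two_class"), "unknown")
})

test_that("a perfect prediction scores 1 on every metric", {
  y <- rep(c("a", "b", "c"), each = 10)
  scores <- matrix(0, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores[cbind(1:30, as.integer(factor(y)))] <- 1
  m <- compute_metrics(y, y, scores)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f_score, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$auc, 1)
})

test_that("binary metrics match the closed-form confusion values", {
  # TP = 40, FN = 10, FP = 10, TN = 40 (positive class 'p')
  y_true <- c(rep("p", 50), rep("n", 50))
  y_pred <- c(rep("p", 40), rep("n", 10), rep("p", 10), rep("n", 40))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$mcc, 0.6)
  expect_equal(m$mcc, naive_binary_mcc(40, 10, 10, 40))
})

test_that("the multiclass MCC reduces to the classical binary formula", {
  set.seed(50)
  for (i in 1:20) {
    y <- sample(c("x", "y"), 40, replace = TRUE)
    p <- sample(c("x", "y"), 40, replace = TRUE)
    conf <- table(factor(y, c("x", "y")), factor(p, c("x", "y")))
    tp <- conf[2, 2]; tn <- conf[1, 1]; fp <- conf[1, 2]; fn <- conf[2, 1]
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    ref <- if (denom == 0) 0 else naive_binary_mcc(tp, fn, fp, tn)
    expect_equal(compute_metrics(y, p)$mcc, ref, tolerance = 1e-12)
  }
})

test_that("two-class AUC equals exhaustive pair counting", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)    # ties included
    scores <- cbind(neg = 1 - s, pos = s)
    m <- compute_metrics(ifelse(y, "pos", "neg"),
                         ifelse(s > 0, "pos", "neg"), scores)
    pair_auc <- naive_auc(s, y)
    per_class <- mean(c(naive_auc(1 - s, !y), pair_auc))
    expect_equal(m$auc, per_class, tolerance = 1e-12)
  }
})

test_that("two-class AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(58)
  y <- sample(c("a", "b"), 80, replace = TRUE)
  s <- rnorm(80)
  m <- compute_metrics(y, y, cbind(a = -s, b = s))
  ref <- suppressMessages(pROC::auc(pROC::roc(y == "b", s,
                                              levels = c(FALSE, TRUE),
                                              direction = "<")))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(52)
  y <- sample(c("a", "b"), 60, replace = TRUE)
  s <- rnorm(60)
  sc1 <- cbind(a = -s, b = s)
  sc2 <- cbind(a = -expm1(s), b = expm1(s))   # monotone transform
  m1 <- compute_metrics(y, y, sc1)
  m2 <- compute_metrics(y, y, sc2)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
})

test_that("random scores give AUC 1/2 on balanced classes", {
  set.seed(53)
  aucs <- vapply(1:20, function(i) {
    y <- rep(c("a", "b"), 150)
    s <- runif(300)
    compute_metrics(y, sample(y), cbind(a = 1 - s, b = s))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("classes absent from y_true are excluded with a warning", {
  y <- rep(c("a", "b"), 10)
  p <- rep(c("a", "b"), 10)
  scores <- matrix(1 / 3, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(m <- compute_metrics(y, p, scores), "absent")
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
})

test_that("accuracy equals the confusion-matrix trace ratio", {
  set.seed(54)
  y <- sample(c("a", "b", "c"), 60, replace = TRUE)
  p <- sample(c("a", "b", "c"), 60, replace = TRUE)
  m <- compute_metrics(y, p)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
})

test_that("cross-validation tests every sample exactly once in balanced folds", {
  set.seed(55)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b"), n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + 4
  rep <- crossvalidate(X, y, model_spec("random_forest", 2, seed = 1),
                       k = 5, seed = 2)
  expect_equal(length(rep$folds), n)
  expect_true(all(table(rep$folds) == 20))   # fold sizes differ by <= 1
  expect_true(all(sort(unique(rep$folds)) == 1:5))
  # separable data: near-perfect out-of-fold predictions
  expect_gte(rep$metrics$accuracy, 0.97)
  expect_gte(rep$metrics$mcc, 0.94)
  # deterministic under seed
  rep2 <- crossvalidate(X, y, model_spec("random_forest", 2, seed = 1),
                        k = 5, seed = 2)
  expect_identical(rep$metrics$accuracy, rep2$metrics$accuracy)
  expect_identical(rep$folds, rep2$folds)
})

test_that("cross-validation refuses classes with fewer samples than folds", {
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- c(rep("a", 9), rep("b", 3))
  expect_error(crossvalidate(X, y, model_spec("svm", 2), k = 5, seed = 1),
               "at least k")
})

test_that("group-wise folds keep all of a subject's cycles together", {
  set.seed(56)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + 4
  groups <- rep(1:8, each = 10)
  rep <- crossvalidate(X, y, model_spec("random_forest", 2, seed = 1),
                       k = 4, seed = 3, groups = groups)
  for (g in unique(groups)) {
    expect_length(unique(rep$folds[groups == g]), 1)
  }
})

test_that("NA labels are dropped before fold assignment", {
  set.seed(57)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b", NA), n / 3)
  rep <- crossvalidate(X, y, model_spec("random_forest", 2, seed = 1),
                       k = 5, seed = 1)
  expect_equal(rep$n, 40)
})
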