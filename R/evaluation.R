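# Label schemes, the metric panel (accuracy, macro precision/recall/F-score,
# multiclass Matthews correlation, one-vs-rest ROC/AUC) and stratified
# k-fold cross-validation.

#' Map walking conditions to classification labels
#'
#' `four_class` keeps the four conditions; `three_class` keeps NW, STROOP
#' and COM and drops MLP cycles (returned as `NA`); `two_class` groups NW
#' and COM as `stable` and STROOP and MLP as `unstable`.
#'
#' @param conditions character vector of `"NW"`, `"STROOP"`, `"COM"`,
#'   `"MLP"`.
#' @param labeling `"four_class"`, `"three_class"` or `"two_class"`.
#' @return Character labels, `NA` for dropped cycles (with a warning if
#'   nothing remains).
#' @export
make_labels <- function(conditions,
                        labeling = c("four_class", "three_class",
                                     "two_class")) {
  labeling <- match.arg(labeling)
  conditions <- as.character(conditions)
  bad <- setdiff(unique(conditions), CONDITIONS)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  out <- switch(labeling,
    four_class = conditions,
    three_class = ifelse(conditions == "MLP", NA_character_, conditions),
    two_class = ifelse(conditions %in% c("NW", "COM"), "stable", "unstable"))
  if (all(is.na(out))) warning("no cycles remain under labeling ", labeling)
  out
}

# rank-based two-class AUC (probability a positive outranks a negative,
# ties counted half)
auc_rank <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[ord])
  fp <- cumsum(!positive[ord])
  keep <- c(diff(score[ord]) != 0, TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / max(sum(!positive), 1L)),
             tpr = c(0, tp[keep] / max(sum(positive), 1L)))
}

#' Classification metric panel
#'
#' Computes accuracy, macro-averaged precision, recall and F-score, the
#' multiclass Matthews correlation coefficient (covariance form, equal to
#' the classical binary MCC for two classes), and the macro one-vs-rest
#' ROC-area/AUC with per-class ROC curves. Classes absent from `y_true`
#' are excluded from the macro averages with a warning.
#'
#' @param y_true,y_pred label vectors.
#' @param scores samples x classes score matrix (column names = classes);
#'   needed for the ROC quantities.
#' @return A list with the metric values, `confusion` (true x predicted)
#'   and `roc_curves` (per class, FPR/TPR data frames).
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true/y_pred length mismatch")
  classes <- if (!is.null(scores) && !is.null(colnames(scores))) {
    colnames(scores)
  } else sort(unique(c(y_true, y_pred)))
  tf <- factor(y_true, levels = classes)
  pf <- factor(y_pred, levels = classes)
  conf <- table(true = tf, predicted = pf)
  n <- length(y_true)
  acc <- sum(diag(conf)) / n

  present <- classes[classes %in% y_true]
  if (length(present) < length(classes)) {
    warning("class(es) absent from y_true excluded from macro averages: ",
            paste(setdiff(classes, present), collapse = ", "))
  }
  prf <- vapply(present, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))

  # Matthews correlation, covariance (multiclass) form
  s <- n
  c_ok <- sum(diag(conf))
  t_k <- rowSums(conf)
  p_k <- colSums(conf)
  num <- c_ok * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  auc <- NA_real_
  roc_curves <- NULL
  if (!is.null(scores)) {
    if (is.null(colnames(scores))) colnames(scores) <- classes
    per_class <- vapply(present, function(cl) {
      auc_rank(scores[, cl], y_true == cl)
    }, numeric(1))
    auc <- mean(per_class, na.rm = TRUE)
    roc_curves <- lapply(setNames(present, present), function(cl) {
      roc_curve(scores[, cl], y_true == cl)
    })
  }

  list(accuracy = acc,
       precision = mean(prf[1, ]), recall = mean(prf[2, ]),
       f_score = mean(prf[3, ]), mcc = mcc,
       roc_area = auc, auc = auc,
       confusion = conf, roc_curves = roc_curves)
}

# stratified fold assignment; with groups, whole groups are kept together
# and greedily balanced over folds
make_folds <- function(y, k, seed, groups = NULL) {
  set.seed(seed)
  n <- length(y)
  folds <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gs <- sample(unique(groups))
    load <- numeric(k)
    for (g in gs) {
      idx <- which(groups == g)
      f <- which.min(load)
      folds[idx] <- f
      load[f] <- load[f] + length(idx)
    }
  }
  folds
}

#' Stratified k-fold cross-validated evaluation of one model
#'
#' Splits cycles into stratified folds, trains on k-1 folds (including any
#' per-fold standardization and, optionally, per-fold feature selection) and
#' tests on the held-out fold, each fold serving as the test set exactly
#' once. The metric panel is computed on the pooled out-of-fold predictions
#' (every sample predicted exactly once), and per-fold accuracies are
#' recorded alongside.
#'
#' @param X feature table or cycle tensor.
#' @param y class labels (`NA` rows/cycles are dropped).
#' @param spec a [model_spec()].
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param groups optional grouping vector (e.g. subject) for leakage-free
#'   group-wise folds.
#' @param per_fold_select if `TRUE` and `X` is a feature table, feature
#'   selection is re-run inside every training fold.
#' @param select_k,corr_threshold selection parameters when
#'   `per_fold_select` is enabled.
#' @param labeling annotation stored in the report.
#' @return An object of class `evaluation_report`.
#' @export
crossvalidate <- function(X, y, spec, k = 5L, seed = 1L, groups = NULL,
                          per_fold_select = FALSE, select_k = 40L,
                          corr_threshold = 0.8, labeling = NA_character_) {
  tensor_in <- length(dim(X)) == 3L
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]
    groups <- groups[keep]
    X <- if (tensor_in) X[, , keep, drop = FALSE] else X[keep, , drop = FALSE]
  }
  y <- as.character(y)
  counts <- table(y)
  if (is.null(groups) && any(counts < k)) {
    stop("every class needs at least k samples (k = ", k, ")")
  }
  n <- length(y)
  folds <- make_folds(y, k, seed, groups)
  classes <- sort(unique(y))
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  preds <- character(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (tensor_in) {
      Xtr <- X[, , tr, drop = FALSE]
      Xte <- X[, , te, drop = FALSE]
    } else {
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      if (per_fold_select) {
        sel <- select_features(Xtr, y[tr], k = select_k,
                               corr_threshold = corr_threshold)
        Xtr <- as_feature_matrix(Xtr)[, sel$selected, drop = FALSE]
        Xte <- as_feature_matrix(Xte)[, sel$selected, drop = FALSE]
      }
    }
    model <- train_model(spec, Xtr, y[tr])
    pr <- predict(model, Xte)
    preds[te] <- pr$labels
    scores[te, colnames(pr$scores)] <- pr$scores
    fold_acc[f] <- mean(pr$labels == y[te])
  }
  metrics <- compute_metrics(y, preds, scores)
  structure(
    list(labeling = labeling, model = spec$kind, n_classes = length(classes),
         classes = classes, metrics = metrics,
         fold_accuracy = fold_acc, folds = folds, k = k, seed = seed,
         n = n),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<evaluation_report> %s, %s (%d cycles, %d-fold CV)\n",
    x$model, x$labeling, x$n, x$k))
  cat(sprintf(
    "  accuracy %.4f  precision %.4f  recall %.4f  F %.4f  MCC %.4f  AUC %.4f\n",
    m$accuracy, m$precision, m$recall, m$f_score, m$mcc, m$auc))
  invisible(x)
}
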