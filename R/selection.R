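# Feature ranking by the absolute standardized Wilcoxon (Mann-Whitney)
# u-statistic and greedy low-redundancy subset selection.

#' Standardized two-sample Wilcoxon u-statistic
#'
#' Computes `U = #\{(i,j): x_i > y_j\} + 0.5 * #\{ties\}` and returns the
#' standardized statistic `z = (U - n1*n2/2) / sigma_U` with the
#' tie-corrected standard deviation
#' `sigma_U = sqrt(n1*n2/12 * ((n1+n2+1) - sum(t^3 - t) / ((n1+n2) * (n1+n2-1))))`.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return The signed z statistic (callers rank by `abs(z)`). If every value
#'   is tied across both samples, 0 is returned with attribute
#'   `degenerate = TRUE`.
#' @export
wilcoxon_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per sample")
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- rle(sort(comb))$lengths
  tie_term <- sum(ties^3) - sum(ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (U - n1 * n2 / 2) / sqrt(sigma2)
}

feature_columns <- function(table) {
  meta <- c("subject", "condition", "cycle_index")
  num <- vapply(table, is.numeric, logical(1))
  setdiff(names(table)[num], meta)
}

#' Rank features by class discriminability
#'
#' For two classes the score of a feature is `|z|` of [wilcoxon_z()] between
#' the class samples; for more than two classes it is the maximum `|z|` over
#' one-vs-rest splits. Features are sorted by descending score; ties are
#' broken by column order, so the ranking is deterministic.
#'
#' @param table feature data frame (metadata columns `subject`, `condition`,
#'   `cycle_index` are ignored) or numeric matrix.
#' @param labels class label per row; at least 2 classes with at least 2
#'   rows each.
#' @return A data frame with `feature` and `score`, ordered best first.
#' @export
rank_features <- function(table, labels) {
  if (is.data.frame(table)) {
    cols <- feature_columns(table)
    X <- as.matrix(table[cols])
  } else {
    X <- as.matrix(table)
    cols <- colnames(X)
    if (is.null(cols)) cols <- paste0("f", seq_len(ncol(X)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels/table length mismatch")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("need at least 2 samples per class")

  score_one <- function(col) {
    if (length(classes) == 2L) {
      abs(wilcoxon_z(col[labels == classes[1]], col[labels == classes[2]]))
    } else {
      max(vapply(classes, function(cl) {
        abs(wilcoxon_z(col[labels == cl], col[labels != cl]))
      }, numeric(1)))
    }
  }
  scores <- apply(X, 2L, score_one)
  ord <- order(-scores)   # stable: ties keep column order
  data.frame(feature = cols[ord], score = scores[ord],
             row.names = NULL)
}

#' Greedy low-redundancy feature selection
#'
#' Takes the top-ranked feature, then repeatedly adds the highest-ranked
#' unselected feature whose mean absolute Pearson correlation with the
#' already selected set does not exceed the threshold, until `k` features
#' are selected or the candidates are exhausted. Features highly correlated
#' with those already selected are thereby excluded.
#'
#' @param table feature data frame or matrix, as in [rank_features()].
#' @param labels class label per row.
#' @param k number of features to select.
#' @param corr_threshold maximal allowed mean `|cor|` with the selected set.
#' @return An object of class `selection_result` with `ranked` (the full
#'   ranking), `selected` (ordered names), `k` and `corr_threshold`.
#' @export
select_features <- function(table, labels, k = 40L, corr_threshold = 0.8) {
  if (k < 1L) stop("k must be >= 1")
  ranked <- rank_features(table, labels)
  if (is.data.frame(table)) {
    X <- as.matrix(table[feature_columns(table)])
  } else {
    X <- as.matrix(table)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  if (k > nrow(ranked)) {
    warning("k exceeds feature count; selecting all eligible features")
    k <- nrow(ranked)
  }
  selected <- character(0)
  sel_mat <- NULL
  for (f in ranked$feature) {
    if (length(selected) >= k) break
    col <- X[, f]
    if (length(selected)) {
      if (sd(col) == 0) next
      cors <- abs(suppressWarnings(cor(col, sel_mat)))
      cors[is.na(cors)] <- 1   # constant columns count as fully redundant
      if (mean(cors) > corr_threshold) next
    }
    selected <- c(selected, f)
    sel_mat <- cbind(sel_mat, col)
  }
  structure(
    list(ranked = ranked, selected = selected, k = k,
         corr_threshold = corr_threshold),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d of %d features (mean |cor| <= %.2f)\n",
    length(x$selected), nrow(x$ranked), x$corr_threshold))
  cat("top:", paste(head(x$selected, 5L), collapse = ", "), "\n")
  invisible(x)
}
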