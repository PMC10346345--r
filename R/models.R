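# The five classifiers: RBF-SVM, random forest and gradient-boosted trees on
# selected feature tables; stacked LSTM and ChronoNet on cycle tensors.

MODEL_KINDS <- c("svm", "random_forest", "xgboost", "rnn_lstm", "chrononet")

default_hyperparameters <- function(kind) {
  switch(kind,
    svm = list(cost = 1, gamma = NULL),   # NULL gamma = 1/(d * var(x))
    random_forest = list(num_trees = 500L, mtry = NULL),
    xgboost = list(nrounds = 300L, max_depth = 4L, eta = 0.1),
    rnn_lstm = list(units = 64L, dropout = 0.3, lr = 1e-3,
                    batch_size = 64L, epochs = 50L, patience = 10L,
                    val_frac = 0.15, clip = 5, weight_decay = 0,
                    noise_sd = 0),
    chrononet = list(filters = 32L, kernels = c(2L, 4L, 8L),
                     gru_units = 32L, dropout = 0.2, lr = 1e-3,
                     batch_size = 64L, epochs = 50L, patience = 10L,
                     val_frac = 0.15, clip = 5, weight_decay = 0,
                     noise_sd = 0, pool = "last"))
}

#' Classifier specification
#'
#' @param kind one of `"svm"`, `"random_forest"`, `"xgboost"`,
#'   `"rnn_lstm"`, `"chrononet"`.
#' @param n_classes number of classes (2, 3 or 4).
#' @param hyperparameters named list overriding the kind's defaults;
#'   unknown keys are rejected up front.
#' @param seed integer seed making training deterministic.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = MODEL_KINDS, n_classes = 2L,
                       hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (!n_classes %in% 2:4) stop("n_classes must be 2, 3 or 4")
  defaults <- default_hyperparameters(kind)
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", kind, ": ",
         paste(unknown, collapse = ", "))
  }
  hp <- modifyList(defaults, hyperparameters)
  structure(
    list(kind = kind, n_classes = as.integer(n_classes),
         hyperparameters = hp, seed = as.integer(seed)),
    class = "model_spec"
  )
}

is_deep <- function(kind) kind %in% c("rnn_lstm", "chrononet")

# standardization helpers: features column-wise, tensors channel-wise
standardizer_fit <- function(X) {
  if (length(dim(X)) == 3L) {
    mu <- apply(X, 1L, mean)
    sg <- apply(X, 1L, sd)
  } else {
    mu <- colMeans(X)
    sg <- apply(X, 2L, sd)
  }
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(mean = mu, sd = sg)
}

standardizer_apply <- function(X, st) {
  if (length(dim(X)) == 3L) {
    (X - st$mean) / st$sd        # recycles over the first (channel) margin
  } else {
    sweep(sweep(X, 2L, st$mean), 2L, st$sd, "/")
  }
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X[feature_columns(X)])
  storage.mode(X) <- "double"
  X
}

#' Train a classifier
#'
#' Feature models (`svm`, `random_forest`, `xgboost`) consume a cycles x
#' features table; sequence models (`rnn_lstm`, `chrononet`) consume a
#' channels x timesteps x cycles tensor. Features are standardized with
#' training-set mean and standard deviation before the SVM and the deep
#' models; deep models are trained single-threaded with Adam and record
#' per-epoch loss/accuracy history. Training is deterministic under the
#' spec's seed.
#'
#' @param spec a [model_spec()].
#' @param X feature table (data frame/matrix) or cycle tensor (3-d array).
#' @param y class labels, one per cycle.
#' @return An object of class `neurogait_model`.
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("y contains a single class")
  if (nlevels(y) != spec$n_classes) {
    stop("y has ", nlevels(y), " classes but spec declares ",
         spec$n_classes)
  }
  tensor_in <- length(dim(X)) == 3L
  if (is_deep(spec$kind) && !tensor_in) {
    stop(spec$kind, " requires a cycle tensor (channels x timesteps x cycles)")
  }
  if (!is_deep(spec$kind) && tensor_in) {
    stop(spec$kind, " requires a feature table, not a cycle tensor")
  }
  hp <- spec$hyperparameters
  set.seed(spec$seed)

  if (!tensor_in) {
    Xm <- as_feature_matrix(X)
    if (length(y) != nrow(Xm)) stop("X and y are not aligned")
    fit <- switch(spec$kind,
      svm = {
        st <- standardizer_fit(Xm)
        Xs <- standardizer_apply(Xm, st)
        gamma <- hp$gamma %||% (1 / (ncol(Xs) * max(var(as.vector(Xs)),
                                                    1e-12)))
        m <- e1071::svm(Xs, y, kernel = "radial", cost = hp$cost,
                        gamma = gamma, probability = TRUE)
        list(model = m, standardizer = st)
      },
      random_forest = {
        mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(Xm))))
        m <- ranger::ranger(x = Xm, y = y, num.trees = hp$num_trees,
                            mtry = mtry, probability = TRUE,
                            seed = spec$seed, num.threads = 1L)
        list(model = m, standardizer = NULL)
      },
      xgboost = {
        dtr <- xgboost::xgb.DMatrix(Xm, label = as.integer(y) - 1L)
        m <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = nlevels(y),
                        max_depth = hp$max_depth, eta = hp$eta,
                        nthread = 1L, seed = spec$seed),
          data = dtr, nrounds = hp$nrounds, verbose = 0)
        list(model = m, standardizer = NULL)
      })
    history <- NULL
    contract <- "features"
    feat_names <- colnames(Xm)
    arch <- NULL
  } else {
    if (length(y) != dim(X)[3]) stop("X and y are not aligned")
    st <- standardizer_fit(X)
    Xs <- standardizer_apply(X, st)
    y_int <- as.integer(y)
    if (spec$kind == "chrononet") {
      arch <- build_chrononet(dim(Xs)[1], dim(Xs)[2], nlevels(y),
                              filters = hp$filters, kernels = hp$kernels,
                              gru_units = hp$gru_units)
      arch$head$pool <- hp$pool
      params <- chrononet_init(arch)
      forward <- function(params, x, yo, dropout) {
        chrononet_forward(params, x, yo, arch, dropout)
      }
    } else {
      arch <- list(model = "rnn_lstm", units = hp$units,
                   n_channels = dim(Xs)[1], n_timesteps = dim(Xs)[2],
                   n_classes = nlevels(y))
      params <- lstm_init(dim(Xs)[1], nlevels(y), hp$units)
      forward <- function(params, x, yo, dropout) {
        lstm_forward(params, x, yo, hp$units, dropout)
      }
    }
    hp$seed <- spec$seed
    tr <- nn_train(params, forward, Xs, y_int, nlevels(y), hp)
    fit <- list(params = tr$params, forward = forward, standardizer = st)
    history <- tr$history
    contract <- "cycle_tensor"
    feat_names <- NULL
  }
  structure(
    list(spec = spec, fit = fit, classes = levels(y),
         input_contract = contract, feature_names = feat_names,
         training_history = history, architecture = arch),
    class = "neurogait_model"
  )
}

#' @export
print.neurogait_model <- function(x, ...) {
  cat(sprintf("<neurogait_model> %s, %d classes (%s), input: %s\n",
              x$spec$kind, length(x$classes),
              paste(x$classes, collapse = "/"), x$input_contract))
  if (!is.null(x$training_history)) {
    last <- tail(x$training_history, 1L)
    cat(sprintf("  trained %d epochs, final train acc %.3f\n",
                nrow(x$training_history), last$train_acc))
  }
  invisible(x)
}

#' Predict classes and class scores
#'
#' @param object a trained [train_model()] result.
#' @param newdata feature table or cycle tensor matching the model's input
#'   contract.
#' @param ... unused.
#' @return A list with `labels` (predicted class per sample, argmax with
#'   lowest-index tie-break) and `scores` (samples x classes matrix, rows
#'   summing to 1).
#' @export
predict.neurogait_model <- function(object, newdata, ...) {
  tensor_in <- length(dim(newdata)) == 3L
  if (object$input_contract == "cycle_tensor" && !tensor_in) {
    stop("model expects a cycle tensor")
  }
  if (object$input_contract == "features" && tensor_in) {
    stop("model expects a feature table")
  }
  K <- length(object$classes)
  if (object$input_contract == "features") {
    Xm <- as_feature_matrix(newdata)
    if (!is.null(object$feature_names) && !is.null(colnames(Xm))) {
      missing <- setdiff(object$feature_names, colnames(Xm))
      if (length(missing)) stop("missing feature columns: ",
                                paste(head(missing, 3L), collapse = ", "))
      Xm <- Xm[, object$feature_names, drop = FALSE]
    }
    scores <- switch(object$spec$kind,
      svm = {
        Xs <- standardizer_apply(Xm, object$fit$standardizer)
        pr <- predict(object$fit$model, Xs, probability = TRUE)
        attr(pr, "probabilities")[, object$classes, drop = FALSE]
      },
      random_forest = {
        pr <- predict(object$fit$model, data = Xm,
                      num.threads = 1L)$predictions
        pr[, object$classes, drop = FALSE]
      },
      xgboost = {
        pr <- predict(object$fit$model, xgboost::xgb.DMatrix(Xm))
        if (!is.matrix(pr)) pr <- matrix(pr, ncol = K, byrow = TRUE)
        dimnames(pr) <- list(NULL, object$classes)
        pr
      })
  } else {
    Xs <- standardizer_apply(newdata, object$fit$standardizer)
    scores <- nn_predict_probs(object$fit$params, object$fit$forward, Xs)
    colnames(scores) <- object$classes
  }
  scores <- scores / rowSums(scores)
  labels <- object$classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}
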