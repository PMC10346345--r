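# The five classifiers: specification validation, separable-data fits,
# determinism, input contracts, chance-level control, architecture layout.

test_that("model specifications are validated up front", {
  expect_error(model_spec("svm", n_classes = 5), "2, 3 or 4")
  expect_error(model_spec("svm", hyperparameters = list(bogus = 1)),
               "unknown hyperparameters")
  expect_error(model_spec("chrononet", hyperparameters = list(cost = 1)),
               "unknown hyperparameters")
  s <- model_spec("xgboost", 3, list(nrounds = 10L))
  expect_equal(s$hyperparameters$nrounds, 10L)
  expect_equal(s$hyperparameters$eta, 0.1)   # defaults retained
})

test_that("every feature model reaches training accuracy 1 on separable data", {
  toy <- toy_features()
  for (kind in c("svm", "random_forest", "xgboost")) {
    spec <- model_spec(kind, 2, seed = 1)
    m <- train_model(spec, toy$X, toy$y)
    pr <- predict(m, toy$X)
    expect_equal(mean(pr$labels == toy$y), 1, info = kind)
    expect_equal(unname(rowSums(pr$scores)), rep(1, nrow(toy$X)),
                 tolerance = 1e-6, info = kind)
  }
})

test_that("both sequence models reach training accuracy 1 on separable data", {
  toy <- toy_tensor()
  for (kind in c("rnn_lstm", "chrononet")) {
    spec <- model_spec(kind, 2,
                       list(epochs = 30L, batch_size = 16L, lr = 5e-3,
                            val_frac = 0),
                       seed = 1)
    m <- train_model(spec, toy$X, toy$y)
    pr <- predict(m, toy$X)
    expect_equal(mean(pr$labels == toy$y), 1, info = kind)
    # training history is recorded and the loss decreases
    h <- m$training_history
    expect_equal(nrow(h), 30)
    expect_lt(tail(h$train_loss, 1), h$train_loss[1])
    expect_true(all(diff(h$train_loss) < 0.05))
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  toy <- toy_features(seed = 2)
  for (kind in c("svm", "random_forest", "xgboost")) {
    p1 <- predict(train_model(model_spec(kind, 2, seed = 9), toy$X, toy$y),
                  toy$X)
    p2 <- predict(train_model(model_spec(kind, 2, seed = 9), toy$X, toy$y),
                  toy$X)
    expect_identical(p1$scores, p2$scores, info = kind)
  }
  tt <- toy_tensor(n = 24, seed = 2)
  spec <- model_spec("chrononet", 2, list(epochs = 3L, batch_size = 8L,
                                          val_frac = 0), seed = 9)
  p1 <- predict(train_model(spec, tt$X, tt$y), tt$X)
  p2 <- predict(train_model(spec, tt$X, tt$y), tt$X)
  expect_identical(p1$scores, p2$scores)
})

test_that("input contracts are enforced", {
  toy <- toy_features()
  tt <- toy_tensor(n = 24)
  expect_error(train_model(model_spec("rnn_lstm", 2), toy$X, toy$y),
               "cycle tensor")
  expect_error(train_model(model_spec("svm", 2), tt$X, tt$y),
               "feature table")
  expect_error(train_model(model_spec("svm", 2), toy$X,
                           rep("a", nrow(toy$X))), "single class")
  m <- train_model(model_spec("random_forest", 2, seed = 1), toy$X, toy$y)
  expect_error(predict(m, tt$X), "feature table")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(40)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- sample(rep(c("a", "b", "c", "d"), n / 4))
    rep <- crossvalidate(X, y, model_spec("random_forest", 4,
                                          list(num_trees = 150L), seed = s),
                         k = 5, seed = s)
    rep$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("the ChronoNet layout follows the dense-GRU inception design", {
  arch <- build_chrononet(64, 100, 4)
  expect_equal(arch$block_lengths, c(50L, 25L, 13L))
  expect_equal(arch$blocks[[1]]$kernels, c(2L, 4L, 8L))
  expect_equal(arch$blocks[[1]]$out_channels, 96L)   # 3 x 32 concatenated
  expect_equal(arch$blocks[[2]]$in_channels, 96L)
  expect_equal(vapply(arch$gru_layers, `[[`, 0L, "input_width"),
               c(96L, 32L, 64L, 96L))                # 4th GRU sees 3 x 32
  # serializable to JSON and back
  rt <- jsonlite::fromJSON(jsonlite::toJSON(arch, auto_unbox = TRUE),
                           simplifyVector = TRUE)
  expect_equal(rt$block_lengths, c(50L, 25L, 13L))
  expect_error(build_chrononet(64, 6, 2), ">= 8")
})

test_that("prediction labels are the argmax with lowest-index tie-break", {
  toy <- toy_features()
  m <- train_model(model_spec("random_forest", 2, seed = 1), toy$X, toy$y)
  pr <- predict(m, toy$X)
  expect_identical(pr$labels,
                   m$classes[max.col(pr$scores, ties.method = "first")])
  # same input twice gives identical output
  expect_identical(pr$scores, predict(m, toy$X)$scores)
})
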