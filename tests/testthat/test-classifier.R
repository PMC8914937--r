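test_that("model construction is seeded and its size follows the closed form", {
  cfg <- cnn_config(seed = 7)
  m1 <- build_cnn(c(12, 12, 1), 6, cfg)
  m2 <- build_cnn(c(12, 12, 1), 6, cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_cnn(c(12, 12, 1), 6, cnn_config(seed = 8))
  expect_false(identical(m3$params$W1, m1$params$W1))

  # closed-form parameter count for a 12x12x1 input, 6 classes:
  # conv1 128*(9*1)+128; conv2 128*(9*128)+128; after pools the map is
  # 1x1x128, dense 256*128+256; output 6*256+6
  expected <- (128 * 9 + 128) + (128 * 9 * 128 + 128) +
    (256 * 128 + 256) + (6 * 256 + 6)
  expect_equal(n_params(m1), expected)

  expect_error(build_cnn(c(5, 5, 1), 2), "too small")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(101)
  cfg <- cnn_config(n_filters = 4L, dense_units = 6L, seed = 3)
  m <- build_cnn(c(10, 10, 2), 3, cfg)
  X <- array(runif(10 * 10 * 2 * 4), dim = c(10, 10, 2, 4))
  y <- c(0L, 1L, 2L, 0L)
  res <- imucanvas:::.cnn_grad_cpp(m$params, X, y)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (i in idx) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- imucanvas:::.cnn_grad_cpp(pp, X, y)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- imucanvas:::.cnn_grad_cpp(pp, X, y)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("stratified folds partition the data and balance the classes", {
  labels <- rep(c("a", "b", "c", "d"), each = 25)
  folds <- stratified_kfold(labels, k = 10, seed = 4)
  expect_length(folds, 10)
  expect_equal(sort(unname(unlist(folds))), 1:100)
  expect_true(all(lengths(folds) == 10))
  for (f in folds) {
    counts <- table(factor(labels[f], levels = c("a", "b", "c", "d")))
    expect_true(max(counts) - min(counts) <= 1)
  }

  # uneven case: class sizes 13 across 5 folds differ by at most one
  labels <- rep(c("a", "b"), each = 13)
  folds <- stratified_kfold(labels, k = 5, seed = 4)
  expect_equal(sort(unname(unlist(folds))), 1:26)
  for (cl in c("a", "b")) {
    per <- vapply(folds, function(f) sum(labels[f] == cl), numeric(1))
    expect_true(max(per) - min(per) <= 1)
  }
})

test_that("stratified fraction splits preserve class proportions", {
  labels <- rep(c("a", "b", "c"), times = c(40, 30, 30))
  sp <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 2)
  expect_equal(sort(unname(unlist(sp))), seq_along(labels))
  expect_equal(sum(labels[sp$train] == "a"), 32)
  expect_equal(sum(labels[sp$test] == "a"), 4)
  expect_equal(sum(labels[sp$val] == "b"), 3)
  # same seed, same split
  expect_identical(sp, stratified_split(labels, c(0.8, 0.1, 0.1), seed = 2))
})

test_that("metrics follow the per-class formulas", {
  counts <- structure(
    data.frame(class = "pos", TP = 50, FP = 10, FN = 10, TN = 30),
    class = c("confusion_counts", "data.frame"))
  m <- classification_metrics(counts)
  expect_equal(m$accuracy[1], 0.80)
  expect_equal(m$precision[1], 50 / 60)
  expect_equal(m$recall[1], 50 / 60)
  expect_equal(m$f1[1], 50 / 60)

  # perfect predictions
  cc <- confusion_counts(c("a", "b", "a"), c("a", "b", "a"))
  m <- classification_metrics(cc)
  expect_true(all(m$accuracy == 1 & m$f1 == 1))

  # random confusion tables against an independent formula oracle
  set.seed(12)
  for (i in 1:20) {
    truth <- sample(letters[1:3], 60, replace = TRUE)
    pred <- sample(letters[1:3], 60, replace = TRUE)
    cc <- confusion_counts(truth, pred)
    m <- classification_metrics(cc)
    for (j in 1:3) {
      cl <- cc$class[j]
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(pred == cl) - tp
      fn <- sum(truth == cl) - tp
      tn <- 60 - tp - fp - fn
      expect_equal(cc$TP[j] + cc$FP[j] + cc$FN[j] + cc$TN[j], 60)
      expect_equal(m$accuracy[j], (tp + tn) / 60)
      expect_equal(m$precision[j], if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(m$recall[j], if (tp + fn == 0) 0 else tp / (tp + fn))
      pr <- m$precision[j]; re <- m$recall[j]
      expect_equal(m$f1[j], if (pr + re == 0) 0 else 2 * pr * re / (pr + re))
    }
    expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
    expect_true(all(m$f1 >= 0 & m$f1 <= 1))
  }
})

test_that("training separates linearly separable images and is reproducible", {
  # two classes of trivially distinct images: bright top half vs bright
  # bottom half, plus small seeded noise
  set.seed(5)
  n <- 40
  X <- array(0, dim = c(12, 12, 1, n))
  labels <- rep(c("top", "bottom"), each = n / 2)
  for (i in seq_len(n)) {
    img <- matrix(runif(144, 0, 0.2), 12, 12)
    if (labels[i] == "top") img[1:6, ] <- img[1:6, ] + 0.8
    else img[7:12, ] <- img[7:12, ] + 0.8
    X[, , 1, i] <- img
  }
  cfg <- cnn_config(n_filters = 8L, dense_units = 16L, epochs = 20L,
                    batch_size = 8L, patience = 5L, seed = 11)
  m <- build_cnn(c(12, 12, 1), 2, cfg)
  fit1 <- train_cnn(m, X, labels, split = c(0.8, 0.2))
  tr <- fit1$split$train
  acc_train <- mean(predict(fit1, X[, , , tr, drop = FALSE]) == labels[tr])
  expect_gte(acc_train, 0.99)

  fit2 <- train_cnn(m, X, labels, split = c(0.8, 0.2))
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history, fit2$history)
})
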