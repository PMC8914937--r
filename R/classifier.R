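#' Reference CNN configuration
#'
#' The network is fixed by design: two convolution blocks (128 filters of
#' size 3x3, ReLU, 2x2 max-pooling with stride 2), a 256-unit dense ReLU
#' layer and a softmax output, trained with cross-entropy loss, the Adam
#' optimizer and early stopping on validation loss.  Optimisation
#' hyper-parameters are explicit configuration with common defaults.
#'
#' @param n_filters filters per convolution layer.
#' @param dense_units units of the dense layer.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs (validation loss
#'   monitored; best weights restored).
#' @param seed RNG seed for weight initialisation and shuffling.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 128L, dense_units = 256L,
                       batch_size = 32L, epochs = 100L, lr = 1e-3,
                       patience = 10L, seed = 1L) {
  structure(list(n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cnn_config")
}

# spatial dimensions after the two conv (3x3 valid) + pool (2x2 s2) blocks
cnn_dims <- function(H, W) {
  h1 <- H - 2L; w1 <- W - 2L
  if (h1 < 2L || w1 < 2L) stop("input too small for a 3x3 convolution + pool")
  h1p <- h1 %/% 2L; w1p <- w1 %/% 2L
  h2 <- h1p - 2L; w2 <- w1p - 2L
  if (h2 < 1L || w2 < 1L) stop("input too small for the second conv block")
  h2p <- max(h2 %/% 2L, 1L); w2p <- max(w2 %/% 2L, 1L)
  if (h2 < 2L || w2 < 2L) stop("input too small for the second pooling layer")
  list(h1 = h1, w1 = w1, h1p = h1p, w1p = w1p,
       h2 = h2, w2 = w2, h2p = h2p, w2p = w2p)
}

#' Build the reference CNN
#'
#' Initialises the weights (He-scaled Gaussian, seeded) for a given input
#' shape and number of classes.
#'
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param n_classes number of activity classes (>= 2).
#' @param cfg a [cnn_config()].
#' @return object of class `cnn_model` holding the parameter matrices and
#'   shape metadata.
#' @export
build_cnn <- function(input_shape, n_classes, cfg = cnn_config()) {
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  C <- as.integer(input_shape[3])
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop("need at least 2 classes")
  d <- cnn_dims(H, W)
  Fn <- cfg$n_filters
  flat <- d$h2p * d$w2p * Fn
  set.seed(cfg$seed)
  he <- function(nrow, ncol, fan_in) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  params <- list(
    W1 = he(Fn, 9L * C, 9L * C), b1 = numeric(Fn),
    W2 = he(Fn, 9L * Fn, 9L * Fn), b2 = numeric(Fn),
    Wd = he(cfg$dense_units, flat, flat), bd = numeric(cfg$dense_units),
    Wo = he(n_classes, cfg$dense_units, cfg$dense_units),
    bo = numeric(n_classes))
  structure(list(params = params, input_shape = c(H, W, C),
                 n_classes = n_classes, cfg = cfg, dims = d,
                 classes = NULL),
            class = "cnn_model")
}

#' Number of trainable parameters of a model
#' @param model a `cnn_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %s, %d classes, %d parameters\n",
              paste(x$input_shape, collapse = "x"), x$n_classes,
              n_params(x)))
  cat("  conv(128,3x3)+ReLU -> pool(2x2,s2) -> conv(128,3x3)+ReLU -> pool\n")
  cat("  -> dense(256)+ReLU -> softmax\n")
  invisible(x)
}

#' Stack rendered images into a CNN input array
#'
#' @param images list of `rendered_image`s of identical shape.
#' @return numeric array `height x width x channels x n` scaled to `[0, 1]`.
#' @export
images_to_array <- function(images) {
  h <- images[[1]]$height; w <- images[[1]]$width; C <- images[[1]]$channels
  X <- array(0, dim = c(h, w, C, length(images)))
  for (i in seq_along(images)) X[, , , i] <- images[[i]]$pixels / 255
  X
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class with the given seed, then allots the requested
#' fractions per class, so per-class proportions are preserved to within one
#' item per part.
#'
#' @param labels character/factor vector.
#' @param fractions numeric vector summing to 1: `c(train, test)` or
#'   `c(train, val, test)`.
#' @param seed RNG seed.
#' @return list of integer index vectors named `train`, (`val`,) `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.8, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!length(fractions) %in% 2:3) stop("give 2 (train/test) or 3 fractions")
  set.seed(seed)
  parts <- lapply(fractions, function(f) integer(0))
  for (cl in sort(unique(as.character(labels)))) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    sizes <- floor(fractions * n)
    # distribute remainder first to parts a positive fraction left empty,
    # then to the earliest parts
    rem <- n - sum(sizes)
    if (rem > 0) {
      order_pref <- order(!(sizes == 0 & fractions > 0), seq_along(sizes))
      grow <- order_pref[seq_len(rem)]
      sizes[grow] <- sizes[grow] + 1L
    }
    at <- 0L
    for (p in seq_along(parts)) {
      parts[[p]] <- c(parts[[p]], idx[at + seq_len(sizes[p])])
      at <- at + sizes[p]
    }
  }
  parts <- lapply(parts, sort)
  names(parts) <- if (length(fractions) == 2) c("train", "test") else
    c("train", "val", "test")
  parts
}

#' Stratified k-fold partition
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of k disjoint, exhaustive integer index vectors; per-class
#'   counts across folds differ by at most one.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  set.seed(seed)
  folds <- vector("list", k)
  off <- 0L   # rotate the fold cursor across classes so fold sizes balance
  for (cl in sort(unique(as.character(labels)))) {
    idx <- sample(which(labels == cl))
    assign_to <- (seq_along(idx) - 1L + off) %% k + 1L
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    off <- (off + length(idx)) %% k
  }
  lapply(folds, sort)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

encode_labels <- function(labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes) - 1L
  if (anyNA(y)) stop("labels outside the model's class set")
  list(y = y, classes = classes)
}

model_loss <- function(model, X, y) {
  prob <- .cnn_predict_cpp(model$params, X)
  p <- prob[cbind(seq_along(y), y + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Train the reference CNN
#'
#' Minibatch Adam with a seeded shuffle each epoch, validation-loss early
#' stopping with best-weight restore.  The split argument selects the
#' evaluation protocol: explicit index sets, a fractions vector (the held
#' out validation part monitors early stopping; with only train/test
#' fractions a tenth of the training part is held out for monitoring), or
#' k-fold indices supplied externally.
#'
#' @param model a [build_cnn()] model.
#' @param X image array `h x w x c x n` (see [images_to_array()]).
#' @param labels class labels, length n.
#' @param split either a list of index vectors (`train`, optional `val`) or
#'   a fractions vector passed to [stratified_split()].
#' @param verbose print per-epoch progress.
#' @return the model with fitted parameters, plus `history` (data.frame of
#'   per-epoch train/val loss) and `classes`.
#' @export
train_cnn <- function(model, X, labels, split = c(0.8, 0.1, 0.1),
                      verbose = FALSE) {
  cfg <- model$cfg
  enc <- encode_labels(labels)
  if (length(enc$classes) < 2) stop("need at least 2 classes")
  if (min(table(labels)) < 2) stop("need at least 2 examples per class")
  if (is.numeric(split)) {
    split <- stratified_split(labels, split, seed = cfg$seed)
  }
  train_idx <- split$train
  val_idx <- split$val
  if (is.null(val_idx)) {
    # hold a tenth of the training part out for early-stopping monitoring
    inner <- stratified_split(labels[train_idx], c(0.9, 0.1),
                              seed = cfg$seed + 1L)
    val_idx <- train_idx[inner$test]
    train_idx <- train_idx[inner$train]
  }
  if (length(train_idx) == 0 || length(val_idx) == 0) {
    stop("degenerate split: empty train or validation part")
  }
  y <- enc$y
  Xtr <- X[, , , train_idx, drop = FALSE]
  ytr <- y[train_idx]
  Xval <- X[, , , val_idx, drop = FALSE]
  yval <- y[val_idx]

  params <- model$params
  st <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  set.seed(cfg$seed + 2L)
  n <- length(ytr)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bidx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      res <- .cnn_grad_cpp(params, Xtr[, , , bidx, drop = FALSE], ytr[bidx])
      upd <- adam_step(params, res$grads, st, cfg$lr)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + res$loss; nb <- nb + 1L
    }
    model$params <- params
    vloss <- model_loss(model, Xval, yval)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = vloss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / nb, vloss))
    }
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$classes <- enc$classes
  model$history <- history
  model$split <- c(list(train = train_idx, val = val_idx),
                   split[setdiff(names(split), c("train", "val"))])
  model
}

#' Predict class labels
#'
#' @param object a trained `cnn_model`.
#' @param X image array.
#' @param ... unused.
#' @return character vector of predicted labels (or 0-based class indices
#'   when the model was never given label names).
#' @export
predict.cnn_model <- function(object, X, ...) {
  prob <- .cnn_predict_cpp(object$params, X)
  k <- max.col(prob, ties.method = "first")
  if (is.null(object$classes)) k - 1L else object$classes[k]
}

#' Per-class confusion counts
#'
#' One-vs-rest TP/FP/FN/TN per class, from which the standard metrics
#' follow.
#'
#' @param truth,pred label vectors of equal length.
#' @param classes class universe (default: union of labels, sorted).
#' @return data.frame of class `confusion_counts`: `class`, `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = tn,
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("confusion_counts", "data.frame"))
}

#' Classification metrics from confusion counts
#'
#' Per class: accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall); each
#' ratio is 0 when its denominator is 0.  The macro average over classes is
#' appended, and the overall (micro) accuracy, i.e. the fraction of
#' correctly classified instances, is reported as attribute
#' `overall_accuracy`.
#'
#' @param counts a [confusion_counts()] data.frame.
#' @return data.frame of class `metrics_report`: `class`, `accuracy`,
#'   `precision`, `recall`, `f1`, with a final `macro` row.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  acc <- safe_div(counts$TP + counts$TN,
                  counts$TP + counts$TN + counts$FP + counts$FN)
  prec <- safe_div(counts$TP, counts$TP + counts$FP)
  rec <- safe_div(counts$TP, counts$TP + counts$FN)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  out <- data.frame(class = counts$class, accuracy = acc, precision = prec,
                    recall = rec, f1 = f1, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(class = "macro", accuracy = mean(acc),
                               precision = mean(prec), recall = mean(rec),
                               f1 = mean(f1)))
  n <- counts$TP[1] + counts$TN[1] + counts$FP[1] + counts$FN[1]
  attr(out, "overall_accuracy") <- sum(counts$TP) / n
  structure(out, class = c("metrics_report", "data.frame"))
}

#' Evaluate a trained model
#'
#' @param model a trained `cnn_model`.
#' @param X image array.
#' @param labels true labels.
#' @return list with `counts` ([confusion_counts()]), `metrics`
#'   ([classification_metrics()]) and `accuracy` (overall fraction correct).
#' @export
evaluate_cnn <- function(model, X, labels) {
  pred <- predict(model, X)
  classes <- if (!is.null(model$classes)) model$classes else
    sort(unique(as.character(labels)))
  counts <- confusion_counts(labels, pred, classes)
  metrics <- classification_metrics(counts)
  list(counts = counts, metrics = metrics,
       accuracy = attr(metrics, "overall_accuracy"))
}
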