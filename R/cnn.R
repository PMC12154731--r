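## Binary CNN for reactive/non-reactive classification of carbonyl contour
## images: architecture spec, stratified splitting, training with early
## stopping and best-weight restoration, prediction with confidences, and
## evaluation with confusion counts.

#' CNN architecture and training specification
#'
#' Defaults: three valid 3x3 convolution blocks (8/16/32 filters, ReLU,
#' 2x2 max-pool), a 32-unit ReLU dense layer, and a single sigmoid output
#' unit; binary cross-entropy, Adam at 1e-3, batch 32, at most 50 epochs
#' with patience-5 early stopping on the validation loss. Inputs are
#' grayscale crops downscaled from 720 x 550 by `downscale`.
#'
#' @param input_shape `c(height, width, channels)` of the preprocessed
#'   image; channels must be 1.
#' @param conv_filters filter counts, one per conv block.
#' @param kernel square kernel size.
#' @param dense dense head width.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience, epochs.
#' @param min_delta smallest validation-loss decrease that counts as an
#'   improvement for the patience counter (the restored weights are always
#'   those of the minimal-validation-loss epoch).
#' @param downscale block-averaging factor from the 720 x 550 crop to
#'   `input_shape` (must divide both crop dimensions).
#' @return list of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = NULL, conv_filters = c(8, 16, 32),
                     kernel = 3, dense = 32, lr = 1e-3, batch_size = 32,
                     max_epochs = 30, patience = 5, min_delta = 1e-3,
                     downscale = 10) {
  if (is.null(input_shape)) {
    if (RENDER_H %% downscale != 0 || CROP_W %% downscale != 0)
      stop_lapnet("downscale must divide the ", RENDER_H, " x ", CROP_W,
                  " crop", class = "lapnet_validation")
    input_shape <- c(RENDER_H %/% downscale, CROP_W %/% downscale, 1L)
  }
  if (length(input_shape) != 3L || input_shape[3] != 1L)
    stop_lapnet("input_shape must be c(height, width, 1)",
                class = "lapnet_validation")
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), dense = as.integer(dense),
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 downscale = as.integer(downscale)),
            class = "cnn_spec")
}

# precompute all layer index structures for a spec
build_cnn_layers <- function(spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- 1L
  conv <- list(); pool <- list()
  for (i in seq_along(spec$conv_filters)) {
    conv[[i]] <- conv_setup(H, W, C, spec$kernel, spec$conv_filters[i])
    H <- conv[[i]]$H_out; W <- conv[[i]]$W_out; C <- spec$conv_filters[i]
    pool[[i]] <- pool_setup(H, W, C)
    H <- pool[[i]]$H2; W <- pool[[i]]$W2
  }
  list(conv = conv, pool = pool, flat_dim = H * W * C)
}

init_cnn_params <- function(spec, layers, seed) {
  set.seed(seed)
  params <- list()
  for (i in seq_along(layers$conv)) {
    l <- layers$conv[[i]]
    params[[paste0("W_conv", i)]] <-
      matrix(stats::rnorm(l$Q * l$Cout, 0, sqrt(2 / l$Q)), l$Q, l$Cout)
    params[[paste0("b_conv", i)]] <- numeric(l$Cout)
  }
  params$W_dense <- matrix(stats::rnorm(layers$flat_dim * spec$dense, 0,
                                        sqrt(2 / layers$flat_dim)),
                           layers$flat_dim, spec$dense)
  params$b_dense <- numeric(spec$dense)
  params$W_out <- matrix(stats::rnorm(spec$dense, 0, sqrt(2 / spec$dense)),
                         spec$dense, 1)
  params$b_out <- 0
  params
}

cnn_forward <- function(layers, params, X, keep_cache = FALSE) {
  A <- X
  caches <- if (keep_cache) vector("list", length(layers$conv)) else NULL
  for (i in seq_along(layers$conv)) {
    cf <- conv_forward(layers$conv[[i]], A, params[[paste0("W_conv", i)]],
                       params[[paste0("b_conv", i)]])
    R <- relu_forward(cf$out)
    pf <- pool_forward(layers$pool[[i]], R)
    if (keep_cache)
      caches[[i]] <- list(conv = cf, pre_relu = cf$out, relu_cols = ncol(R),
                          pool = pf)
    A <- pf$out
  }
  Zd <- sweep(A %*% params$W_dense, 2, params$b_dense, "+")
  Rd <- relu_forward(Zd)
  z <- drop(Rd %*% params$W_out) + params$b_out
  list(z = z, flat = A, Zd = Zd, Rd = Rd, caches = caches)
}

cnn_backward <- function(layers, params, fwd, dz) {
  N <- length(dz)
  grads <- list()
  dzm <- matrix(dz, N, 1)
  grads$W_out <- crossprod(fwd$Rd, dzm)
  grads$b_out <- sum(dz)
  dRd <- tcrossprod(dzm, params$W_out)
  dZd <- relu_backward(fwd$Zd, dRd)
  grads$W_dense <- crossprod(fwd$flat, dZd)
  grads$b_dense <- colSums(dZd)
  dA <- tcrossprod(dZd, params$W_dense)
  for (i in rev(seq_along(layers$conv))) {
    cache <- fwd$caches[[i]]
    dR <- pool_backward(layers$pool[[i]], cache$pool, dA, cache$relu_cols)
    dZ <- relu_backward(cache$pre_relu, dR)
    cb <- conv_backward(layers$conv[[i]], cache$conv, dZ,
                        params[[paste0("W_conv", i)]])
    grads[[paste0("W_conv", i)]] <- cb$dW
    grads[[paste0("b_conv", i)]] <- cb$db
    dA <- cb$dX
  }
  grads
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset by class with a seeded shuffle; per-class
#' validation counts follow the ratio with deterministic rounding.
#'
#' @param dataset a `contour_dataset` (or any list with a binary `labels`
#'   element, or a bare label vector).
#' @param ratio train:validation ratio, as `c(4, 1)` or `"4:1"`.
#' @param seed RNG seed.
#' @return list of class `dataset_split` with disjoint index vectors
#'   `train` and `val` whose union is the full dataset.
#' @export
split_dataset <- function(dataset, ratio = c(4, 1), seed = 1) {
  labels <- if (is.list(dataset)) dataset$labels else dataset
  if (is.null(labels) || length(labels) == 0L)
    stop_lapnet("dataset is empty", class = "lapnet_contract")
  if (is.character(ratio))
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  frac_val <- ratio[2] / sum(ratio)
  set.seed(seed)
  val <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_val <- as.integer(round(length(idx) * frac_val))
    val <- c(val, sample(idx)[seq_len(n_val)])
  }
  val <- sort(val)
  structure(list(train = setdiff(seq_along(labels), val), val = val,
                 ratio = ratio, seed = seed),
            class = "dataset_split")
}

# stack dataset images (already downscaled) into a row-per-image matrix
dataset_matrix <- function(images, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]
  X <- matrix(0, length(images), H * W)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (inherits(img, "rendered_map")) img <- img$pixels
    if (nrow(img) != H || ncol(img) != W) {
      f <- nrow(img) %/% H
      if (f >= 1 && nrow(img) == H * f && ncol(img) == W * f)
        img <- downscale_image(img, f)
      else
        stop_lapnet("image shape ", nrow(img), " x ", ncol(img),
                    " does not match the CNN input ", H, " x ", W,
                    class = "lapnet_contract")
    }
    X[i, ] <- as.vector(img)
  }
  X
}

# first index of the minimal validation loss: the epoch whose weights an
# early-stopped fit restores
select_best_epoch <- function(val_losses) which.min(val_losses)

#' Train the contour-image CNN with early stopping
#'
#' Minibatch Adam on binary cross-entropy. Training halts when the
#' validation loss has not improved for `spec$patience` epochs (or at
#' `spec$max_epochs`), and the returned weights are those of the
#' minimal-validation-loss epoch. The per-epoch history records training
#' (running minibatch averages) and validation loss and accuracy.
#'
#' @param dataset a `contour_dataset`.
#' @param split a `dataset_split` from [split_dataset()].
#' @param spec a [cnn_spec()].
#' @param seed RNG seed for weight initialization and shuffling.
#' @param verbose print per-epoch progress.
#' @return list of class `cnn_model` with `spec`, `params`, `history`,
#'   `best_epoch`.
#' @export
cnn_train <- function(dataset, split, spec = cnn_spec(), seed = 1,
                      verbose = FALSE) {
  layers <- build_cnn_layers(spec)
  X <- dataset_matrix(dataset$images, spec$input_shape)
  y <- as.numeric(dataset$labels)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE]; yva <- y[split$val]
  params <- init_cnn_params(spec, layers, derive_seed(seed, 1))
  state <- adam_init(params)
  history <- NULL
  best <- list(loss = Inf, epoch = 0L, params = params)
  signif_best <- Inf
  wait <- 0L
  n <- nrow(Xtr)
  for (epoch in seq_len(spec$max_epochs)) {
    set.seed(derive_seed(seed, 100 + epoch))
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      ii <- perm[start:min(start + spec$batch_size - 1L, n)]
      fwd <- cnn_forward(layers, params, Xtr[ii, , drop = FALSE],
                         keep_cache = TRUE)
      p <- sigmoid(fwd$z)
      loss <- bce_loss(fwd$z, ytr[ii])
      if (!is.finite(loss))
        stop_lapnet("non-finite training loss at epoch ", epoch,
                    " (learning rate too high or corrupt inputs)",
                    class = "lapnet_numeric")
      dz <- (p - ytr[ii]) / length(ii)
      grads <- cnn_backward(layers, params, fwd, dz)
      upd <- adam_step(params, grads, state, spec$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss * length(ii)
      ep_correct <- ep_correct + sum((p >= 0.5) == (ytr[ii] == 1))
    }
    va <- cnn_forward(layers, params, Xva)
    val_loss <- bce_loss(va$z, yva)
    val_acc <- mean((sigmoid(va$z) >= 0.5) == (yva == 1))
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / n,
                                train_acc = ep_correct / n,
                                val_loss = val_loss, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f/%.4f  val %.4f/%.4f", epoch,
                      ep_loss / n, ep_correct / n, val_loss, val_acc))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, epoch = epoch, params = params)
    if (val_loss < signif_best - spec$min_delta) {
      signif_best <- val_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(spec = spec, params = best$params, history = history,
                 best_epoch = best$epoch, seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  h <- x$history
  cat("cnn_model:", paste(x$spec$input_shape, collapse = "x"), "input,",
      paste(x$spec$conv_filters, collapse = "/"), "filters\n")
  cat("  epochs run:", nrow(h), " best epoch:", x$best_epoch,
      " val acc at best:", h$val_acc[x$best_epoch], "\n")
  invisible(x)
}

preprocess_images <- function(images, spec) {
  if (inherits(images, "rendered_map") || is.matrix(images))
    images <- list(images)
  dataset_matrix(images, spec$input_shape)
}

#' Classify contour images with a trained CNN
#'
#' Deterministic given fixed weights. The label is `reactive` iff the raw
#' sigmoid score is `>= 0.5`; the confidence is `max(raw, 1 - raw)`.
#'
#' @param model a `cnn_model`.
#' @param images a cropped `rendered_map`, a grayscale matrix at the CNN
#'   input size (or an integer multiple of it, which is block-averaged
#'   down), or a list of either.
#' @return data.frame with columns `raw`, `label`, `confidence`.
#' @export
cnn_predict <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  X <- preprocess_images(images, model$spec)
  layers <- build_cnn_layers(model$spec)
  raw <- numeric(nrow(X))
  for (start in seq(1, nrow(X), by = 256)) {
    ii <- start:min(start + 255L, nrow(X))
    raw[ii] <- sigmoid(cnn_forward(layers, model$params,
                                   X[ii, , drop = FALSE])$z)
  }
  classification_result(raw)
}

#' Label and confidence from raw sigmoid scores
#'
#' @param raw scores in `[0, 1]`.
#' @return data.frame with `raw`, `label` (`reactive` iff `raw >= 0.5`)
#'   and `confidence` (`max(raw, 1 - raw)`).
#' @export
classification_result <- function(raw) {
  if (any(raw < 0 | raw > 1))
    stop_lapnet("raw scores must lie in [0, 1]", class = "lapnet_contract")
  data.frame(raw = raw,
             label = ifelse(raw >= 0.5, "reactive", "nonreactive"),
             confidence = pmax(raw, 1 - raw))
}

#' Evaluate a CNN on labeled images
#'
#' @param model a `cnn_model`.
#' @param images list of images (see [cnn_predict()]).
#' @param labels true binary labels (1 reactive / 0 nonreactive).
#' @return list of class `cnn_evaluation`: `accuracy`, `confusion` (2x2
#'   true-by-predicted counts), `results` (per-image predictions with truth
#'   and confidences, for violin-style summaries).
#' @export
cnn_evaluate <- function(model, images, labels) {
  if (length(labels) == 0L)
    stop_lapnet("labeled set is empty", class = "lapnet_contract")
  pred <- cnn_predict(model, images)
  truth <- factor(ifelse(labels == 1, "reactive", "nonreactive"),
                  levels = c("reactive", "nonreactive"))
  predf <- factor(pred$label, levels = c("reactive", "nonreactive"))
  confusion <- table(truth = truth, predicted = predf)
  pred$truth <- as.character(truth)
  structure(list(accuracy = mean(pred$label == pred$truth),
                 confusion = confusion, results = pred),
            class = "cnn_evaluation")
}

#' @export
print.cnn_evaluation <- function(x, ...) {
  cat("cnn_evaluation: accuracy", round(x$accuracy, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Save a CNN model as a self-describing JSON container
#'
#' Stores the spec, weights (with dimensions), history and best epoch in
#' one JSON file at full numeric precision.
#'
#' @param model a `cnn_model`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
cnn_save <- function(model, path) {
  payload <- list(
    format = "lapnet_cnn", version = 1L,
    spec = unclass(model$spec),
    best_epoch = model$best_epoch,
    history = model$history,
    params = lapply(model$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CNN model saved by [cnn_save()]
#' @param path path to the JSON container.
#' @return a `cnn_model`.
#' @export
cnn_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "lapnet_cnn"))
    stop_lapnet("not a lapnet CNN container: ", path, class = "lapnet_io")
  spec <- do.call(cnn_spec, payload$spec[c("input_shape", "conv_filters",
                                           "kernel", "dense", "lr",
                                           "batch_size", "max_epochs",
                                           "patience", "min_delta",
                                           "downscale")])
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(list(spec = spec, params = params, history = payload$history,
                 best_epoch = payload$best_epoch),
            class = "cnn_model")
}
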