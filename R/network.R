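# HawksheadNet: a lightweight CNN for binary tile classification.
# Architecture: input (s, s, 3) -> conv(128, 3x3, same, ReLU) -> maxpool(2)
# -> conv(64, 3x3, same, ReLU) -> maxpool(2) -> global average pool ->
# dropout -> dense(128, ReLU) -> dense(64, ReLU) -> dense(1, sigmoid).
# Optimisation is Adam on binary cross-entropy in a compiled single-threaded
# backend; optional L1/L2 penalties act on the dense weights.

#' HawksheadNet architecture specification
#'
#' @param input_size Input edge length in pixels (square, 3 channels); must
#'   be divisible by 4 for the two pooling stages. Default 128.
#' @param conv_filters Filter counts of the two convolutional layers.
#' @param kernel_size Convolution kernel edge (square, stride 1, same
#'   padding).
#' @param dense_widths Widths of the three dense layers; the last must be 1.
#' @param dropout_rate Dropout fraction applied after global average pooling.
#' @param l1,l2 Regularisation penalties on dense-layer weights.
#' @return An object of class `hawkshead_spec`.
#' @export
hawkshead_spec <- function(input_size = 128L, conv_filters = c(128L, 64L),
                           kernel_size = 3L, dense_widths = c(128L, 64L, 1L),
                           dropout_rate = 0.25, l1 = 0, l2 = 0) {
  if (input_size %% 4L != 0L) abort("input_size must be divisible by 4")
  if (length(conv_filters) != 2L) abort("conv_filters must have two entries")
  if (length(dense_widths) != 3L || dense_widths[3] != 1L)
    abort("dense_widths must be three widths ending in 1")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (l1 < 0 || l2 < 0) abort("l1 and l2 must be >= 0")
  structure(
    list(input_size = as.integer(input_size),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         dense_widths = as.integer(dense_widths),
         dropout_rate = dropout_rate, l1 = l1, l2 = l2),
    class = "hawkshead_spec"
  )
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(prod(dims), -lim, lim), dims[1], dims[2])
}

#' Build a HawksheadNet model
#'
#' Initialises weights (Glorot-uniform, seeded) for the architecture in
#' `spec`.
#'
#' @param spec A [hawkshead_spec()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `hawkshead_model` with elements `spec`,
#'   `weights`, and (after training) `history`.
#' @export
build_hawkshead <- function(spec = hawkshead_spec(), seed = 1L) {
  k <- spec$kernel_size
  f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
  d1 <- spec$dense_widths[1]; d2 <- spec$dense_widths[2]
  weights <- with_seed(seed, list(
    W1 = glorot(k * k * 3, k * k * f1, c(k * k * 3, f1)),
    b1 = numeric(f1),
    W2 = glorot(k * k * f1, k * k * f2, c(k * k * f1, f2)),
    b2 = numeric(f2),
    U1 = glorot(f2, d1, c(f2, d1)),
    c1 = numeric(d1),
    U2 = glorot(d1, d2, c(d1, d2)),
    c2 = numeric(d2),
    U3 = glorot(d2, 1, c(d2, 1)),
    c3 = numeric(1)
  ))
  structure(list(spec = spec, weights = weights, history = NULL, seed = seed),
            class = "hawkshead_model")
}

#' Layer-by-layer description of a model
#'
#' @param model A `hawkshead_model` or `tl_head_model`.
#' @return Data frame with columns `layer`, `type`, and `output` (channel or
#'   unit count), in forward order.
#' @export
model_layers <- function(model) {
  if (inherits(model, "hawkshead_model")) {
    s <- model$spec
    data.frame(
      layer = c("input", "conv1", "maxpool1", "conv2", "maxpool2",
                "global_average_pool", "dropout", "dense1", "dense2", "dense3"),
      type = c("input", "conv2d", "maxpool2d", "conv2d", "maxpool2d",
               "gap", "dropout", "dense", "dense", "dense_sigmoid"),
      output = c(3L, s$conv_filters[1], s$conv_filters[1], s$conv_filters[2],
                 s$conv_filters[2], s$conv_filters[2], s$conv_filters[2],
                 s$dense_widths),
      stringsAsFactors = FALSE
    )
  } else if (inherits(model, "tl_head_model")) {
    data.frame(
      layer = c("feature_extractor", "flatten", "dropout", "dense1", "dense2", "dense3"),
      type = c("frozen_extractor", "flatten", "dropout", "dense", "dense", "dense_sigmoid"),
      output = c(model$feature_dim, model$feature_dim, model$feature_dim,
                 model$dense_widths),
      stringsAsFactors = FALSE
    )
  } else abort("unknown model class")
}

#' Trainable parameter count
#'
#' For a `tl_head_model` only the head counts: the extractor is frozen.
#'
#' @param model A `hawkshead_model` or `tl_head_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' @export
print.hawkshead_model <- function(x, ...) {
  cat(sprintf("HawksheadNet: input %dx%dx3, conv (%s), dense (%s), dropout %.2f, %d parameters%s\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$conv_filters, collapse = ", "),
              paste(x$spec$dense_widths, collapse = ", "),
              x$spec$dropout_rate, count_params(x),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Resize and scale tiles into a model input batch
#'
#' Bilinear (half-pixel-centre) resize of 512x512 RGB tiles to the network
#' input size, with pixel values scaled to `[0, 1]`.
#'
#' @param tiles A `tile_set`, a list of `(512, 512, 3)` arrays, or a single
#'   such array.
#' @param target_size Output edge length (128 for HawksheadNet, 224 for the
#'   transfer-learning head).
#' @param expected_size Required input tile edge length.
#' @return A `(target_size, target_size, 3, N)` array with values in
#'   `[0, 1]`.
#' @export
preprocess_tiles <- function(tiles, target_size = 128L, expected_size = 512L) {
  pix <- if (inherits(tiles, "tile_set")) tiles$pixels
         else if (is.array(tiles) && length(dim(tiles)) == 3L) list(tiles)
         else if (is.list(tiles)) tiles
         else abort("tiles must be a tile_set, a list of arrays, or one array")
  n <- length(pix)
  t_ <- as.integer(target_size)
  out <- array(0, dim = c(t_, t_, 3L, n))
  for (i in seq_len(n)) {
    img <- pix[[i]]
    d <- dim(img)
    if (length(d) != 3L || d[1] != expected_size || d[2] != expected_size || d[3] != 3L)
      abort("tile ", i, " is not ", expected_size, "x", expected_size, "x3")
    out[, , , i] <- resize_bilinear_cpp(as.numeric(img), d[1], d[2], 3L, t_, t_) / 255
  }
  out
}

#' Training configuration
#'
#' Defaults are desk-scale: batch 128 and 20 epochs (the full-scale settings
#' of batch 512 and 100 epochs remain available by argument).
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum (and, without early stopping, exact) epochs.
#' @param optimiser Only `"adam"` is implemented.
#' @param loss Only `"bce"` (binary cross-entropy) is implemented.
#' @param early_stop_patience Epochs without validation-accuracy improvement
#'   before stopping, or `NULL` to always run `max_epochs`.
#' @param lr_decay_rate,lr_decay_steps Exponential learning-rate decay
#'   (factor per step count), used by the transfer-learning head.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 20L, optimiser = "adam", loss = "bce",
                         early_stop_patience = NULL,
                         lr_decay_rate = 0.96, lr_decay_steps = 1000L,
                         seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (batch_size < 1L) abort("batch_size must be >= 1")
  if (!identical(optimiser, "adam")) abort("only the adam optimiser is implemented")
  if (!identical(loss, "bce")) abort("only binary cross-entropy loss is implemented")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), optimiser = optimiser, loss = loss,
         early_stop_patience = early_stop_patience,
         lr_decay_rate = lr_decay_rate, lr_decay_steps = as.integer(lr_decay_steps),
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

check_train_inputs <- function(x_train, y_train, x_val, y_val, input_size) {
  for (nm in c("x_train", "x_val")) {
    x <- get(nm)
    d <- dim(x)
    if (length(d) != 4L || d[1] != input_size || d[2] != input_size || d[3] != 3L)
      abort(nm, " must be a (", input_size, ", ", input_size, ", 3, N) array")
  }
  if (dim(x_train)[4] == 0L || dim(x_val)[4] == 0L)
    abort("training and validation sets must be non-empty")
  if (length(y_train) != dim(x_train)[4] || length(y_val) != dim(x_val)[4])
    abort("label length does not match batch size")
  if (length(unique(y_train)) < 2L)
    abort("training set contains a single class; both classes are required")
}

#' Train a model
#'
#' Runs seeded minibatch Adam on binary cross-entropy. A `hawkshead_model`
#' trains for `max_epochs` unless `early_stop_patience` is set; a
#' `tl_head_model` defaults to early stopping on validation accuracy with
#' patience 3 and exponential learning-rate decay. Execution is
#' single-threaded and bit-reproducible for a given seed.
#'
#' @param model A `hawkshead_model` or `tl_head_model`.
#' @param x_train,x_val Input arrays `(s, s, 3, N)` with values in `[0, 1]`
#'   (see [preprocess_tiles()]).
#' @param y_train,y_val 0/1 label vectors.
#' @param config A [train_config()].
#' @return The model with updated weights and a `history` data frame
#'   (`epoch, train_loss, val_loss, train_acc, val_acc`, one row per epoch
#'   run).
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        config = train_config()) {
  UseMethod("train_model")
}

history_frame <- function(res) {
  data.frame(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss, val_loss = res$val_loss,
    train_acc = res$train_acc, val_acc = res$val_acc
  )
}

#' @rdname train_model
#' @export
train_model.hawkshead_model <- function(model, x_train, y_train, x_val, y_val,
                                        config = train_config()) {
  s <- model$spec$input_size
  check_train_inputs(x_train, y_train, x_val, y_val, s)
  patience <- if (is.null(config$early_stop_patience)) -1L
              else as.integer(config$early_stop_patience)
  res <- cnn_train_cpp(model$weights,
                       as.numeric(x_train), as.numeric(y_train), dim(x_train)[4],
                       as.numeric(x_val), as.numeric(y_val), dim(x_val)[4],
                       s, config$learning_rate, config$batch_size,
                       config$max_epochs, model$spec$dropout_rate,
                       model$spec$l1, model$spec$l2,
                       patience, config$seed, config$verbose)
  model$weights <- res$weights
  model$history <- history_frame(res)
  model$train_config <- config
  model
}

#' Model scores for a batch of tiles
#'
#' @param object A trained (or freshly built) model.
#' @param newdata A preprocessed input array, or a `tile_set` (preprocessed
#'   internally to the model's input size).
#' @param ... Unused.
#' @return If `newdata` carries tile metadata (a `tile_set`), a prediction
#'   data frame (`tile_id, slide_id, x_origin, y_origin, score, label`),
#'   order-preserving; otherwise a numeric score vector in `[0, 1]`.
#' @export
predict.hawkshead_model <- function(object, newdata, ...) {
  info <- NULL
  if (inherits(newdata, "tile_set")) {
    info <- newdata$info
    newdata <- preprocess_tiles(newdata, object$spec$input_size)
  }
  d <- dim(newdata)
  s <- object$spec$input_size
  if (length(d) != 4L || d[1] != s || d[2] != s || d[3] != 3L)
    abort("newdata must be a (", s, ", ", s, ", 3, N) array or a tile_set")
  scores <- cnn_forward_cpp(object$weights, as.numeric(newdata), d[4], s)
  prediction_records(scores, info)
}

prediction_records <- function(scores, info) {
  if (is.null(info)) return(scores)
  data.frame(
    tile_id = info$tile_id, slide_id = info$slide_id,
    x_origin = info$x_origin, y_origin = info$y_origin,
    score = scores, label = info$label, stringsAsFactors = FALSE
  )
}

## ---- transfer-learning head ----------------------------------------------

#' Build a classification head on a frozen feature extractor
#'
#' The head is flatten -> dropout -> dense(32, ReLU) -> dense(16, ReLU) ->
#' dense(1, sigmoid); only the head weights are trainable. The extractor is
#' an arbitrary R function mapping an input batch `(input_size, input_size,
#' 3, N)` to an `N x feature_dim` feature matrix, and is never modified.
#'
#' @param feature_extractor Frozen extractor function.
#' @param feature_dim Length of the flattened feature vector the extractor
#'   emits.
#' @param input_size Input edge length the extractor expects (default 224).
#' @param dense_widths Head layer widths, final width 1.
#' @param dropout_rate Dropout on the flattened features during training.
#' @param seed Integer seed for head initialisation.
#' @return An object of class `tl_head_model`.
#' @export
build_tl_head <- function(feature_extractor, feature_dim, input_size = 224L,
                          dense_widths = c(32L, 16L, 1L), dropout_rate = 0.25,
                          seed = 1L) {
  if (!is.function(feature_extractor)) abort("feature_extractor must be a function")
  if (feature_dim < 1L) abort("feature_dim must be >= 1")
  if (length(dense_widths) != 3L || dense_widths[3] != 1L)
    abort("dense_widths must be three widths ending in 1")
  d <- as.integer(feature_dim)
  w1 <- dense_widths[1]; w2 <- dense_widths[2]
  weights <- with_seed(seed, list(
    U1 = glorot(d, w1, c(d, w1)), c1 = numeric(w1),
    U2 = glorot(w1, w2, c(w1, w2)), c2 = numeric(w2),
    U3 = glorot(w2, 1, c(w2, 1)), c3 = numeric(1)
  ))
  structure(
    list(feature_extractor = feature_extractor, feature_dim = d,
         input_size = as.integer(input_size),
         dense_widths = as.integer(dense_widths),
         dropout_rate = dropout_rate, weights = weights, history = NULL),
    class = "tl_head_model"
  )
}

#' @export
print.tl_head_model <- function(x, ...) {
  cat(sprintf("Transfer-learning head: frozen extractor (%d features, input %d), dense (%s), %d trainable parameters\n",
              x$feature_dim, x$input_size,
              paste(x$dense_widths, collapse = ", "), count_params(x)))
  invisible(x)
}

extract_features <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4L || d[1] != model$input_size || d[2] != model$input_size || d[3] != 3L)
    abort("extractor requires (", model$input_size, ", ", model$input_size,
          ", 3, N) input")
  f <- model$feature_extractor(x)
  if (!is.matrix(f) || nrow(f) != d[4] || ncol(f) != model$feature_dim)
    abort("feature_extractor must return an N x feature_dim matrix")
  t(f)  # features as columns for the backend
}

#' @rdname train_model
#' @export
train_model.tl_head_model <- function(model, x_train, y_train, x_val, y_val,
                                      config = train_config(learning_rate = 5e-4,
                                                            early_stop_patience = 3L)) {
  ftr <- extract_features(model, x_train)
  fv <- extract_features(model, x_val)
  if (ncol(ftr) == 0L || ncol(fv) == 0L)
    abort("training and validation sets must be non-empty")
  if (length(unique(y_train)) < 2L)
    abort("training set contains a single class; both classes are required")
  patience <- if (is.null(config$early_stop_patience)) -1L
              else as.integer(config$early_stop_patience)
  res <- mlp_train_cpp(model$weights, ftr, as.numeric(y_train), fv,
                       as.numeric(y_val), config$learning_rate,
                       config$batch_size, config$max_epochs,
                       model$dropout_rate, config$lr_decay_rate,
                       config$lr_decay_steps, patience, config$seed,
                       config$verbose)
  model$weights <- res$weights
  model$history <- history_frame(res)
  model$train_config <- config
  model
}

#' @rdname predict.hawkshead_model
#' @export
predict.tl_head_model <- function(object, newdata, ...) {
  info <- NULL
  if (inherits(newdata, "tile_set")) {
    info <- newdata$info
    newdata <- preprocess_tiles(newdata, object$input_size)
  }
  f <- extract_features(object, newdata)
  scores <- mlp_forward_cpp(object$weights, f)
  prediction_records(scores, info)
}

#' Save / load model weights
#'
#' Weights and architecture are written as one YAML file (full precision),
#' the package's standard single-file model format.
#'
#' @param model A `hawkshead_model`.
#' @param path Output file.
#' @return `save_model_weights()`: `path`, invisibly. `read_model_weights()`:
#'   a `hawkshead_model` (untrained history).
#' @export
save_model_weights <- function(model, path) {
  if (!inherits(model, "hawkshead_model")) abort("only hawkshead_model weights are serialised")
  obj <- list(
    spec = unclass(model$spec),
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    })
  )
  writeLines(yaml::as.yaml(obj, precision = 17L), path)
  invisible(path)
}

#' @rdname save_model_weights
#' @export
read_model_weights <- function(path) {
  obj <- yaml::read_yaml(path)
  spec <- do.call(hawkshead_spec, obj$spec)
  weights <- lapply(obj$weights, function(w) {
    d <- unlist(w$dim)
    x <- as.numeric(unlist(w$data))
    if (length(d) == 2L) matrix(x, d[1], d[2]) else x
  })
  structure(list(spec = spec, weights = weights, history = NULL),
            class = "hawkshead_model")
}

#' Write a training history to CSV
#'
#' @param model A trained model (with `history`).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) abort("model has no training history")
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
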