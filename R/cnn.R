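#' Convolutional regressor configuration
#'
#' The default architecture: five 5x5 convolutional layers with 32, 64, 128,
#' 216 and 512 kernels, zero-padding (1 px) on the second and third
#' convolutional layers only, 2x2 stride-2 average pooling after the first
#' four, dropout at rate 0.5 on the flattened features, and one fully
#' connected layer with three outputs (LFW, LDW, LA). With a 128 x 128 x 3
#' input every feature-map side stays integral and the map entering the
#' fully connected layer is 1 x 1 x 512.
#'
#' @param input_side Input image side, pixels.
#' @param conv_channels Integer vector of length 5: kernels per conv layer.
#' @param padded_layers Indices (1-based) of conv layers with 1-px zero
#'   padding.
#' @param pool `"average"` or `"max"` (the architecture uses average; max is
#'   exposed for experimentation and handled in the shape plan only).
#' @param dropout_rate Dropout rate on the flattened features.
#' @param outputs Number of regression outputs.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(input_side = 128L, conv_channels = c(32L, 64L, 128L, 216L, 512L),
                       padded_layers = c(2L, 3L), pool = c("average", "max"),
                       dropout_rate = 0.5, outputs = 3L) {
  pool <- match.arg(pool)
  if (length(conv_channels) != 5L) abort("`conv_channels` must have length 5.")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must lie in [0, 1).")
  structure(list(input_side = as.integer(input_side),
                 conv_channels = as.integer(conv_channels),
                 padded_layers = as.integer(padded_layers), pool = pool,
                 dropout_rate = dropout_rate, outputs = as.integer(outputs)),
            class = "cnn_config")
}

#' Training schedule configuration
#'
#' Stochastic gradient descent with an initial learning rate of 0.001
#' dropped by a factor of 0.1 every 20 epochs, mini-batches of 128, up to
#' 300 epochs; targets standardized per trait with training-set statistics.
#'
#' @param lr0 Initial learning rate (> 0).
#' @param lr_drop_every Epochs between learning-rate drops.
#' @param lr_drop_factor Multiplicative drop factor in (0, 1).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param momentum SGD momentum (0 reproduces plain SGD).
#' @param init_gain Target pre-activation standard deviation of the
#'   variance-calibrated weight initialization (seeded He draws rescaled
#'   layer-wise on a calibration batch so that average pooling does not
#'   shrink the signal reaching the regression head).
#' @param rng_seed Seed for weight init, shuffling and dropout.
#' @param target_scaling `"standardize"` or `"none"`.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, lr_drop_every = 20L, lr_drop_factor = 0.1,
                         batch_size = 128L, max_epochs = 300L, momentum = 0.9,
                         init_gain = 0.2, rng_seed = 1L,
                         target_scaling = c("standardize", "none")) {
  target_scaling <- match.arg(target_scaling)
  if (lr0 <= 0) abort("`lr0` must be positive.")
  if (lr_drop_factor <= 0 || lr_drop_factor >= 1) {
    abort("`lr_drop_factor` must lie strictly between 0 and 1.")
  }
  if (init_gain <= 0) abort("`init_gain` must be positive.")
  structure(list(lr0 = lr0, lr_drop_every = as.integer(lr_drop_every),
                 lr_drop_factor = lr_drop_factor,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 init_gain = init_gain, rng_seed = as.integer(rng_seed),
                 target_scaling = target_scaling),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr(epoch) = lr0 * lr_drop_factor ^ floor(epoch / lr_drop_every)` with
#' `epoch` counted from 0.
#'
#' @param epoch Integer epoch(s), 0-based.
#' @param schedule A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, schedule = train_config()) {
  schedule$lr0 * schedule$lr_drop_factor^floor(epoch / schedule$lr_drop_every)
}

#' Per-layer feature-map plan
#'
#' Walks the architecture and returns the side and channel count after
#' every convolution and pooling step, rejecting configurations whose
#' pooling would hit an odd side or whose convolution input is smaller than
#' the kernel (the feature-map sizes must stay integral).
#'
#' @param config A [cnn_config()].
#' @return Tibble `(layer, type, side, channels)` from input to the fully
#'   connected output.
#' @export
layer_shape_plan <- function(config = cnn_config()) {
  side <- config$input_side
  cin <- 3L
  rows <- list(tibble(layer = "input", type = "input", side = side, channels = cin))
  for (l in seq_along(config$conv_channels)) {
    pad <- as.integer(l %in% config$padded_layers)
    if (side + 2 * pad < 5) {
      abort(sprintf("Configuration error at conv%d: input side %d is smaller than the 5x5 kernel.",
                    l, side))
    }
    side <- side + 2L * pad - 4L
    cin <- config$conv_channels[l]
    rows[[length(rows) + 1]] <- tibble(layer = sprintf("conv%d%s", l, ifelse(pad > 0, " (pad 1)", "")),
                                       type = "conv", side = side, channels = cin)
    if (l < length(config$conv_channels)) {
      if (side %% 2L != 0L) {
        abort(sprintf("Configuration error at pool%d: conv%d output side %d is odd; pooling would make the feature map non-integral.",
                      l, l, side))
      }
      side <- side %/% 2L
      rows[[length(rows) + 1]] <- tibble(layer = sprintf("pool%d", l),
                                         type = "pool", side = side, channels = cin)
    }
  }
  rows[[length(rows) + 1]] <- tibble(layer = "fc", type = "fc", side = 1L,
                                     channels = config$outputs)
  bind_rows(rows)
}

cnn_pads <- function(config) {
  as.integer(seq_along(config$conv_channels) %in% config$padded_layers)
}

# named list of S x S x 3 arrays -> S x S x 3 x N array
images_to_array <- function(images, side) {
  if (is.array(images) && length(dim(images)) == 4L) {
    if (dim(images)[1] != side || dim(images)[2] != side) {
      abort(sprintf("Images must be %d x %d.", side, side))
    }
    return(images)
  }
  if (!length(images)) abort("No images supplied.")
  ok <- vapply(images, function(im) {
    is.array(im) && length(dim(im)) == 3L && all(dim(im)[1:2] == side) && dim(im)[3] == 3L
  }, logical(1))
  if (!all(ok)) {
    abort(sprintf("All images must be %d x %d x 3 arrays (got a mismatch at %s).",
                  side, side, paste(head(names(images)[!ok], 3), collapse = ", ")))
  }
  arr <- array(0, c(side, side, 3L, length(images)))
  for (i in seq_along(images)) arr[, , , i] <- images[[i]]
  dimnames(arr) <- list(NULL, NULL, NULL, names(images))
  arr
}

trait_matrix <- function(traits) {
  cols <- c("lfw_g", "ldw_g", "la_cm2")
  if (is.matrix(traits)) {
    if (ncol(traits) != 3L) abort("Trait matrix must have 3 columns.")
    colnames(traits) <- cols
    return(traits)
  }
  if (!all(cols %in% names(traits))) {
    abort("Traits must contain columns lfw_g, ldw_g, la_cm2.")
  }
  as.matrix(traits[cols])
}

#' Train the convolutional trait regressor
#'
#' Maps `input_side` x `input_side` x 3 images to the three growth traits
#' (LFW g, LDW g, LA cm^2) with the architecture of [cnn_config()] and the
#' schedule of [train_config()]. Targets are standardized per trait using
#' training-set mean/sd (so gram and cm^2 scales do not dominate each
#' other); the loss is mean squared error summed over the three
#' standardized outputs. When a validation set is given, the weights with
#' the best validation loss are retained. Training is deterministic per
#' seed on a given platform.
#'
#' @param images Named list of RGB arrays (or an S x S x 3 x N array).
#' @param traits Tibble or matrix of training targets (columns `lfw_g`,
#'   `ldw_g`, `la_cm2`).
#' @param val_images,val_traits Optional validation set in the same form.
#' @param config A [cnn_config()].
#' @param schedule A [train_config()].
#' @param verbose Print progress every few epochs.
#' @return Object of class `cnn_fit`: weights, configs, target-scaling
#'   constants, per-epoch training log and the best-validation epoch.
#' @export
train_cnn <- function(images, traits, val_images = NULL, val_traits = NULL,
                      config = cnn_config(), schedule = train_config(),
                      verbose = FALSE) {
  layer_shape_plan(config)  # validate before any work
  X <- images_to_array(images, config$input_side)
  Y <- trait_matrix(traits)
  if (dim(X)[4] != nrow(Y)) abort("Number of images and trait rows differ.")
  if (!all(is.finite(Y))) abort("Targets must be finite.")
  if (config$pool != "average") {
    abort("Only average pooling is implemented in the trainer.")
  }

  if (schedule$target_scaling == "standardize") {
    mu <- colMeans(Y)
    sdev <- apply(Y, 2, stats::sd)
    sdev[sdev == 0] <- 1
  } else {
    mu <- c(0, 0, 0)
    sdev <- c(1, 1, 1)
  }
  Ys <- sweep(sweep(Y, 2, mu), 2, sdev, "/")

  # inputs are zero-centred with the training-set mean: all-positive pixel
  # values give badly correlated first-layer gradients at the fixed
  # learning rate (variance is left untouched to keep the update scale
  # matched to the schedule)
  mu_x <- mean(X)
  sd_x <- 1
  X <- (X - mu_x) / sd_x

  has_val <- !is.null(val_images)
  Xv <- if (has_val) {
    (images_to_array(val_images, config$input_side) - mu_x) / sd_x
  } else numeric(0)
  Yv <- if (has_val) {
    sweep(sweep(trait_matrix(val_traits), 2, mu), 2, sdev, "/")
  } else matrix(0, 0, 3)
  if (has_val && length(dim(Xv)) == 4L && dim(Xv)[4] != nrow(Yv)) {
    abort("Validation images and traits differ in length.")
  }

  res <- cpp_cnn_train(X, Ys, Xv, Yv, config$conv_channels, cnn_pads(config),
                       schedule$lr0, schedule$lr_drop_every,
                       schedule$lr_drop_factor, schedule$momentum,
                       schedule$batch_size, schedule$max_epochs,
                       config$dropout_rate, schedule$init_gain %||% 0.2,
                       schedule$rng_seed, verbose)
  structure(list(weights = res$weights, config = config, schedule = schedule,
                 scaling = list(mean = mu, sd = sdev,
                                input_mean = mu_x, input_sd = sd_x),
                 log = tibble::as_tibble(res$log),
                 best_epoch = res$best_epoch,
                 version = 1L),
            class = "cnn_fit")
}

#' Predict traits with a fitted convolutional regressor
#'
#' @param object A `cnn_fit`.
#' @param images Named list of RGB arrays (or S x S x 3 x N array) at the
#'   model's input side.
#' @param ... Unused.
#' @return N x 3 matrix with columns `lfw_g`, `ldw_g`, `la_cm2` in physical
#'   units; negative raw outputs are clamped to 0 and the clamp count is
#'   attached as attribute `n_clamped`.
#' @export
predict.cnn_fit <- function(object, images, ...) {
  X <- images_to_array(images, object$config$input_side)
  X <- (X - object$scaling$input_mean) / object$scaling$input_sd
  raw <- cpp_cnn_predict(object$weights, X, object$config$conv_channels,
                         cnn_pads(object$config), object$config$outputs)
  out <- sweep(sweep(raw, 2, object$scaling$sd, "*"), 2, object$scaling$mean, "+")
  n_clamped <- sum(out < 0)
  if (n_clamped > 0) {
    inform(sprintf("Clamped %d negative trait prediction(s) to 0.", n_clamped))
  }
  out <- pmax(out, 0)
  colnames(out) <- c("lfw_g", "ldw_g", "la_cm2")
  rownames(out) <- dimnames(X)[[4]]
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Save / load a fitted convolutional regressor
#'
#' The checkpoint is a single versioned archive holding the weights, the
#' architecture and schedule configs and the target-scaling constants.
#'
#' @param fit A `cnn_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_cnn()`: `path`, invisibly. `load_cnn()`: the `cnn_fit`.
#' @export
save_cnn <- function(fit, path) {
  stopifnot(inherits(fit, "cnn_fit"))
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) abort("Not a regressor checkpoint.")
  structure(obj, class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> %d-conv regressor, input %d px, %d epochs (best val at %d)\n",
              length(x$config$conv_channels), x$config$input_side,
              nrow(x$log), x$best_epoch))
  invisible(x)
}
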