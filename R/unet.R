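#' U-Net architecture configuration
#'
#' A modified 2-D U-Net: per encoder level two 3x3 convolutions (stride 1,
#' size-preserving padding) with ReLU, a dropout layer after the repeated
#' convolutions, then 2x2 max pooling (no pooling after the deepest level);
#' per decoder level nearest-neighbour 2x upsampling followed by a 2x2
#' convolution, concatenation with the matching encoder feature map, and two
#' 3x3 convolutions with ReLU; a final 1x1 convolution to `n_classes`
#' channels with per-pixel softmax.
#'
#' @param encoder_channels Strictly increasing feature-channel counts of the
#'   contracting path (default `c(32, 64, 128, 256, 512)`).
#' @param dropout_rate Dropout fraction in `[0, 1)` applied after each
#'   encoder convolution pair (default 0.5).
#' @param input_size Slice edge length in pixels; must be divisible by
#'   `2^(length(encoder_channels) - 1)`.
#' @param n_classes Output channels (default 2: background, foreground).
#' @param seed Seed for the weight initialization (He-normal) and dropout.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(encoder_channels = c(32, 64, 128, 256, 512),
                        dropout_rate = 0.5, input_size = 256, n_classes = 2,
                        seed = 1L) {
  if (length(encoder_channels) < 2L || any(diff(encoder_channels) <= 0))
    stop("encoder_channels must be strictly increasing with length >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  depth <- length(encoder_channels)
  if (input_size %% 2^(depth - 1) != 0)
    stop(sprintf("input_size %d incompatible with depth %d (must be divisible by %d)",
                 input_size, depth, 2^(depth - 1)))
  structure(list(encoder_channels = as.integer(encoder_channels),
                 dropout_rate = dropout_rate,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Build a trainable U-Net
#'
#' Instantiates the network described by a [unet_config()] with seeded
#' He-normal weight initialization. The returned handle owns mutable native
#' state; use [unet_weights()] / [set_unet_weights()] to checkpoint or
#' restore parameters.
#'
#' @param cfg A [unet_config()].
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ptr <- unet_create_cpp(cfg$encoder_channels, cfg$input_size, cfg$n_classes,
                         cfg$dropout_rate, cfg$seed)
  structure(list(ptr = ptr, config = cfg), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> channels [%s], input %d, %d classes, %s parameters\n",
              paste(x$config$encoder_channels, collapse = ", "),
              x$config$input_size, x$config$n_classes,
              format(unet_param_count(x$config), big.mark = ",")))
  invisible(x)
}

#' Per-pixel class probabilities for a batch of slices
#'
#' Inference-mode forward pass (dropout inactive). Probabilities sum to 1
#' over classes at every pixel.
#'
#' @param model A [build_unet()] handle.
#' @param images A matrix (one slice) or array `(H, W, B)` of slices matching
#'   the configured `input_size`.
#' @return Array `(H, W, n_classes, B)` of class probabilities.
#' @export
predict_batch <- function(model, images) {
  stopifnot(inherits(model, "unet_model"))
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 3L || d[1] != model$config$input_size || d[2] != model$config$input_size)
    stop(sprintf("images must be %dx%d slices", model$config$input_size,
                 model$config$input_size))
  unet_predict_cpp(model$ptr, images)
}

#' One optimizer step on a mini-batch
#'
#' Training-mode forward/backward pass (dropout active) followed by a single
#' Adam update (beta1 = 0.9, beta2 = 0.999, eps = 1e-7) on the mean
#' categorical cross-entropy gradient of the batch.
#'
#' @param model A [build_unet()] handle.
#' @param images Array `(H, W, B)` of input slices.
#' @param labels Integer array `(H, W, B)` of per-pixel class ids (0-based).
#' @param lr Learning rate.
#' @return The mean categorical cross-entropy of the batch (before update).
#' @export
train_batch <- function(model, images, labels, lr) {
  stopifnot(inherits(model, "unet_model"))
  storage.mode(labels) <- "integer"
  unet_train_batch_cpp(model$ptr, images, labels, lr)
}

#' Mean categorical cross-entropy of a batch (no update)
#'
#' @inheritParams train_batch
#' @return Mean cross-entropy in inference mode.
#' @export
eval_loss <- function(model, images, labels) {
  stopifnot(inherits(model, "unet_model"))
  storage.mode(labels) <- "integer"
  unet_loss_cpp(model$ptr, images, labels)
}

#' Extract / restore network weights
#'
#' @param model A [build_unet()] handle.
#' @return `unet_weights` returns a list of per-layer `W`/`b` arrays.
#' @export
unet_weights <- function(model) unet_get_weights_cpp(model$ptr)

#' @rdname unet_weights
#' @param weights A weight list from [unet_weights()].
#' @export
set_unet_weights <- function(model, weights) {
  unet_set_weights_cpp(model$ptr, weights)
  invisible(model)
}

#' Closed-form parameter count of a U-Net configuration
#'
#' Pure function of the configuration; agrees with the instantiated
#' network's actual parameter count.
#'
#' @param cfg A [unet_config()].
#' @return Total number of trainable parameters.
#' @export
unet_param_count <- function(cfg) {
  ch <- cfg$encoder_channels
  D <- length(ch)
  conv_p <- function(k, cin, cout) cout * (k * k * cin) + cout
  total <- 0
  cin <- 1L
  for (lvl in 1:(D - 1)) {
    total <- total + conv_p(3, cin, ch[lvl]) + conv_p(3, ch[lvl], ch[lvl])
    cin <- ch[lvl]
  }
  total <- total + conv_p(3, ch[D - 1], ch[D]) + conv_p(3, ch[D], ch[D])
  for (lvl in (D - 1):1) {
    cup <- if (lvl == D - 1) ch[D] else ch[lvl + 1]
    total <- total + conv_p(2, cup, ch[lvl]) +
      conv_p(3, 2 * ch[lvl], ch[lvl]) + conv_p(3, ch[lvl], ch[lvl])
  }
  total + conv_p(1, ch[1], cfg$n_classes)
}

#' Save / load a network checkpoint
#'
#' Weights plus the JSON-serializable configuration, written as an RDS file
#' with a JSON sidecar describing the configuration.
#'
#' @param model A [build_unet()] handle.
#' @param path Checkpoint path (`.rds`).
#' @return `load_unet` returns a rebuilt [build_unet()] handle with restored
#'   weights.
#' @export
save_unet <- function(model, path) {
  saveRDS(list(config = unclass(model$config), weights = unet_weights(model)), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(unet_config, x$config[c("encoder_channels", "dropout_rate",
                                         "input_size", "n_classes", "seed")])
  model <- build_unet(cfg)
  set_unet_weights(model, x$weights)
  model
}
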