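## U-net trainer. The network is the standard symmetric encoder-decoder with
## skip connections: `depth` (default 3) max-pooling stages mirrored by
## nearest-neighbour upsampling stages, one skip per stage, two 3x3
## convolution + ReLU layers per block, a 1x1 convolution scoring layer and a
## softmax, optimised with stochastic gradient descent with momentum under L2
## regularisation and a stepped learning-rate schedule, with generalized dice
## loss. The numerical core lives in src/unet.cpp.

#' U-net architecture specification
#'
#' @param depth number of max-pooling stages; the number of skip connections
#'   equals the depth.
#' @param base_filters channels of the first encoder block; doubled at each
#'   stage.
#' @param n_classes output classes.
#' @param in_channels input image channels.
#' @return object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 3, base_filters = 16, n_classes = 3,
                      in_channels = 2) {
  if (depth < 1) stop("depth must be >= 1")
  if (base_filters < 1) stop("base_filters must be >= 1")
  structure(list(depth = as.integer(depth),
                 skip_connections = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "unet_spec")
}

#' Training configuration
#'
#' Defaults follow the reference schedule: stochastic gradient descent with
#' momentum 0.9, L2 regularisation 0.001, initial learning rate 0.002 for the
#' weak-label (CDL) mode or 0.001 for the curated (MDL) mode, dropped by a
#' factor 0.8 every 3 epochs, mini-batch size 4, 15 epochs, random
#' reflection/rotation augmentation, and a 0.85/0.10/0.05 split (0.80/0.10/0.10
#' in MDL mode).
#'
#' @param mode `"cdl"` (trained on weak labels) or `"mdl"` (trained on a small
#'   curated set).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param momentum SGD momentum.
#' @param l2 L2 regularisation coefficient.
#' @param initial_lr initial learning rate; default depends on `mode`.
#' @param lr_drop_factor multiplicative learning-rate drop.
#' @param lr_drop_every epochs between drops.
#' @param grad_clip global L2-norm gradient clipping threshold; `Inf`
#'   (default) disables clipping and matches plain SGD with momentum. A
#'   bounded loss like generalized dice relies on large gradients to leave
#'   its initial plateau, so clipping is off unless instability is observed.
#' @param ce_weight weight of an auxiliary cross-entropy term added to the
#'   generalized dice training criterion (`0` = pure generalized dice). The
#'   cross-entropy gradient does not vanish when a class's probability
#'   saturates, so a positive weight keeps rare classes recoverable in short
#'   training runs; the dice term still provides the class balancing.
#' @param split `(train, validation, test)` fractions.
#' @param augment apply random reflection/rotation augmentation.
#' @param seed integer seed (weight init, shuffling, augmentation draws).
#' @return object of class `train_config`.
#' @export
train_config <- function(mode = c("cdl", "mdl"), epochs = 15, batch_size = 4,
                         momentum = 0.9, l2 = 0.001, initial_lr = NULL,
                         lr_drop_factor = 0.8, lr_drop_every = 3,
                         grad_clip = Inf, ce_weight = 0, split = NULL,
                         augment = TRUE, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(initial_lr)) initial_lr <- if (mode == "cdl") 0.002 else 0.001
  if (is.null(split)) split <- if (mode == "cdl") c(0.85, 0.10, 0.05) else c(0.80, 0.10, 0.10)
  if (abs(sum(split) - 1) > 1e-8) stop("split must sum to 1")
  if (initial_lr <= 0 || momentum < 0 || l2 < 0 || lr_drop_factor <= 0)
    stop("rates must be positive")
  structure(list(mode = mode, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 l2 = l2, initial_lr = initial_lr,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_every = as.integer(lr_drop_every),
                 grad_clip = grad_clip, ce_weight = ce_weight, split = split,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

# He-normal initial weights for every conv layer, in execution order
init_unet_weights <- function(spec) {
  f <- spec$base_filters
  D <- spec$depth
  widths <- f * 2^(0:(D))
  layers <- list()
  add_conv <- function(cin, cout) {
    W <- matrix(rnorm(cin * 9 * cout, 0, sqrt(2 / (cin * 9))), cin * 9, cout)
    layers[[length(layers) + 1]] <<- list(W = W, b = rep(0, cout))
  }
  cin <- spec$in_channels
  for (i in 1:D) {                      # encoder
    add_conv(cin, widths[i]); add_conv(widths[i], widths[i])
    cin <- widths[i]
  }
  add_conv(cin, widths[D + 1]); add_conv(widths[D + 1], widths[D + 1])
  cin <- widths[D + 1]
  for (i in D:1) {                      # decoder (skip concat doubles input)
    add_conv(widths[i] + cin, widths[i]); add_conv(widths[i], widths[i])
    cin <- widths[i]
  }
  layers[[length(layers) + 1]] <- list(
    W = matrix(rnorm(cin * spec$n_classes, 0, sqrt(2 / cin)), cin, spec$n_classes),
    b = rep(0, spec$n_classes)
  )
  layers
}

flatten_image <- function(image, spec) {
  d <- dim(image)
  if (length(d) == 2) { image <- array(image, c(d, 1)); d <- dim(image) }
  if (d[3] != spec$in_channels)
    stop("image has ", d[3], " channels; the network expects ", spec$in_channels)
  matrix(image, d[1] * d[2], d[3])
}

check_divisible <- function(H, W, depth) {
  if (H %% 2^depth != 0 || W %% 2^depth != 0)
    stop("image dimensions must be divisible by 2^depth = ", 2^depth)
}

#' Train a U-net on images and label masks
#'
#' @param images list of `height x width x in_channels` arrays (normalise
#'   first with [normalize_image()]).
#' @param masks list of matching integer label matrices over `0..K-1`.
#' @param config a [train_config()].
#' @param spec a [unet_spec()].
#' @param val_images,val_masks optional validation pairs (per-epoch validation
#'   loss is logged).
#' @return object of class `weakseg_model` with elements `weights`, `spec`,
#'   `config` and `log` (per-epoch data frame: epoch, learning rate, training
#'   loss, validation loss).
#' @export
train_model <- function(images, masks, config = train_config(),
                        spec = unet_spec(), val_images = NULL,
                        val_masks = NULL) {
  if (length(images) < config$batch_size)
    stop("need at least batch_size (", config$batch_size, ") training pairs")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  d <- dim(images[[1]])
  H <- d[1]; W <- d[2]
  check_divisible(H, W, spec$depth)
  present <- sort(unique(unlist(lapply(masks, function(m) unique(as.vector(m))))))
  all_classes <- seq_len(spec$n_classes) - 1L
  if (!all(all_classes %in% present))
    warning("classes absent from all training masks: ",
            paste(setdiff(all_classes, present), collapse = ", "))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  weights <- init_unet_weights(spec)
  n <- length(images)
  order_mat <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                        integer(n)))
  aug_mat <- if (config$augment && H == W) {
    matrix(sample(0:7, config$epochs * n, replace = TRUE), config$epochs, n)
  } else if (config$augment) {
    # non-square inputs: reflections only (rotations would change the shape)
    matrix(sample(c(0L, 4L), config$epochs * n, replace = TRUE), config$epochs, n)
  } else {
    matrix(0L, config$epochs, n)
  }
  perms <- symmetry_perms(H, W)

  xs <- lapply(images, flatten_image, spec = spec)
  ys <- lapply(masks, function(m) as.integer(m))
  vx <- if (is.null(val_images)) list() else lapply(val_images, flatten_image, spec = spec)
  vy <- if (is.null(val_masks)) list() else lapply(val_masks, function(m) as.integer(m))

  fit <- .unet_train_cpp(xs, ys, vx, vy, weights, H, W, spec$depth,
                         spec$n_classes, spec$in_channels, order_mat, aug_mat,
                         perms, config$batch_size, config$initial_lr,
                         config$momentum, config$l2, config$lr_drop_factor,
                         config$lr_drop_every, config$grad_clip,
                         if (is.null(config$ce_weight)) 0 else config$ce_weight)

  structure(list(
    weights = fit$weights, spec = spec, config = config,
    log = data.frame(epoch = seq_len(config$epochs), lr = fit$lr,
                     train_loss = fit$train_loss, val_loss = fit$val_loss)
  ), class = "weakseg_model")
}

#' Predict a label mask (or class probabilities) for an image
#'
#' @param object a trained `weakseg_model`.
#' @param image `height x width x in_channels` array (normalised like the
#'   training data).
#' @param type `"mask"` for the per-pixel argmax label matrix, `"prob"` for
#'   the `height x width x n_classes` probability array.
#' @param ... unused.
#' @return label matrix over `0..K-1`, or probability array.
#' @export
predict.weakseg_model <- function(object, image, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  spec <- object$spec
  d <- dim(image)
  check_divisible(d[1], d[2], spec$depth)
  x <- flatten_image(image, spec)
  prob <- .unet_forward_cpp(object$weights, x, d[1], d[2], spec$depth,
                            spec$n_classes, spec$in_channels)
  if (type == "prob") return(array(prob, c(d[1], d[2], spec$n_classes)))
  matrix(max.col(prob, ties.method = "first") - 1L, d[1], d[2])
}

#' Save / load a trained model as JSON
#'
#' The model file is self-describing: it embeds the architecture spec and the
#' training configuration alongside the weights.
#'
#' @param model a `weakseg_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  obj <- list(
    spec = unclass(model$spec),
    config = unclass(model$config),
    log = model$log,
    weights = lapply(model$weights, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = as.vector(l$b)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(nrow(obj$weights)), function(i)
    list(W = matrix(obj$weights$W[[i]], obj$weights$dim[[i]][1],
                    obj$weights$dim[[i]][2]),
         b = obj$weights$b[[i]]))
  config <- as.list(obj$config)
  if (!is.null(config$grad_clip)) config$grad_clip <- as.numeric(config$grad_clip)
  structure(list(
    weights = weights,
    spec = structure(as.list(obj$spec), class = "unet_spec"),
    config = structure(config, class = "train_config"),
    log = obj$log
  ), class = "weakseg_model")
}
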