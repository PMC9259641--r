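## Dataset handling for network training: train/validation/test splitting,
## per-image min-max normalisation, paired geometric augmentation, and the
## generalized dice loss used as the training criterion under strong class
## imbalance.

#' Split sample ids into train / validation / test sets
#'
#' Ids are shuffled with the seed; validation and test receive
#' `floor(n * fraction)` ids each and the remainder goes to training, so the
#' three sets always partition the input.
#'
#' @param sample_ids vector of ids.
#' @param fractions `(train, validation, test)`, non-negative, summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(sample_ids, fractions = c(0.85, 0.10, 0.05), seed = 1) {
  n <- length(sample_ids)
  if (n == 0) stop("no sample ids to split")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  shuffled <- sample(sample_ids)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  list(
    train = shuffled[seq_len(n_train)],
    validation = shuffled[n_train + seq_len(n_val)],
    test = shuffled[n_train + n_val + seq_len(n_test)]
  )
}

#' Per-image, per-channel min-max normalisation
#'
#' Each channel is scaled to `[0, 1]`; a constant channel maps to all zeros.
#'
#' @param image `height x width x channels` array (or a matrix, treated as one
#'   channel).
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_image <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1))
  if (any(!is.finite(image))) stop("non-finite values in image")
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    x <- image[, , ch]
    rng <- range(x)
    out[, , ch] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
  }
  if (dim(out)[3] == 1) out <- out[, , 1, drop = TRUE]
  out
}

# the eight axis-aligned symmetries of a square image, as (reflection,
# rotation) pairs; rotation is counter-clockwise in matrix (row, col) terms
apply_symmetry <- function(x, reflection = c("none", "horizontal", "vertical"),
                           rotation = 0L) {
  reflection <- match.arg(reflection)
  flip_one <- function(m) {
    if (reflection == "horizontal") m[, ncol(m):1, drop = FALSE]
    else if (reflection == "vertical") m[nrow(m):1, , drop = FALSE]
    else m
  }
  rot_one <- function(m) {
    k <- rotation %% 4L
    for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
    m
  }
  op <- function(m) rot_one(flip_one(m))
  if (is.matrix(x)) return(op(x))
  slices <- lapply(seq_len(dim(x)[3]), function(ch) op(x[, , ch]))
  out <- array(0, c(dim(slices[[1]]), length(slices)))
  for (ch in seq_along(slices)) out[, , ch] <- slices[[ch]]
  out
}

#' Random paired reflection/rotation augmentation
#'
#' Draws one random reflection (none/horizontal/vertical) and one random
#' rotation (multiple of 90 degrees) and applies the identical transform to
#' the image and its mask, so class pixel counts are preserved.
#'
#' @param image `height x width x channels` array.
#' @param mask matching label matrix.
#' @param seed integer seed for the draw.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, seed = 1) {
  if (!identical(dim(image)[1:2], dim(mask))) stop("image and mask shapes differ")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  reflection <- sample(c("none", "horizontal", "vertical"), 1)
  rotation <- sample(0:3, 1)
  list(
    image = apply_symmetry(image, reflection, rotation),
    mask = apply_symmetry(mask, reflection, rotation),
    reflection = reflection,
    rotation = rotation
  )
}

# 0-based pixel permutations realising each symmetry code on an H x W grid;
# code = rotation + 4 * flip_horizontal, used by the C++ training loop
symmetry_perms <- function(H, W) {
  idx <- matrix(seq_len(H * W), H, W)
  perms <- vector("list", 8)
  for (flip in 0:1) {
    for (rot in 0:3) {
      m <- if (flip == 1) idx[, W:1, drop = FALSE] else idx
      k <- rot
      while (k > 0) { m <- t(m)[ncol(m):1, , drop = FALSE]; k <- k - 1 }
      perms[[rot + 4 * flip + 1]] <- as.integer(m) - 1L
    }
  }
  perms
}

#' Generalized dice loss
#'
#' Class-volume-weighted dice cost for multi-class segmentation under strong
#' class imbalance:
#' \deqn{L = 1 - 2 \frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
#'                      {\sum_l w_l \sum_n (r_{ln} + p_{ln}) + \epsilon},
#'       \quad w_l = \frac{1}{(\sum_n r_{ln} + \epsilon)^2}}
#' with \eqn{\epsilon = 10^{-7}} guarding absent classes. The loss is 0 for a
#' perfect one-hot prediction and 1 when all prediction mass sits on wrong
#' classes.
#'
#' @param scores per-pixel class probabilities: `N x K` matrix or
#'   `H x W x K` array, rows summing to 1.
#' @param truth one-hot reference of the same shape, or an integer label
#'   matrix/vector over `0..K-1`.
#' @return scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(scores, truth) {
  eps <- 1e-7
  if (is.array(scores) && length(dim(scores)) == 3) {
    K <- dim(scores)[3]
    scores <- matrix(scores, ncol = K)
  }
  K <- ncol(scores)
  if (is.matrix(truth) && !identical(dim(truth), dim(scores))) {
    truth <- as.vector(truth)
  } else if (is.array(truth) && length(dim(truth)) == 3) {
    truth <- matrix(truth, ncol = K)
  }
  if (!is.matrix(truth)) {
    y <- as.integer(truth)
    if (length(y) != nrow(scores)) stop("scores and truth shapes differ")
    truth <- matrix(0, nrow(scores), K)
    truth[cbind(seq_along(y), y + 1L)] <- 1
  }
  if (!identical(dim(truth), dim(scores))) stop("scores and truth shapes differ")
  w <- 1 / (colSums(truth) + eps)^2
  num <- sum(w * colSums(truth * scores))
  den <- sum(w * (colSums(truth) + colSums(scores))) + eps
  1 - 2 * num / den
}
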