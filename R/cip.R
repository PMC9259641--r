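## Conventional-image-processing (CIP) weak labeler and controlled label
## corruption.
##
## The labeler chains the classic spot-detection operators: difference of
## Gaussians band-pass, white top-hat background suppression, thresholding
## (Otsu or fixed), small-object removal and an optional watershed split on
## the distance transform. Detected components are classified by the
## green/red mean-intensity ratio: the pH-sensitive green reporter is
## quenched in acidic autolysosomes, so a high ratio indicates a phagophore.

#' CIP weak-labeler configuration
#'
#' @param dog_sigmas `(narrow, wide)` Gaussian sigmas of the band-pass, pixels.
#' @param tophat_radius radius of the white top-hat disc, pixels.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold response threshold used when `threshold_mode = "fixed"`.
#' @param min_event_area minimum component area kept, pixels^2.
#' @param use_watershed split merged events by watershed on the distance map.
#' @param ratio_tau green/red mean-ratio cutoff: components at or above the
#'   cutoff are phagophores (class 1), below it autolysosomes (class 2).
#' @return object of class `cip_config`.
#' @export
cip_config <- function(dog_sigmas = c(1.5, 6), tophat_radius = 9,
                       threshold_mode = c("otsu", "fixed"),
                       fixed_threshold = 0.05, min_event_area = 5,
                       use_watershed = TRUE, ratio_tau = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (dog_sigmas[1] >= dog_sigmas[2]) stop("dog_sigmas must satisfy narrow < wide")
  if (min_event_area < 1) stop("min_event_area must be >= 1")
  if (ratio_tau <= 0) stop("ratio_tau must be positive")
  structure(list(
    dog_sigmas = dog_sigmas, tophat_radius = tophat_radius,
    threshold_mode = threshold_mode, fixed_threshold = fixed_threshold,
    min_event_area = min_event_area, use_watershed = use_watershed,
    ratio_tau = ratio_tau
  ), class = "cip_config")
}

#' Spot-enhancing filter
#'
#' Difference of Gaussians (narrow minus wide sigma) followed by a white
#' top-hat with the configured disc radius. The output is a non-negative
#' background-suppressed response, maximal inside bright puncta.
#'
#' @param channel 2-D intensity matrix.
#' @param config a [cip_config()].
#' @return matrix of the same shape, values `>= 0`.
#' @export
enhance <- function(channel, config = cip_config()) {
  if (!is.matrix(channel)) stop("enhance() expects a 2-D matrix")
  if (any(!is.finite(channel))) stop("non-finite intensities")
  img <- EBImage::Image(channel)
  dog <- EBImage::gblur(img, sigma = config$dog_sigmas[1]) -
    EBImage::gblur(img, sigma = config$dog_sigmas[2])
  dog <- as.matrix(dog)
  dog[dog < 0] <- 0
  kern <- EBImage::makeBrush(2 * floor(config$tophat_radius) + 1, shape = "disc")
  as.matrix(EBImage::whiteTopHat(EBImage::Image(dog), kern))
}

#' Segment and classify vesicles with conventional image processing
#'
#' Detection runs on the pixelwise maximum of the two channels (so red-only
#' autolysosomes are detectable), thresholds the enhanced response, removes
#' components below `min_event_area`, optionally splits touching events by
#' watershed on the distance transform, and classifies every surviving
#' component by its mean green/red intensity ratio.
#'
#' @param red,green 2-D intensity matrices of equal shape.
#' @param config a [cip_config()].
#' @return integer label mask over \{0 background, 1 phagophore,
#'   2 autolysosome\}.
#' @export
segment_events <- function(red, green, config = cip_config()) {
  if (!identical(dim(red), dim(green))) stop("red and green must have the same shape")
  resp <- enhance(pmax(red, green), config)
  thr <- if (config$threshold_mode == "otsu") {
    rng <- range(resp)
    if (rng[2] <= rng[1]) Inf  # flat response: nothing detectable
    else {
      sc <- (resp - rng[1]) / (rng[2] - rng[1])
      EBImage::otsu(EBImage::Image(sc)) * (rng[2] - rng[1]) + rng[1]
    }
  } else config$fixed_threshold
  binary <- resp > thr

  if (!any(binary)) return(matrix(0L, nrow(red), ncol(red)))

  if (config$use_watershed) {
    dm <- EBImage::distmap(EBImage::Image(matrix(as.numeric(binary),
                                                 nrow(binary), ncol(binary))))
    lab <- as.matrix(EBImage::watershed(dm, tolerance = 1))
  } else {
    lab <- label_components(binary)
  }

  # area filter, then classify by channel ratio
  out <- matrix(0L, nrow(red), ncol(red))
  ids <- setdiff(unique(as.vector(lab)), 0)
  for (id in ids) {
    px <- lab == id
    if (sum(px) < config$min_event_area) next
    ratio <- mean(green[px]) / (mean(red[px]) + 1e-12)
    out[px] <- if (ratio >= config$ratio_tau) 1L else 2L
  }
  out
}

#' Label-corruption model configuration
#'
#' Controlled weak-label noise with the three canonical error types of
#' conventional pipelines: missed events, misclassified events, and
#' incomplete segmentation (eroded outlines).
#'
#' @param p_miss probability an event is deleted entirely.
#' @param p_swap probability a surviving event's class is flipped (1 <-> 2).
#' @param erosion_fraction fraction of each remaining event's area removed by
#'   peeling boundary pixels (never below 1 pixel left).
#' @param seed integer seed.
#' @return object of class `error_model_config`.
#' @export
error_model_config <- function(p_miss = 0, p_swap = 0, erosion_fraction = 0,
                               seed = 1) {
  if (p_miss < 0 || p_miss > 1 || p_swap < 0 || p_swap > 1)
    stop("probabilities must lie in [0, 1]")
  if (erosion_fraction < 0 || erosion_fraction >= 1)
    stop("erosion_fraction must lie in [0, 1)")
  structure(list(p_miss = p_miss, p_swap = p_swap,
                 erosion_fraction = erosion_fraction,
                 seed = as.integer(seed)),
            class = "error_model_config")
}

#' Corrupt a label mask with controlled errors
#'
#' Per 8-connected event (components taken within each class), independently:
#' with probability `p_miss` the event is set to background; otherwise with
#' probability `p_swap` its class is flipped; otherwise its outline is eroded
#' by removing the `erosion_fraction` of its pixels closest to the boundary
#' (keeping at least one pixel). The three error modes are mutually exclusive
#' per event. Reproducible given the config seed.
#'
#' @param mask integer label mask over \{0, 1, 2\}.
#' @param config an [error_model_config()].
#' @return corrupted label mask.
#' @export
corrupt_mask <- function(mask, config) {
  stopifnot(inherits(config, "error_model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  out <- mask
  for (cls in c(1L, 2L)) {
    lab <- label_components(mask == cls)
    n <- max(lab)
    if (n == 0) next
    u_miss <- runif(n)
    u_swap <- runif(n)
    for (k in seq_len(n)) {
      px <- which(lab == k)
      if (u_miss[k] < config$p_miss) {
        out[px] <- 0L
      } else if (u_swap[k] < config$p_swap) {
        out[px] <- if (cls == 1L) 2L else 1L
      } else if (config$erosion_fraction > 0) {
        keep <- max(1L, ceiling(length(px) * (1 - config$erosion_fraction)))
        if (keep < length(px)) {
          # peel from the outside in: keep the pixels deepest inside the event
          ev <- matrix(0, nrow(mask), ncol(mask))
          ev[px] <- 1
          d <- as.matrix(EBImage::distmap(EBImage::Image(ev)))
          ord <- order(d[px], px, decreasing = c(TRUE, FALSE), method = "radix")
          out[px[ord[(keep + 1):length(px)]]] <- 0L
        }
      }
    }
  }
  out
}
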