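## Synthetic two-channel autophagy HTS image simulator.
##
## Emulates fields of view from a dual-fluorophore pH biosensor screen:
## phagophores (class 1) fluoresce in both channels, autolysosomes (class 2)
## are acidic, so the green (pH-sensitive) channel is quenched and only the
## red channel remains; autolysosomes are larger on average. Defaults are
## calibrated so pooled pixel frequencies approximate 0.95 background /
## 0.023 phagophore / 0.024 autolysosome.

CLASS_LABELS <- c("background", "phagophore", "autolysosome")

#' Simulation configuration
#'
#' Parameters of the synthetic vesicle field generator. Intensities are on a
#' `[0, 1]` scale, lengths in pixels. Class identities follow the biosensor
#' colour logic: the phagophore channel profile must be bright in both
#' channels (`green >= 0.8 * red`) and the autolysosome profile green-quenched
#' (`green <= 0.2 * red`); the autolysosome mean radius must exceed the
#' phagophore one.
#'
#' @param width,height image size in pixels.
#' @param n_images number of fields to simulate.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration including the seed.
#' @param phagophore_count_mean,autolysosome_count_mean expected number of
#'   events per image (Poisson).
#' @param phagophore_radius,autolysosome_radius `(mean, sd)` of the event
#'   radius in pixels (normal, truncated below at 1).
#' @param channel_profiles list with elements `phagophore` and `autolysosome`,
#'   each `(red, green)` mean intensities in `[0, 1]`.
#' @param intensity_cv coefficient of variation of the per-vesicle brightness
#'   multiplier (fluorophore expression varies between vesicles; dim events
#'   are what conventional pipelines miss).
#' @param background_level baseline intensity in both channels.
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param noise `(gaussian_sd, poisson_scale)`: additive read noise and the
#'   photon count scale of the shot noise (larger = less noise).
#' @param clutter_density amplitude of smooth non-event background texture.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(width = 256, height = 256, n_images = 50,
                              seed = 1,
                              phagophore_count_mean = 29,
                              autolysosome_count_mean = 13.5,
                              phagophore_radius = c(4, 1),
                              autolysosome_radius = c(6, 1.5),
                              channel_profiles = list(
                                phagophore = c(red = 0.70, green = 0.80),
                                autolysosome = c(red = 0.80, green = 0.10)
                              ),
                              intensity_cv = 0.35,
                              background_level = 0.06,
                              psf_sigma = 1.2,
                              noise = c(gaussian_sd = 0.015, poisson_scale = 300),
                              clutter_density = 0.03) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_images = as.integer(n_images), seed = as.integer(seed),
    phagophore_count_mean = phagophore_count_mean,
    autolysosome_count_mean = autolysosome_count_mean,
    phagophore_radius = phagophore_radius,
    autolysosome_radius = autolysosome_radius,
    channel_profiles = channel_profiles,
    intensity_cv = intensity_cv,
    background_level = background_level,
    psf_sigma = psf_sigma,
    noise = noise,
    clutter_density = clutter_density
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$width <= 0L || cfg$height <= 0L) stop("image dimensions must be positive")
  if (cfg$n_images <= 0L) stop("n_images must be positive")
  if (cfg$phagophore_count_mean < 0 || cfg$autolysosome_count_mean < 0)
    stop("count means must be >= 0")
  if (any(cfg$phagophore_radius <= 0) || any(cfg$autolysosome_radius <= 0))
    stop("radius parameters must be positive")
  if (cfg$autolysosome_radius[1] <= cfg$phagophore_radius[1])
    stop("autolysosome mean radius must exceed the phagophore mean radius")
  p <- cfg$channel_profiles$phagophore
  a <- cfg$channel_profiles$autolysosome
  ints <- c(p, a, cfg$background_level)
  if (any(ints < 0) || any(ints > 1)) stop("intensities must lie in [0, 1]")
  if (p[["green"]] < 0.8 * p[["red"]])
    stop("phagophore profile must be bright in both channels (green >= 0.8 * red)")
  if (a[["green"]] > 0.2 * a[["red"]])
    stop("autolysosome profile must be green-quenched (green <= 0.2 * red)")
  if (cfg$psf_sigma <= 0) stop("psf_sigma must be positive")
  invisible(cfg)
}

#' Rescale the default calibration to another field size
#'
#' Keeps the calibrated event density (events per unit area), so class pixel
#' frequencies are preserved at any geometry.
#'
#' @param width,height field size in pixels.
#' @param n_images number of fields.
#' @param seed integer seed.
#' @param base configuration whose density is carried over.
#' @return a `sim_config`.
#' @export
simulation_config_scaled <- function(width, height, n_images = 50, seed = 1,
                                     base = simulation_config()) {
  scale <- (width * height) / (base$width * base$height)
  cfg <- base
  cfg$width <- as.integer(width)
  cfg$height <- as.integer(height)
  cfg$n_images <- as.integer(n_images)
  cfg$seed <- as.integer(seed)
  cfg$phagophore_count_mean <- base$phagophore_count_mean * scale
  cfg$autolysosome_count_mean <- base$autolysosome_count_mean * scale
  validate_sim_config(cfg)
  cfg
}

#' Full-scale geometry preset
#'
#' Same calibration as the default configuration but at the native HTS frame
#' geometry (680 x 512, two channels).
#'
#' @param n_images number of fields.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
simulation_config_full_scale <- function(n_images = 50, seed = 1) {
  simulation_config_scaled(680, 512, n_images = n_images, seed = seed)
}

# render one field: returns list(image HxWx2, mask HxW, vesicles data.frame)
render_field <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  n_p <- rpois(1, cfg$phagophore_count_mean)
  n_a <- rpois(1, cfg$autolysosome_count_mean)
  n <- n_p + n_a
  cls <- c(rep(1L, n_p), rep(2L, n_a))
  if (n > 0) {
    ord <- sample.int(n)  # interleave draw order of the two classes
    cls <- cls[ord]
  }
  rad_par <- list(cfg$phagophore_radius, cfg$autolysosome_radius)
  rows <- runif(n, 0, H)
  cols <- runif(n, 0, W)
  radii <- numeric(n)
  for (k in seq_len(n)) {
    rp <- rad_par[[cls[k]]]
    radii[k] <- max(1, rnorm(1, rp[1], rp[2]))
  }
  # per-vesicle brightness multiplier (expression variability); dim events
  # are the ones a threshold-based labeler misses
  bright <- if (cfg$intensity_cv > 0)
    pmax(0.2, rnorm(n, 1, cfg$intensity_cv)) else rep(1, n)

  mask <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  red <- matrix(cfg$background_level, H, W)
  green <- matrix(cfg$background_level, H, W)
  rowg <- matrix(seq_len(H) - 0.5, H, W)
  colg <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)

  for (k in seq_len(n)) {
    r0 <- rows[k]; c0 <- cols[k]; rad <- radii[k]
    rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad + 1))
    cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad + 1))
    d2 <- outer((rr - 0.5 - r0)^2, (cc - 0.5 - c0)^2, "+")
    inside <- d2 <= rad^2
    if (!any(inside)) next
    sub_mask <- mask[rr, cc, drop = FALSE]
    sub_best <- bestd[rr, cc, drop = FALSE]
    # nearest covering vesicle wins; later-drawn wins ties
    take <- inside & (d2 <= sub_best)
    sub_mask[take] <- cls[k]
    sub_best[take] <- d2[take]
    mask[rr, cc] <- sub_mask
    bestd[rr, cc] <- sub_best
    prof <- cfg$channel_profiles[[cls[k]]]
    subr <- red[rr, cc, drop = FALSE]; subg <- green[rr, cc, drop = FALSE]
    subr[inside] <- pmax(subr[inside], min(1, prof[["red"]] * bright[k]))
    subg[inside] <- pmax(subg[inside], min(1, prof[["green"]] * bright[k]))
    red[rr, cc] <- subr
    green[rr, cc] <- subg
  }

  # optics + noise: PSF blur, smooth clutter, shot noise, read noise
  blur <- function(x) {
    as.matrix(EBImage::gblur(EBImage::Image(x), sigma = cfg$psf_sigma))
  }
  red <- blur(red); green <- blur(green)
  if (cfg$clutter_density > 0) {
    tex <- as.matrix(EBImage::gblur(
      EBImage::Image(matrix(runif(H * W), H, W)), sigma = 4))
    tex <- tex - mean(tex)
    red <- red + cfg$clutter_density * tex
    green <- green + cfg$clutter_density * tex
  }
  ps <- cfg$noise[["poisson_scale"]]
  if (is.finite(ps) && ps > 0) {
    red <- rpois(H * W, pmax(red, 0) * ps) / ps
    green <- rpois(H * W, pmax(green, 0) * ps) / ps
    dim(red) <- c(H, W); dim(green) <- c(H, W)
  }
  gs <- cfg$noise[["gaussian_sd"]]
  if (gs > 0) {
    red <- red + rnorm(H * W, 0, gs)
    green <- green + rnorm(H * W, 0, gs)
  }
  img <- array(0, c(H, W, 2))
  img[, , 1] <- pmin(pmax(red, 0), 1)
  img[, , 2] <- pmin(pmax(green, 0), 1)

  vesicles <- data.frame(
    row = rows, col = cols, radius = radii,
    class_id = if (n > 0) cls else integer(0)
  )
  list(image = img, mask = mask, vesicles = vesicles)
}

#' Generate a synthetic dataset
#'
#' Draws per-image event counts from Poisson distributions, renders each
#' vesicle as a disk with its class channel profile, applies a Gaussian PSF,
#' shot and read noise, and returns for each field the noisy image, the clean
#' label mask (0 background, 1 phagophore, 2 autolysosome), the vesicle list
#' and tight ground-truth bounding boxes of the mask components. Deterministic
#' given the configuration (including its seed).
#'
#' @param config a [simulation_config()].
#' @return list of `synthetic_sample` objects with elements `image`
#'   (`height x width x 2`, channels red then green), `mask`, `vesicles`,
#'   `boxes` and `image_id`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  lapply(seq_len(config$n_images), function(i) {
    f <- render_field(config)
    boxes <- extract_bounding_boxes(f$mask, image_id = i)
    structure(
      list(image = f$image, mask = f$mask, vesicles = f$vesicles,
           boxes = boxes, image_id = i),
      class = "synthetic_sample"
    )
  })
}

#' Pooled class pixel frequencies of a dataset
#'
#' @param samples list of samples from [generate_dataset()] (or any objects
#'   with a `mask` element).
#' @return named numeric vector of length 3 summing to 1.
#' @export
class_frequencies <- function(samples) {
  counts <- c(0, 0, 0)
  for (s in samples) {
    tab <- tabulate(s$mask + 1L, nbins = 3L)
    counts <- counts + tab
  }
  stats::setNames(counts / sum(counts), CLASS_LABELS)
}
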