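# Shared fixtures: tiny synthetic fields and hand-built masks.

# small field with both event classes reasonably likely present
tiny_sim_config <- function(n_images = 1, seed = 1, width = 64, height = 64,
                            ...) {
  simulation_config(width = width, height = height, n_images = n_images,
                    seed = seed,
                    phagophore_count_mean = 4, autolysosome_count_mean = 3,
                    ...)
}

# noiseless single-event field: one disk of the given class in the centre
single_event_field <- function(class_id, radius = 5, size = 48,
                               profiles = list(phagophore = c(red = 0.7, green = 0.8),
                                               autolysosome = c(red = 0.8, green = 0.1)),
                               background = 0.05) {
  prof <- profiles[[class_id]]
  red <- matrix(background, size, size)
  green <- matrix(background, size, size)
  centre <- size / 2
  d2 <- outer((seq_len(size) - 0.5 - centre)^2,
              (seq_len(size) - 0.5 - centre)^2, "+")
  inside <- d2 <= radius^2
  red[inside] <- prof[["red"]]
  green[inside] <- prof[["green"]]
  mask <- matrix(0L, size, size)
  mask[inside] <- as.integer(class_id)
  list(red = red, green = green, mask = mask)
}

# brute-force optimal one-to-one box matching by total IoU, pairs >= tau only;
# enumerates every assignment (feasible for <= 4 boxes per side)
brute_force_match <- function(method_boxes, reference_boxes, tau = 0.1) {
  nm <- nrow(method_boxes); nr <- nrow(reference_boxes)
  if (nm == 0 || nr == 0)
    return(list(n_matches = 0L, total_iou = 0))
  iou <- outer(seq_len(nm), seq_len(nr),
               Vectorize(function(i, j) bb_iou(method_boxes[i, ], reference_boxes[j, ])))
  iou[iou < tau] <- NA
  best <- list(n_matches = 0L, total_iou = 0)
  recurse <- function(i, used_r, n, tot) {
    if (n > best$n_matches ||
        (n == best$n_matches && tot > best$total_iou + 1e-12))
      best <<- list(n_matches = n, total_iou = tot)
    if (i > nm) return()
    recurse(i + 1, used_r, n, tot)  # leave method box i unmatched
    for (j in seq_len(nr)) {
      if (!used_r[j] && !is.na(iou[i, j])) {
        used_r[j] <- TRUE
        recurse(i + 1, used_r, n + 1L, tot + iou[i, j])
        used_r[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nr), 0L, 0)
  best
}

# brute-force two-sample KS statistic: sup of |ECDF difference| over the
# pooled sample points
brute_force_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# shared desk-scale dataset for the heavy end-to-end checks (computed once
# per session): 240 fields of 128x128 at the calibrated event density
desk128_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(simulation_config_scaled(128, 128,
                                                      n_images = 240, seed = 1))
      cache <<- list(
        ds = ds,
        images = lapply(ds, function(s) normalize_image(s$image)),
        test_ids = 201:240,
        truths = lapply(201:240, function(i) ds[[i]]$mask)
      )
    }
    cache
  }
})

random_boxes <- function(n, max_coord = 20) {
  if (n == 0)
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0)))
  r0 <- sample.int(max_coord - 2, n, replace = TRUE)
  c0 <- sample.int(max_coord - 2, n, replace = TRUE)
  data.frame(image_id = 1L, class_id = 1L,
             row_min = r0, col_min = c0,
             row_max = r0 + sample.int(6, n, replace = TRUE),
             col_max = c0 + sample.int(6, n, replace = TRUE))
}
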