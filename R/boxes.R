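## Bounding-box surrogate detection analysis. Detection agreement between a
## method's boxes and reference (human) boxes is a cheap proxy for
## segmentation quality: boxes are matched one-to-one by IoU (greedy, only
## pairs with IoU >= 0.1 considered, to remove random overlap), unmatched
## method boxes are false positives, unmatched reference boxes false
## negatives, and matched pairs are binned into lower [0.1, 0.49] and higher
## [0.5, 1] overlap ranges.

#' Extract tight bounding boxes from a label mask
#'
#' One box per 8-connected component per class. Coordinates are 0-based with
#' half-open intervals: a single pixel at (row 5, col 5) yields
#' `(5, 5, 6, 6)`.
#'
#' @param mask integer label matrix over \{0, 1, 2\}.
#' @param image_id id stored in the `image_id` column.
#' @return data frame with columns `image_id, class_id, row_min, col_min,
#'   row_max, col_max`.
#' @export
extract_bounding_boxes <- function(mask, image_id = 1L) {
  out <- list()
  for (cls in sort(setdiff(unique(as.vector(mask)), 0))) {
    lab <- label_components(mask == cls)
    n <- max(lab)
    if (n == 0) next
    idx <- which(lab > 0)
    rows <- (idx - 1L) %% nrow(mask)        # 0-based
    cols <- (idx - 1L) %/% nrow(mask)
    comp <- lab[idx]
    out[[length(out) + 1]] <- data.frame(
      image_id = image_id, class_id = as.integer(cls),
      row_min = as.integer(tapply(rows, comp, min)),
      col_min = as.integer(tapply(cols, comp, min)),
      row_max = as.integer(tapply(rows, comp, max)) + 1L,
      col_max = as.integer(tapply(cols, comp, max)) + 1L
    )
  }
  if (length(out) == 0)
    return(data.frame(image_id = integer(0), class_id = integer(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersection-over-union of two bounding boxes
#'
#' Boxes are `(row_min, col_min, row_max, col_max)` with half-open intervals;
#' accepts one-row data frames or named vectors.
#'
#' @param a,b boxes.
#' @return scalar in `[0, 1]` (0 for disjoint boxes); symmetric in its
#'   arguments.
#' @export
bb_iou <- function(a, b) {
  g <- function(x, f) as.numeric(if (is.data.frame(x)) x[[f]][1] else x[[f]])
  ih <- min(g(a, "row_max"), g(b, "row_max")) - max(g(a, "row_min"), g(b, "row_min"))
  iw <- min(g(a, "col_max"), g(b, "col_max")) - max(g(a, "col_min"), g(b, "col_min"))
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  area <- function(x) (g(x, "row_max") - g(x, "row_min")) *
    (g(x, "col_max") - g(x, "col_min"))
  inter / (area(a) + area(b) - inter)
}

#' Match method boxes against reference boxes
#'
#' Candidate pairs are those with IoU at or above `tau`; matching is
#' one-to-one, greedy by descending IoU (ties broken by method then reference
#' index), which prevents one method box from being counted against several
#' reference boxes.
#'
#' @param method_boxes,reference_boxes data frames of boxes from one image and
#'   one class.
#' @param tau minimum IoU considered a detection of the same event.
#' @return list with `matches` (data frame `method_idx, reference_idx, iou`),
#'   `unmatched_method` and `unmatched_reference` (integer row indices).
#' @export
match_boxes <- function(method_boxes, reference_boxes, tau = 0.1) {
  nm <- nrow(method_boxes); nr <- nrow(reference_boxes)
  pairs <- NULL
  if (nm > 0 && nr > 0) {
    iou <- outer(seq_len(nm), seq_len(nr),
                 Vectorize(function(i, j) bb_iou(method_boxes[i, ], reference_boxes[j, ])))
    cand <- which(iou >= tau, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(-iou[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_m <- logical(nm); used_r <- logical(nr)
      keep <- integer(0)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_m[i] && !used_r[j]) {
          used_m[i] <- TRUE; used_r[j] <- TRUE
          keep <- c(keep, k)
        }
      }
      if (length(keep) > 0)
        pairs <- data.frame(method_idx = cand[keep, 1],
                            reference_idx = cand[keep, 2],
                            iou = iou[cand[keep, , drop = FALSE]])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(method_idx = integer(0), reference_idx = integer(0),
                        iou = numeric(0))
  list(
    matches = pairs,
    unmatched_method = setdiff(seq_len(nm), pairs$method_idx),
    unmatched_reference = setdiff(seq_len(nr), pairs$reference_idx)
  )
}

#' Detection report: method boxes vs human reference boxes
#'
#' Boxes are grouped by image and class and matched with [match_boxes()].
#' Per class (plus an `"all"` row): total box counts, the false-positive
#' ratio (unmatched method boxes over total method boxes), the
#' false-negative ratio (unmatched reference boxes over total reference
#' boxes), matched-pair counts in the lower `[0.1, 0.5)` and higher
#' `[0.5, 1]` IoU bins, and the detection-overlap percentage
#' (100 * matched reference boxes / total reference boxes). A zero
#' denominator yields a ratio of 0 and sets the corresponding flag column.
#'
#' @param method_boxes,human_boxes box data frames (columns as written by
#'   [extract_bounding_boxes()]).
#' @param tau IoU matching threshold.
#' @param bin_split boundary between the lower and higher overlap bins.
#' @return data frame, one row per class and an `"all"` summary row.
#' @export
detection_report <- function(method_boxes, human_boxes, tau = 0.1,
                             bin_split = 0.5) {
  classes <- sort(union(unique(method_boxes$class_id), unique(human_boxes$class_id)))
  one_class <- function(cls) {
    mb <- method_boxes[is.na(cls) | method_boxes$class_id == cls, , drop = FALSE]
    hb <- human_boxes[is.na(cls) | human_boxes$class_id == cls, , drop = FALSE]
    images <- union(unique(mb$image_id), unique(hb$image_id))
    n_matched <- 0L; n_um <- 0L; n_ur <- 0L
    lower <- 0L; higher <- 0L
    for (im in images) {
      m <- match_boxes(mb[mb$image_id == im, , drop = FALSE],
                       hb[hb$image_id == im, , drop = FALSE], tau = tau)
      n_matched <- n_matched + nrow(m$matches)
      n_um <- n_um + length(m$unmatched_method)
      n_ur <- n_ur + length(m$unmatched_reference)
      lower <- lower + sum(m$matches$iou < bin_split)
      higher <- higher + sum(m$matches$iou >= bin_split)
    }
    data.frame(
      class = if (is.na(cls)) "all" else CLASS_LABELS[cls + 1],
      n_method_boxes = nrow(mb), n_reference_boxes = nrow(hb),
      false_positive_ratio = if (nrow(mb) > 0) n_um / nrow(mb) else 0,
      false_negative_ratio = if (nrow(hb) > 0) n_ur / nrow(hb) else 0,
      no_method_boxes = nrow(mb) == 0, no_reference_boxes = nrow(hb) == 0,
      matched_lower_bin = lower, matched_higher_bin = higher,
      detection_overlap_percent = if (nrow(hb) > 0) 100 * n_matched / nrow(hb) else 0
    )
  }
  res <- do.call(rbind, lapply(c(as.list(classes), NA), one_class))
  rownames(res) <- NULL
  res
}
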