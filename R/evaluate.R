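## Pixel-level segmentation evaluation: confusion matrices (rows = predicted
## class, columns = actual class), one-vs-rest per-class metric suite
## (accuracy, precision, recall, specificity, IoU), boundary F1 score, and
## the Global / Mean / Weighted aggregations.

#' Pixel confusion matrix
#'
#' `counts[i, j]` is the number of pixels predicted as class `i - 1` whose
#' true class is `j - 1` (rows = predicted, columns = actual).
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param K number of classes.
#' @param class_labels optional class names.
#' @return object of class `weakseg_confusion` with elements `counts` and
#'   `normalized` (rows divided by their sums; all-zero rows stay zero).
#' @export
confusion_matrix <- function(pred, truth, K = 3,
                             class_labels = CLASS_LABELS[seq_len(K)]) {
  if (!identical(dim(pred), dim(truth))) stop("pred and truth shapes differ")
  counts <- matrix(0, K, K, dimnames = list(predicted = class_labels,
                                            actual = class_labels))
  tab <- table(factor(as.vector(pred), levels = 0:(K - 1)),
               factor(as.vector(truth), levels = 0:(K - 1)))
  counts[] <- as.numeric(tab)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, normalized = normalized,
                 class_labels = class_labels),
            class = "weakseg_confusion")
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class: TP, FP, FN, TN and the standard formula suite
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `IoU = TP/(TP+FP+FN)`. Per-class accuracy is
#' `TP/(TP+FN)` (the per-class semantic-segmentation convention, identical to
#' recall); the column `accuracy_as_printed` additionally reports
#' `TP/(TP+TN)` for transparency. Undefined `0/0` ratios are `NaN` and are
#' excluded from Mean aggregation downstream.
#'
#' @param confusion a [confusion_matrix()] or a plain K x K count matrix
#'   (rows = predicted).
#' @return data frame, one row per class.
#' @export
per_class_metrics <- function(confusion) {
  counts <- if (inherits(confusion, "weakseg_confusion")) confusion$counts else confusion
  K <- nrow(counts)
  total <- sum(counts)
  tp <- diag(counts)
  fp <- rowSums(counts) - tp
  fn <- colSums(counts) - tp
  tn <- total - tp - fp - fn
  ratio <- function(a, b) ifelse(b > 0, a / b, NaN)
  data.frame(
    class = if (!is.null(rownames(counts))) rownames(counts) else as.character(0:(K - 1)),
    class_id = 0:(K - 1),
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = ratio(tp, tp + fn),
    accuracy_as_printed = ratio(tp, tp + tn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    iou = ratio(tp, tp + fp + fn),
    row.names = NULL
  )
}

# boundary pixels of a class region: region pixels with a 4-neighbour outside
# the region (out-of-image counts as outside)
mask_boundary <- function(mask, class_id) {
  region <- mask == class_id
  H <- nrow(region); W <- ncol(region)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- region
  inner <- pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)]
  region & !inner
}

#' Boundary F1 score for one class
#'
#' Boundary precision is the fraction of predicted boundary pixels lying
#' within `tolerance` (Euclidean) of a true boundary pixel; boundary recall is
#' the symmetric quantity; the score is their harmonic mean. Two empty
#' boundaries score 1; an empty boundary against a non-empty one scores 0.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param class_id class evaluated.
#' @param tolerance pixel tolerance; default `ceil(0.0075 * image diagonal)`.
#' @return scalar in `[0, 1]`.
#' @export
boundary_f1 <- function(pred, truth, class_id, tolerance = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("pred and truth shapes differ")
  if (is.null(tolerance))
    tolerance <- ceiling(0.0075 * sqrt(nrow(pred)^2 + ncol(pred)^2))
  bp <- mask_boundary(pred, class_id)
  bt <- mask_boundary(truth, class_id)
  if (!any(bp) && !any(bt)) return(1)
  if (!any(bp) || !any(bt)) return(0)
  dist_to <- function(boundary) {
    # distance of every pixel to the nearest boundary pixel
    as.matrix(EBImage::distmap(EBImage::Image(
      matrix(as.numeric(!boundary), nrow(boundary), ncol(boundary)))))
  }
  dt <- dist_to(bt)
  dp <- dist_to(bp)
  precision <- mean(dt[bp] <= tolerance)
  recall <- mean(dp[bt] <= tolerance)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Aggregate segmentation metrics over a set of images
#'
#' Pools per-image confusion matrices and reports the full metric suite:
#' per-class metrics (from the pooled confusion) plus per-class mean boundary
#' F1, and the three aggregations: `global_accuracy` (correct pixels over all
#' pixels, regardless of class), `mean_*` (unweighted average over classes,
#' `NaN` classes excluded), and `weighted_iou` (class IoUs weighted by true
#' class pixel shares).
#'
#' @param preds,truths lists of label matrices (same length and shapes).
#' @param K number of classes.
#' @param class_labels class names.
#' @param bfs_tolerance boundary F1 tolerance (default as in [boundary_f1()]).
#' @param mean_mode `"pooled"` pools pixels per class over all images before
#'   averaging over classes; `"per_image"` averages per-image per-class scores.
#' @return object of class `weakseg_seg_report`: list with `per_class`,
#'   `global_accuracy`, `mean_accuracy`, `mean_iou`, `weighted_iou`,
#'   `mean_bfs` and `confusion`.
#' @export
aggregate_metrics <- function(preds, truths, K = 3,
                              class_labels = CLASS_LABELS[seq_len(K)],
                              bfs_tolerance = NULL,
                              mean_mode = c("pooled", "per_image")) {
  mean_mode <- match.arg(mean_mode)
  if (length(preds) < 1 || length(preds) != length(truths))
    stop("need equal, non-empty lists of predictions and references")
  confs <- mapply(function(p, t) confusion_matrix(p, t, K, class_labels)$counts,
                  preds, truths, SIMPLIFY = FALSE)
  pooled <- Reduce(`+`, confs)
  rs <- rowSums(pooled)
  pooled_conf <- structure(list(counts = pooled,
                                normalized = pooled / ifelse(rs > 0, rs, 1),
                                class_labels = class_labels),
                           class = "weakseg_confusion")
  pc <- per_class_metrics(pooled_conf)

  bfs_mat <- vapply(seq_along(preds), function(i)
    vapply(0:(K - 1), function(cl)
      boundary_f1(preds[[i]], truths[[i]], cl, bfs_tolerance), numeric(1)),
    numeric(K))
  pc$bfs <- rowMeans(matrix(bfs_mat, nrow = K), na.rm = TRUE)

  if (mean_mode == "per_image") {
    per_img <- lapply(confs, per_class_metrics)
    acc_m <- rowMeans(vapply(per_img, function(m) m$accuracy, numeric(K)), na.rm = TRUE)
    iou_m <- rowMeans(vapply(per_img, function(m) m$iou, numeric(K)), na.rm = TRUE)
    mean_accuracy <- mean(acc_m, na.rm = TRUE)
    mean_iou <- mean(iou_m, na.rm = TRUE)
  } else {
    mean_accuracy <- mean(pc$accuracy, na.rm = TRUE)
    mean_iou <- mean(pc$iou, na.rm = TRUE)
  }
  shares <- colSums(pooled) / sum(pooled)   # true class pixel shares
  defined <- !is.nan(pc$iou)
  structure(list(
    per_class = pc,
    global_accuracy = sum(diag(pooled)) / sum(pooled),
    mean_accuracy = mean_accuracy,
    mean_iou = mean_iou,
    weighted_iou = sum(shares[defined] * pc$iou[defined]),
    mean_bfs = mean(pc$bfs, na.rm = TRUE),
    confusion = pooled_conf,
    n_images = length(preds),
    mean_mode = mean_mode
  ), class = "weakseg_seg_report")
}

#' @export
print.weakseg_seg_report <- function(x, ...) {
  cat(sprintf("Segmentation report over %d image(s)\n", x$n_images))
  cat(sprintf("  global accuracy: %.4f\n", x$global_accuracy))
  cat(sprintf("  mean accuracy:   %.4f\n", x$mean_accuracy))
  cat(sprintf("  mean IoU:        %.4f\n", x$mean_iou))
  cat(sprintf("  weighted IoU:    %.4f\n", x$weighted_iou))
  cat(sprintf("  mean BFS:        %.4f\n", x$mean_bfs))
  cat("per class:\n")
  print(x$per_class[, c("class", "accuracy", "precision", "recall",
                        "specificity", "iou", "bfs")], digits = 4)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test for rating scores
#'
#' `D` is the supremum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic two-sample Kolmogorov distribution.
#'
#' @param scores_a,scores_b numeric vectors (both non-empty).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0)
    stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Compare rating scores between two labelling methods
#'
#' Takes a table of expert ratings (columns `expert_id`, `image_id`, `method`,
#' `score`) and runs the two-sample KS test between the two methods, overall
#' and per expert.
#'
#' @param ratings data frame of rating records; scores on a 1-10 scale.
#' @param methods the two method labels to compare.
#' @return list with per-method mean scores, the overall KS result and a per
#'   expert data frame.
#' @export
compare_ratings <- function(ratings, methods = c("CIP", "CDL")) {
  stopifnot(all(c("expert_id", "method", "score") %in% names(ratings)))
  if (any(ratings$score < 1 | ratings$score > 10))
    stop("scores must lie in 1..10")
  a <- ratings$score[ratings$method == methods[1]]
  b <- ratings$score[ratings$method == methods[2]]
  overall <- ks_two_sample(a, b)
  per_expert <- do.call(rbind, lapply(split(ratings, ratings$expert_id), function(r) {
    ks <- ks_two_sample(r$score[r$method == methods[1]],
                        r$score[r$method == methods[2]])
    data.frame(expert_id = r$expert_id[1], D = ks$statistic,
               p_value = ks$p_value)
  }))
  rownames(per_expert) <- NULL
  list(
    mean_scores = stats::setNames(c(mean(a), mean(b)), methods),
    ks = overall,
    per_expert = per_expert
  )
}
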