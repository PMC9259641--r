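test_that("confusion matrix counts pixels with rows = predicted, cols = actual", {
  # 2x2 toy case, enumerated by hand
  pred <- matrix(c(0L, 1L, 1L, 2L), 2, 2)
  truth <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  cm <- confusion_matrix(pred, truth, K = 3)
  expect_equal(sum(cm$counts), 4)
  expect_equal(unname(cm$counts["background", "background"]), 1)
  expect_equal(unname(cm$counts["phagophore", "phagophore"]), 1)
  expect_equal(unname(cm$counts["phagophore", "autolysosome"]), 1)
  expect_equal(unname(cm$counts["autolysosome", "autolysosome"]), 1)

  # perfect prediction: diagonal, trace = pixel count
  cm2 <- confusion_matrix(truth, truth, K = 3)
  expect_equal(sum(diag(cm2$counts)), length(truth))
  expect_equal(sum(cm2$counts) - sum(diag(cm2$counts)), 0)

  # row normalisation: rows sum to 1 (or 0 for empty predicted classes)
  expect_true(all(abs(rowSums(cm$normalized) - c(1, 1, 1)) < 1e-12))
  expect_error(confusion_matrix(pred, matrix(0L, 3, 3)), "shape")
})

test_that("per-class metrics reproduce the formula suite on hand-built counts", {
  # one-vs-rest counts TP=6 FP=2 FN=2 TN=90 for class 1 in a 2-class confusion
  counts <- matrix(c(90, 2, 2, 6), 2, 2,
                   dimnames = list(predicted = c("bg", "ev"),
                                   actual = c("bg", "ev")))
  m <- per_class_metrics(counts)
  ev <- m[m$class == "ev", ]
  expect_equal(ev$tp, 6)
  expect_equal(ev$fp, 2)
  expect_equal(ev$fn, 2)
  expect_equal(ev$tn, 90)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$iou, 0.6)
  expect_equal(ev$specificity, 90 / 92)
  expect_equal(ev$accuracy, 0.75)             # TP/(TP+FN)
  expect_equal(ev$accuracy_as_printed, 6 / 96) # TP/(TP+TN), misprint exposed

  # perfect class
  perfect <- per_class_metrics(diag(c(10, 5)))
  expect_true(all(perfect$precision == 1))
  expect_true(all(perfect$iou == 1))

  # class absent from truth and prediction -> NaN, excluded from means
  counts3 <- matrix(0, 3, 3)
  counts3[1, 1] <- 10; counts3[2, 2] <- 5
  m3 <- per_class_metrics(counts3)
  expect_true(is.nan(m3$iou[3]))
  expect_true(is.nan(m3$precision[3]))
})

test_that("IoU is bounded by precision and recall for every class", {
  set.seed(11)
  for (rep in 1:20) {
    counts <- matrix(rpois(9, 20), 3, 3)
    m <- per_class_metrics(counts)
    ok <- !is.nan(m$iou)
    expect_true(all(m$iou[ok] <= m$precision[ok] + 1e-12))
    expect_true(all(m$iou[ok] <= m$recall[ok] + 1e-12))
  }
})

test_that("boundary F1 handles identity, small and large shifts, and empties", {
  sq <- function(r0, c0, side = 6, size = 32) {
    m <- matrix(0L, size, size)
    m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1L
    m
  }
  a <- sq(10, 10)
  expect_equal(boundary_f1(a, a, 1), 1)

  # 1-pixel shift within tolerance >= 1 -> all boundary pixels matched
  expect_equal(boundary_f1(sq(11, 10), a, 1, tolerance = 1), 1)
  expect_equal(boundary_f1(sq(11, 10), a, 1, tolerance = 2), 1)

  # shift by 3x tolerance -> no boundary pixel within reach on the far sides
  expect_equal(boundary_f1(sq(10, 22), a, 1, tolerance = 2), 0)

  # empty-vs-empty -> 1; empty-vs-nonempty -> 0
  empty <- matrix(0L, 32, 32)
  expect_equal(boundary_f1(empty, empty, 1), 1)
  expect_equal(boundary_f1(empty, a, 1), 0)
  expect_equal(boundary_f1(a, empty, 1), 0)

  # default tolerance is ceil(0.0075 * diagonal)
  expect_equal(boundary_f1(sq(11, 10), a, 1), 1)  # 32x32: tol = 1
})

test_that("aggregation pools confusions additively and weights IoU by pixel share", {
  set.seed(5)
  preds <- lapply(1:3, function(i) matrix(sample(0:2, 64, TRUE), 8, 8))
  truths <- lapply(1:3, function(i) matrix(sample(0:2, 64, TRUE), 8, 8))
  rep <- aggregate_metrics(preds, truths)

  pooled <- Reduce(`+`, lapply(1:3, function(i)
    confusion_matrix(preds[[i]], truths[[i]])$counts))
  expect_equal(rep$confusion$counts, pooled)
  expect_equal(rep$global_accuracy, sum(diag(pooled)) / sum(pooled))

  shares <- colSums(pooled) / sum(pooled)
  expect_equal(rep$weighted_iou, sum(shares * rep$per_class$iou))
  expect_equal(rep$mean_iou, mean(rep$per_class$iou))
  expect_true(all(c(rep$global_accuracy, rep$mean_accuracy, rep$mean_iou,
                    rep$weighted_iou, rep$mean_bfs) >= 0))
  expect_true(all(c(rep$global_accuracy, rep$mean_accuracy, rep$mean_iou,
                    rep$weighted_iou, rep$mean_bfs) <= 1))

  # hand-checked weighted aggregation: IoUs 0.2 / 0.8 with shares 0.9 / 0.1
  expect_equal(0.9 * 0.2 + 0.1 * 0.8, 0.26)
  expect_equal(mean(c(0.2, 0.8)), 0.5)

  # single class, all correct -> every aggregate is 1
  ones <- list(matrix(0L, 4, 4))
  rep1 <- aggregate_metrics(ones, ones, K = 1, class_labels = "background")
  expect_equal(rep1$global_accuracy, 1)
  expect_equal(rep1$mean_iou, 1)
  expect_equal(rep1$weighted_iou, 1)
  expect_equal(rep1$mean_bfs, 1)
})

test_that("KS statistic matches the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(1:3, 11:13)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$statistic, 1 / 3,
               tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:25) {
    a <- sample(1:10, sample(3:30, 1), replace = TRUE)
    b <- sample(1:10, sample(3:30, 1), replace = TRUE)
    expect_equal(ks_two_sample(a, b)$statistic, brute_force_ks_D(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("rating comparison runs the KS analysis per expert", {
  set.seed(3)
  ratings <- expand.grid(expert_id = 1:4, image_id = 1:20,
                         method = c("CIP", "CDL"))
  ratings$score <- ifelse(ratings$method == "CIP",
                          pmin(10, pmax(1, round(rnorm(nrow(ratings), 4.3, 1.5)))),
                          pmin(10, pmax(1, round(rnorm(nrow(ratings), 8.3, 1)))))
  res <- compare_ratings(ratings)
  expect_named(res$mean_scores, c("CIP", "CDL"))
  expect_lt(res$mean_scores["CIP"], res$mean_scores["CDL"])
  expect_lt(res$ks$p_value, 0.01)
  expect_equal(nrow(res$per_expert), 4)
})
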