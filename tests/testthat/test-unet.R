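# deterministic 32x32 two-channel field with one event of each class
two_event_pair <- function() {
  size <- 32
  disk <- function(r0, c0, radius) {
    outer((seq_len(size) - 0.5 - r0)^2, (seq_len(size) - 0.5 - c0)^2, "+") <=
      radius^2
  }
  d1 <- disk(10, 10, 4)    # phagophore: bright in both channels
  d2 <- disk(22, 22, 5)    # autolysosome: red only, larger
  red <- matrix(0.05, size, size)
  green <- matrix(0.05, size, size)
  red[d1] <- 0.7; green[d1] <- 0.8
  red[d2] <- 0.8; green[d2] <- 0.1
  mask <- matrix(0L, size, size)
  mask[d1] <- 1L; mask[d2] <- 2L
  img <- array(0, c(size, size, 2))
  img[, , 1] <- red; img[, , 2] <- green
  list(image = normalize_image(img), mask = mask)
}

test_that("architecture spec and training config enforce their invariants", {
  spec <- unet_spec()
  expect_equal(spec$depth, 3L)
  expect_equal(spec$skip_connections, spec$depth)
  expect_error(unet_spec(depth = 0), "depth")

  cfg <- train_config()
  expect_equal(cfg$initial_lr, 0.002)     # weak-label mode default
  expect_equal(cfg$split, c(0.85, 0.10, 0.05))
  mdl <- train_config(mode = "mdl")
  expect_equal(mdl$initial_lr, 0.001)
  expect_equal(mdl$split, c(0.80, 0.10, 0.10))
  expect_error(train_config(split = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("the learning rate drops by the configured factor every 3 epochs", {
  pair <- two_event_pair()
  m <- train_model(rep(list(pair$image), 4), rep(list(pair$mask), 4),
                   train_config(epochs = 4, augment = FALSE, seed = 1),
                   unet_spec(depth = 2, base_filters = 4))
  expect_equal(m$log$lr[1:3], rep(0.002, 3))
  expect_equal(m$log$lr[4], 0.002 * 0.8)
})

test_that("an overfit run reproduces its training masks and drives the loss down", {
  # one single-class field per event class: within each image the event is
  # the sole (hence maximally weighted) rare class of the dice loss
  size <- 32
  disk <- function(r0, c0, radius)
    outer((seq_len(size) - 0.5 - r0)^2, (seq_len(size) - 0.5 - c0)^2, "+") <=
    radius^2
  mk <- function(cls) {
    d <- disk(16, 16, if (cls == 1) 4 else 5)
    red <- matrix(0.05, size, size); green <- matrix(0.05, size, size)
    if (cls == 1) { red[d] <- 0.7; green[d] <- 0.8 }
    else { red[d] <- 0.8; green[d] <- 0.1 }
    mask <- matrix(0L, size, size); mask[d] <- cls
    img <- array(0, c(size, size, 2))
    img[, , 1] <- red; img[, , 2] <- green
    list(image = normalize_image(img), mask = mask)
  }
  a <- mk(1L); b <- mk(2L)
  m <- train_model(c(rep(list(a$image), 4), rep(list(b$image), 4)),
                   c(rep(list(a$mask), 4), rep(list(b$mask), 4)),
                   train_config(epochs = 60, augment = FALSE, seed = 2,
                                initial_lr = 0.01, lr_drop_every = 20,
                                grad_clip = 1),
                   unet_spec(base_filters = 8))
  expect_lt(tail(m$log$train_loss, 1), 0.1)
  expect_gt(mean(predict(m, a$image) == a$mask), 0.95)
  expect_gt(mean(predict(m, b$image) == b$mask), 0.95)

  # prediction surface: values in {0,1,2}, spatial shape preserved
  pred <- predict(m, b$image)
  expect_identical(dim(pred), dim(b$mask))
  expect_true(all(pred %in% 0:2))
  prob <- predict(m, b$image, type = "prob")
  expect_equal(dim(prob), c(32, 32, 3))
  expect_equal(apply(prob, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-10)
})

test_that("training is reproducible for a fixed seed and logs validation loss", {
  pair <- two_event_pair()
  args <- list(rep(list(pair$image), 4), rep(list(pair$mask), 4),
               train_config(epochs = 2, seed = 5),
               unet_spec(depth = 2, base_filters = 4),
               val_images = list(pair$image), val_masks = list(pair$mask))
  m1 <- do.call(train_model, args)
  m2 <- do.call(train_model, args)
  expect_equal(m1$log$train_loss, m2$log$train_loss, tolerance = 1e-12)
  expect_equal(m1$log$val_loss, m2$log$val_loss, tolerance = 1e-12)
  expect_false(any(is.na(m1$log$val_loss)))
})

test_that("input validation catches shape and channel errors", {
  pair <- two_event_pair()
  spec <- unet_spec(depth = 2, base_filters = 4)
  m <- train_model(rep(list(pair$image), 4), rep(list(pair$mask), 4),
                   train_config(epochs = 1, seed = 1), spec)
  expect_error(predict(m, array(0, c(32, 32, 3))), "channels")
  expect_error(predict(m, array(0, c(30, 30, 2))), "divisible")
  expect_error(train_model(list(pair$image), list(pair$mask),
                           train_config(epochs = 1), spec),
               "batch_size")
  expect_warning(train_model(rep(list(pair$image), 4),
                             rep(list(matrix(0L, 32, 32)), 4),
                             train_config(epochs = 1, seed = 1), spec),
                 "absent")
})

test_that("the internal training loss matches the exported loss function", {
  pair <- two_event_pair()
  set.seed(3)
  sc <- matrix(runif(1024 * 3), 1024, 3)
  sc <- sc / rowSums(sc)
  y <- as.integer(pair$mask)
  expect_equal(weakseg:::.unet_gdl_cpp(sc, y, 3L),
               generalized_dice_loss(sc, y), tolerance = 1e-12)
})

test_that("models survive a JSON save/load round trip", {
  pair <- two_event_pair()
  m <- train_model(rep(list(pair$image), 4), rep(list(pair$mask), 4),
                   train_config(epochs = 1, seed = 1),
                   unet_spec(depth = 2, base_filters = 4))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, pair$image), predict(m, pair$image))
  expect_equal(m2$spec$depth, m$spec$depth)
  unlink(path)
})
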