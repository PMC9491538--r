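tiny_set <- function(n = 6, seed = 303) {
  # learnable toy set: dark ellipse on bright noisy tissue
  set.seed(seed)
  H <- 64; W <- 64
  images <- array(0, c(H, W, n)); masks <- array(0, c(H, W, n))
  rows <- outer(seq_len(H), rep(1, W)); cols <- outer(rep(1, H), seq_len(W))
  for (k in seq_len(n)) {
    cy <- 32 + sample(-4:4, 1); cx <- 32 + sample(-4:4, 1)
    b <- sample(4:7, 1)
    inside <- ((rows - cy) / 14)^2 + ((cols - cx) / b)^2 <= 1
    img <- 0.35 + 0.05 * rnorm(H * W)
    img[inside] <- -0.6 + 0.05 * rnorm(sum(inside))
    images[, , k] <- pmin(1, pmax(-1, img))
    masks[, , k] <- inside
  }
  list(images = images, masks = masks)
}

test_that("model construction is shaped, bounded and seeded", {
  m <- build_model(depth = 3, base_channels = 8, seed = 1)
  expect_gt(m$n_params, 0)
  m2 <- build_model(depth = 3, base_channels = 8, seed = 1)
  expect_identical(m$params, m2$params)
  m3 <- build_model(depth = 3, base_channels = 8, seed = 2)
  expect_false(identical(m$params, m3$params))

  x <- matrix(runif(64 * 64, -1, 1), 64)
  p <- predict_masks(m, array(x, c(64, 64, 1)))
  expect_identical(dim(p$masks), c(64L, 64L, 1L))
  expect_true(all(p$masks >= 0 & p$masks <= 255))
})

test_that("geometry contract: inputs must be divisible by 32", {
  m <- build_model(3, 8, seed = 1)
  bad <- array(0, c(63, 64, 1))
  expect_error(predict_masks(m, bad), "geometry error")
  expect_error(train_model(m, bad, bad), "geometry error")
  expect_error(train_model(m, array(0, c(64, 64, 0)),
                           array(0, c(64, 64, 0))), "empty training set")
})

test_that("zero learning rate leaves parameters untouched", {
  ts <- tiny_set()
  m <- build_model(3, 8, seed = 5)
  m2 <- train_model(m, ts$images, ts$masks, epochs = 2, learning_rate = 0,
                    seed = 1)
  # unchanged up to the single-precision storage of the compute path
  expect_equal(m$params, m2$params, tolerance = 1e-6)
})

test_that("training is deterministic and overfits a small set", {
  ts <- tiny_set()
  m0 <- build_model(3, 8, seed = 5)
  m1 <- train_model(m0, ts$images, ts$masks, epochs = 40,
                    learning_rate = 1e-3, seed = 9)
  m1b <- train_model(m0, ts$images, ts$masks, epochs = 40,
                     learning_rate = 1e-3, seed = 9)
  expect_identical(m1$params, m1b$params)
  # loss broadly decreases
  expect_lt(mean(tail(m1$loss_history, 5)), mean(head(m1$loss_history, 5)))
  # overfit: near-perfect IoU on the training frames themselves
  pred <- predict_masks(m1, ts$images)
  ious <- vapply(seq_len(dim(ts$masks)[3]), function(t)
    iou(ts$masks[, , t] > 0.5, pred$masks[, , t] / 255 > 0.5), numeric(1))
  expect_gte(mean(ious), 0.95)
})

test_that("inference is stateless and respects the ROI contract", {
  ts <- tiny_set(n = 1)
  m <- build_model(3, 8, seed = 5)
  rep3 <- array(rep(ts$images[, , 1], 3), c(64, 64, 3))
  p <- predict_masks(m, rep3)
  expect_identical(p$masks[, , 1], p$masks[, , 2])
  expect_identical(p$masks[, , 1], p$masks[, , 3])

  roi <- roi_box(16, 8, 32, 32)
  pr <- predict_masks(m, ts$images, roi = roi)
  outside <- pr$masks
  outside[(roi$y0 + 1):(roi$y0 + roi$height),
          (roi$x0 + 1):(roi$x0 + roi$width), ] <- 0L
  expect_true(all(outside == 0))
  # the full-frame embedding restricted to the ROI is the ROI inference
  crop <- pr$masks[(roi$y0 + 1):(roi$y0 + roi$height),
                   (roi$x0 + 1):(roi$x0 + roi$width), 1]
  direct <- predict_masks(m, array(ts$images[(roi$y0 + 1):(roi$y0 + 32),
                                             (roi$x0 + 1):(roi$x0 + 32), 1],
                                   c(32, 32, 1)))
  expect_identical(crop, direct$masks[, , 1])
})
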