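# Dice coefficient closed forms, U-Net training contracts, stitching.

test_that("dice closed forms hold", {
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_identical(dice_coefficient(m, m, epsilon = 0), 1)
  expect_identical(dice_coefficient(m, m, epsilon = 1), 1)
  a <- matrix(0, 4, 4); a[1, ] <- 1
  b <- matrix(0, 4, 4); b[3, ] <- 1
  expect_identical(dice_coefficient(a, b, epsilon = 0), 0)
  # half-confidence everywhere against an all-ones mask: 2 * 0.5n / 1.5n
  pred <- matrix(0.5, 6, 6)
  truth <- matrix(1, 6, 6)
  expect_equal(dice_coefficient(pred, truth, epsilon = 0), 2 / 3)
  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape mismatch")
  expect_error(dice_coefficient(matrix(2, 2, 2), matrix(1, 2, 2)))
})

test_that("dice is symmetric for binary masks and 1 - dice is a loss", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(rbinom(36, 1, 0.5), 6, 6)
    b <- matrix(rbinom(36, 1, 0.5), 6, 6)
    expect_equal(dice_coefficient(a, b, 0), dice_coefficient(b, a, 0))
    if (sum(a) > 0) {
      loss <- 1 - dice_coefficient(a, a, 0)
      expect_identical(loss, 0)
      if (!identical(a, b)) expect_gt(1 - dice_coefficient(a, b, 0), 0)
    }
  }
})

test_that("the dice training gradient matches finite differences", {
  set.seed(3)
  z <- matrix(rnorm(16), 4, 4)
  truth <- matrix(rbinom(16, 1, 0.5), 4, 4)
  prob <- 1 / (1 + exp(-z))
  db <- slideheat:::dice_forward_backward(prob, truth, eps = 1)
  eps <- 1e-6
  for (k in c(1, 7, 16)) {
    z2 <- z; z2[k] <- z[k] + eps
    p2 <- 1 / (1 + exp(-z2))
    num <- (slideheat:::dice_forward_backward(p2, truth, 1)$loss -
              db$loss) / eps
    expect_equal(db$dz[k], num, tolerance = 1e-4)
  }
})

test_that("stitching averages overlapping tiles", {
  # constant tiles reconstruct the constant
  maps <- replicate(4, matrix(0.7, 4, 4), simplify = FALSE)
  offs <- tibble::tibble(offset_x = c(0, 2, 0, 2), offset_y = c(0, 0, 2, 2))
  st <- stitch(maps, offs, width = 6, height = 6)
  expect_equal(st, matrix(0.7, 6, 6))
  # a single tile covering the canvas is the identity
  one <- matrix(runif(16), 4, 4)
  expect_equal(stitch(list(one), tibble::tibble(offset_x = 0, offset_y = 0),
                      4, 4), one)
  # two half-overlapping tiles: the overlap is exactly the mean
  two <- stitch(list(matrix(0.2, 4, 4), matrix(0.8, 4, 4)),
                tibble::tibble(offset_x = c(0, 2), offset_y = c(0, 0)),
                width = 6, height = 4)
  expect_equal(two[, 3:4], matrix(0.5, 4, 2))
  expect_equal(two[, 1:2], matrix(0.2, 4, 2))
  expect_equal(two[, 5:6], matrix(0.8, 4, 2))
})

test_that("stitching is linear and rejects uncovered pixels", {
  set.seed(8)
  maps <- list(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4))
  offs <- tibble::tibble(offset_x = c(0, 2), offset_y = c(0, 0))
  s1 <- stitch(maps, offs, 6, 4)
  s3 <- stitch(lapply(maps, function(m) 3 * m), offs, 6, 4)
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
  expect_error(stitch(maps, offs, width = 10, height = 4), "covered by no")
})

test_that("overhanging tile regions are cropped before averaging", {
  # tile extends 2 px past the canvas; the overhang must not wrap or error
  st <- stitch(list(matrix(1, 4, 4), matrix(0, 4, 4)),
               tibble::tibble(offset_x = c(0, 2), offset_y = c(0, 0)),
               width = 4, height = 4)
  expect_equal(st[, 1:2], matrix(1, 4, 2))
  expect_equal(st[, 3:4], matrix(0.5, 4, 2))
})

test_that("segmentation config validates its invariants", {
  expect_error(segmentation_config(depth = 0))
  expect_error(segmentation_config(base_filters = 0))
  expect_error(segmentation_config(depth = 5, input_size = 48))
  cfg <- segmentation_config()
  expect_identical(cfg$depth, 4L)
  expect_identical(cfg$base_filters, 64L)
  expect_identical(cfg$loss, "dice")
})

test_that("training fails without positive pixels and keeps shapes", {
  set.seed(2)
  tiles <- tibble::tibble(
    tile = replicate(4, array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)),
                     simplify = FALSE),
    mask_tile = replicate(4, matrix(0, 32, 32), simplify = FALSE))
  cfg <- segmentation_config(depth = 2, base_filters = 4, input_size = 32,
                             epochs = 1)
  expect_error(train_unet(tiles, cfg), "no positive pixels")

  tiles$mask_tile[[1]][10:20, 10:20] <- 1
  m <- train_unet(tiles, cfg)
  pm <- predict_tiles(m, tiles)
  expect_identical(dim(pm[[1]]), c(32L, 32L))
  expect_true(all(pm[[1]] >= 0 & pm[[1]] <= 1))
})

test_that("training logs are reproducible for a fixed seed", {
  set.seed(4)
  tiles <- tibble::tibble(
    tile = replicate(6, array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)),
                     simplify = FALSE),
    mask_tile = replicate(6, matrix(rbinom(32 * 32, 1, 0.3), 32, 32),
                          simplify = FALSE),
    split = rep(c("training", "validation"), c(4, 2)))
  cfg <- segmentation_config(depth = 2, base_filters = 4, input_size = 32,
                             epochs = 2, seed = 9)
  m1 <- train_unet(tiles, cfg)
  m2 <- train_unet(tiles, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  expect_identical(nrow(m1$log), 2L)
})

test_that("a high-contrast texture tile set is segmented well", {
  # tumor-textured left half vs normal right half, many seeds
  set.seed(10)
  mk_tile <- function(s) {
    sl <- generate_slide(64, 64, 0, seed = 600 + s, patch_size = 64)
    img <- sl$image
    tum <- generate_slide(64, 64, 0, seed = 700 + s, patch_size = 64,
                          normal_params = tumor_texture_params())
    w <- sample(20:44, 1)
    img[, 1:w, ] <- tum$image[, 1:w, ]
    msk <- matrix(0, 64, 64); msk[, 1:w] <- 1
    list(tile = img, mask = msk)
  }
  tl <- lapply(1:28, mk_tile)
  tiles <- tibble::tibble(tile = lapply(tl, `[[`, "tile"),
                          mask_tile = lapply(tl, `[[`, "mask"),
                          split = rep(c("training", "validation"), c(22, 6)))
  m <- train_unet(tiles, unet_test_config(epochs = 5, seed = 1))
  expect_gte(m$val_dice, 0.8)
  expect_identical(m$best_epoch, which.max(m$log$val_dice))
})
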