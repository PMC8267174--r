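# Tiling: grid arithmetic, half-overlap subsampling, augmentation
# algebra, and balanced leakage-free manifests.

test_that("patch grids follow the floor((dim - patch)/stride + 1) rule", {
  img <- array(128, c(256, 512, 3))        # H x W
  p <- tile_slide(img, patch_size = 128, stride = 128)
  expect_identical(nrow(p), 8L)            # 4 x 2 grid
  # row-major enumeration: x varies fastest
  expect_identical(p$x[1:4], c(0L, 128L, 256L, 384L))
  expect_identical(p$y[1:4], rep(0L, 4))

  one <- tile_slide(array(0, c(128, 128, 3)), patch_size = 128)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$x, one$y), c(0L, 0L))

  # stride half the patch: offsets 0, 64, ..., 384 per axis
  dense <- tile_slide(array(0, c(512, 512, 3)), patch_size = 128,
                      stride = 64)
  expect_identical(nrow(dense), 49L)
  expect_identical(sort(unique(dense$x)), seq(0L, 384L, 64L))

  # smaller than one patch with drop: empty, not an error
  tiny <- tile_slide(array(0, c(64, 64, 3)), patch_size = 128)
  expect_identical(nrow(tiny), 0L)
})

test_that("pad edge policy completes edge tiles by reflection", {
  img <- array(seq_len(96 * 96 * 3), c(96, 96, 3))
  p <- tile_slide(img, patch_size = 64, stride = 64, edge_policy = "pad")
  expect_identical(nrow(p), 4L)
  edge <- p$image[[4]]                     # tile at (64, 64): 32 px real
  expect_identical(dim(edge), c(64L, 64L, 3L))
  expect_identical(edge[1:32, 1:32, ], img[65:96, 65:96, ])
  # mirrored region: row 33 reflects row 32 (edge included)
  expect_identical(edge[33, 1:32, 1], img[96, 65:96, 1])
})

test_that("patches re-crop exactly from the source slide", {
  sl <- small_slides()[[1]]
  p <- tile_slide(sl, patch_size = 128)
  for (k in c(1L, 7L, nrow(p))) {
    expect_identical(p$image[[k]], recrop_patch(p[k, ], sl))
  }
})

test_that("a 1,024 patch yields 64 half-overlap tiles", {
  patch <- array(seq_len(1024 * 1024 * 3) %% 251, c(1024, 1024, 3))
  tl <- subsample_half_overlap(patch)
  expect_identical(nrow(tl), 64L)
  expect_identical(sort(unique(tl$offset_x)), seq(0L, 896L, 128L))
  expect_identical(dim(tl$tile[[1]]), c(256L, 256L, 3L))
  # tile at (0, 0) is the top-left crop, pixel for pixel
  expect_identical(tl$tile[[1]], patch[1:256, 1:256, ])
})

test_that("a 256 input yields the 4 tiles at offsets {0, 128}^2", {
  patch <- array(runif(256 * 256 * 3), c(256, 256, 3))
  tl <- subsample_half_overlap(patch)
  expect_identical(nrow(tl), 4L)
  expect_identical(unique(sort(tl$offset_x)), c(0L, 128L))
  expect_identical(unique(sort(tl$offset_y)), c(0L, 128L))
  expect_error(subsample_half_overlap(array(0, c(250, 250, 3))),
               "divisible")
  expect_error(subsample_half_overlap(array(0, c(256, 512, 3))),
               "square|divisible")
})

test_that("mask tiles are cut with identical geometry", {
  patch <- array(runif(256 * 256 * 3), c(256, 256, 3))
  mask <- matrix(rbinom(256 * 256, 1, 0.3), 256, 256)
  tl <- subsample_half_overlap(patch, mask = mask)
  expect_identical(tl$mask_tile[[1]], mask[1:256, 1:256])
  k <- which(tl$offset_x == 128 & tl$offset_y == 0)
  expect_identical(tl$mask_tile[[k]][, 1:128], mask[1:256, 129:256])
})

test_that("half-overlap tiles stitched by averaging reconstruct a constant", {
  patch <- array(0.7 * 255, c(256, 256, 3))
  tl <- subsample_half_overlap(patch)
  maps <- lapply(tl$tile, function(t) t[, , 1] / 255)
  st <- stitch(maps, tl[, c("offset_x", "offset_y")],
               width = 256, height = 256)
  expect_equal(st, matrix(0.7, 256, 256), tolerance = 1e-12)
})

test_that("augmentation produces one record per op and inherits labels", {
  rec <- small_pool()[1, ]
  a <- augment(rec)
  expect_identical(nrow(a), 5L)
  expect_identical(unique(a$label), rec$label)
  expect_identical(unique(a$x), rec$x)
  expect_setequal(a$augmentation_tag,
                  c("rot90", "rot180", "rot270", "fliph", "flipv"))
})

test_that("augmentation ops satisfy their algebra", {
  set.seed(1)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  apply_aug <- function(x, tag) slideheat:::apply_augmentation(x, tag)
  expect_identical(apply_aug(apply_aug(img, "rot180"), "rot180"), img)
  expect_identical(apply_aug(apply_aug(img, "fliph"), "fliph"), img)
  # fliph then flipv equals rot180
  expect_identical(apply_aug(apply_aug(img, "fliph"), "flipv"),
                   apply_aug(img, "rot180"))
  # four quarter turns are the identity
  x <- img
  for (i in 1:4) x <- apply_aug(x, "rot90")
  expect_identical(x, img)
})

test_that("balanced manifests hit their targets without leakage", {
  man <- small_manifest()
  counts <- manifest_counts(man)
  expect_identical(sort(unique(counts$n)), c(6L, 18L))
  # class balance within 1% per split
  wide <- split(counts$n, counts$split)
  for (w in wide) expect_lte(abs(diff(w)) / max(w), 0.01)
  # no parent appears in two splits
  by_split <- split(man$parent_id, man$split)
  expect_length(intersect(by_split$training, by_split$validation), 0)
  expect_length(intersect(by_split$training, by_split$testing), 0)
  expect_length(intersect(by_split$validation, by_split$testing), 0)
  # augmented descendants share their parent's split
  parents <- man[man$augmentation_tag == "identity", ]
  aug <- man[man$augmentation_tag != "identity", ]
  expect_identical(aug$split,
                   parents$split[match(aug$parent_id, parents$patch_id)])
})

test_that("manifest building is deterministic and fails loudly on deficits", {
  m1 <- build_balanced_manifest(small_pool(),
                                target = c(training = 12, validation = 6,
                                           testing = 6), seed = 3)
  m2 <- build_balanced_manifest(small_pool(),
                                target = c(training = 12, validation = 6,
                                           testing = 6), seed = 3)
  expect_identical(m1$patch_id, m2$patch_id)
  expect_identical(m1$split, m2$split)
  expect_error(
    build_balanced_manifest(small_pool(),
                            target = c(training = 500, validation = 6,
                                       testing = 6), seed = 3),
    "deficit")
})

test_that("default targets follow the roughly 8:1:1 split structure", {
  # 100 parents per class: expect 6x augmentation capacity used as 80/10/10
  set.seed(4)
  fake <- tibble::tibble(
    slide_id = "s",
    patch_id = sprintf("p%03d_%s", rep(1:100, 2), rep(c("n", "c"), each = 100)),
    x = 0L, y = 0L, size = 8L,
    label = rep(c("normal", "carcinoma"), each = 100),
    tumor_fraction = rep(c(0, 1), each = 100),
    background_flag = FALSE,
    augmentation_tag = "identity",
    image = replicate(200, array(runif(8 * 8 * 3), c(8, 8, 3)),
                      simplify = FALSE)
  )
  man <- build_balanced_manifest(fake, seed = 1)
  counts <- manifest_counts(man)
  tr <- counts$n[counts$split == "training"][1]
  va <- counts$n[counts$split == "validation"][1]
  te <- counts$n[counts$split == "testing"][1]
  expect_identical(tr / va, 8)
  expect_identical(va, te)
})

test_that("background flagging marks near-white patches", {
  white <- array(250, c(64, 64, 3))
  tissue <- array(180, c(64, 64, 3))
  img <- array(250, c(64, 128, 3))
  img[, 65:128, ] <- tissue
  p <- tile_slide(img, patch_size = 64)
  expect_identical(p$background_flag, c(TRUE, FALSE))
})
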