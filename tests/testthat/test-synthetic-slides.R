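# Synthetic slide generator: labels, determinism, mask rasterization,
# class separability, annotation round trips.

test_that("slide label follows the tumor-region count", {
  sl0 <- generate_slide(256, 256, 0, seed = 1, patch_size = 128)
  expect_identical(sl0$slide_label, "normal")
  expect_length(sl0$tumor_polygons, 0)

  sl2 <- generate_slide(512, 256, 2, seed = 1, patch_size = 128,
                        region_radius_range = c(40, 60))
  expect_identical(sl2$slide_label, "cancerous")
  expect_length(sl2$tumor_polygons, 2)
  for (poly in sl2$tumor_polygons) {
    expect_true(all(poly[, 1] >= 0 & poly[, 1] <= sl2$width))
    expect_true(all(poly[, 2] >= 0 & poly[, 2] <= sl2$height))
  }
})

test_that("equal seed and parameters give byte-identical slides", {
  a <- generate_slide(256, 256, 1, seed = 7, patch_size = 128)
  b <- generate_slide(256, 256, 1, seed = 7, patch_size = 128)
  expect_identical(a$image, b$image)
  expect_identical(a$tumor_polygons, b$tumor_polygons)
  c <- generate_slide(256, 256, 1, seed = 8, patch_size = 128)
  expect_false(identical(a$image, c$image))
})

test_that("canvas smaller than one patch is rejected", {
  expect_error(generate_slide(100, 4096, 0, seed = 1),
               "smaller than one patch")
  expect_error(generate_slide(4096, 100, 0, seed = 1),
               "smaller than one patch")
})

test_that("texture parameter invariants are enforced", {
  expect_error(texture_params(-1, c(3, 6), c(0, 0, 0), c(1, 1, 1)))
  expect_error(texture_params(1, c(6, 3), c(0, 0, 0), c(1, 1, 1)))
  expect_error(texture_params(1, c(3, 6), c(0, 0, 300), c(1, 1, 1)))
  expect_s3_class(tumor_texture_params(), "texture_params")
})

test_that("mask pixels and the slide label agree", {
  for (s in 1:3) {
    sl <- generate_slide(256, 256, if (s == 2) 0L else 1L, seed = s,
                         patch_size = 128)
    has_tumor_pixels <- sum(rasterize_mask(sl)) > 0
    expect_identical(has_tumor_pixels, sl$slide_label == "cancerous")
  }
})

test_that("rasterize_mask handles trivial windows", {
  sl <- generate_slide(256, 256, 1, seed = 3, patch_size = 128,
                       region_radius_range = c(50, 70))
  # window far from any polygon: polygons live in the disc around the
  # centre, so a corner window of 10 px is safely outside
  poly <- sl$tumor_polygons[[1]]
  far <- c(0, 0, 8, 8)
  if (min(poly[, 1]) > 10 && min(poly[, 2]) > 10) {
    expect_true(all(rasterize_mask(sl, far) == 0))
  }
  expect_error(rasterize_mask(sl, c(250, 0, 10, 10)), "outside")

  # solid axis-aligned square: interior of its bounding box is all ones
  sq <- list(cbind(c(2, 12, 12, 2), c(2, 2, 12, 12)))
  m <- rasterize_mask(sq, window = c(2, 2, 10, 10))
  expect_true(all(m == 1))
})

test_that("triangle mask equals a brute-force point-in-polygon count", {
  tri <- list(cbind(c(0, 10, 0), c(0, 0, 10)))
  m <- rasterize_mask(tri, window = c(0, 0, 10, 10))
  # brute force: even-odd ray cast for every pixel centre
  brute <- 0L
  for (iy in 0:9) {
    for (ix in 0:9) {
      px <- ix + 0.5; py <- iy + 0.5
      verts <- tri[[1]]
      n <- nrow(verts); cross <- 0L
      for (e in seq_len(n)) {
        x1 <- verts[e, 1]; y1 <- verts[e, 2]
        x2 <- verts[e %% n + 1, 1]; y2 <- verts[e %% n + 1, 2]
        if ((y1 > py) != (y2 > py)) {
          xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
          if (xint > px) cross <- cross + 1L
        }
      }
      brute <- brute + cross %% 2L
    }
  }
  expect_identical(sum(m), brute)
  # the triangle x + y < 10 contains the centres with ix + iy <= 8
  expect_identical(sum(m), sum(outer(0:9 + 0.5, 0:9 + 0.5, "+") < 10))
})

test_that("tumor and normal textures are separable by patch mean intensity", {
  set.seed(99)
  n <- 100L
  tp <- tumor_texture_params()
  np <- normal_texture_params()
  tumor_means <- numeric(n)
  normal_means <- numeric(n)
  half <- n / 2L
  tum <- generate_slide(640, 640, 1, seed = 101, patch_size = 64,
                        region_radius_range = c(300, 310),
                        tumor_params = tp, normal_params = np)
  nor <- generate_slide(640, 640, 0, seed = 102, patch_size = 64,
                        normal_params = np)
  mask <- rasterize_mask(tum)
  k <- 0L; tries <- 0L
  while (k < half && tries < 2000L) {
    tries <- tries + 1L
    x <- sample(0:(640 - 64), 1); y <- sample(0:(640 - 64), 1)
    if (all(mask[(y + 1):(y + 64), (x + 1):(x + 64)] == 1)) {
      k <- k + 1L
      tumor_means[k] <- mean(tum$image[(y + 1):(y + 64), (x + 1):(x + 64), ])
    }
  }
  expect_gte(k, half)
  for (k in seq_len(half)) {
    x <- sample(0:(640 - 64), 1); y <- sample(0:(640 - 64), 1)
    normal_means[k] <- mean(nor$image[(y + 1):(y + 64), (x + 1):(x + 64), ])
  }
  tm <- tumor_means[seq_len(half)]; nm <- normal_means[seq_len(half)]
  pooled_sd <- sqrt((var(tm) + var(nm)) / 2)
  expect_gte(abs(mean(tm) - mean(nm)) / pooled_sd, 3)
})

test_that("annotations survive a GeoJSON round trip", {
  sl <- generate_slide(256, 256, 2, seed = 5, patch_size = 128,
                       region_radius_range = c(30, 40))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotation_geojson(sl$tumor_polygons, path, slide_id = sl$slide_id)
  back <- read_annotation_geojson(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(unname(back[[i]]), unname(sl$tumor_polygons[[i]]),
                 tolerance = 1e-12)
  }
})

test_that("slide images survive a PNG round trip", {
  sl <- generate_slide(128, 128, 0, seed = 9, patch_size = 128)
  path <- withr::local_tempfile(fileext = ".png")
  write_slide(sl, path)
  img <- png::readPNG(path) * 255
  expect_equal(round(img[, , 1]), sl$image[, , 1])
})

test_that("slide manifests carry ids, labels and seeds", {
  sls <- small_slides()
  mf <- slide_manifest(sls)
  expect_identical(nrow(mf), 4L)
  expect_identical(mf$label, c("cancerous", "normal", "cancerous", "normal"))
  expect_identical(mf$seed, 1:4)
})
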