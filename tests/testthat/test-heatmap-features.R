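# The 36 heatmap features: band scheme, worked examples, linkage
# identities, and the brute-force band-count oracle.

test_that("band boundaries follow the half-open scheme", {
  expect_identical(band_of(0.9995), 1L)
  expect_identical(band_of(0.999), 2L)    # boundary belongs to the lower band
  expect_identical(band_of(1), 1L)
  expect_identical(band_of(0.95), 4L)
  expect_identical(band_of(0.6), 8L)
  expect_identical(band_of(0.5), NA_integer_)
  expect_identical(band_of(0.2), NA_integer_)
  expect_error(band_of(1.2), "\\[0, 1\\]")
  expect_error(band_of(-0.1), "\\[0, 1\\]")
})

test_that("feature names are 36, stable and ordered", {
  nms <- heatmap_feature_names()
  expect_length(nms, 36)
  expect_identical(nms[1], "normal_mean")
  expect_identical(nms[10], "tumor_mean")
  expect_identical(nms[19], "np_normal_p_gt_0.999")
  expect_identical(nms[20], "np_tumor_p_gt_0.999")
  expect_identical(nms[33], "np_normal_0.5_lt_p_le_0.6")
  expect_identical(nms[35], "argmax_mean_label")
  expect_identical(nms[36], "argmax_count_label")
})

test_that("a degenerate all-tumor heatmap gives the closed-form features", {
  hm <- heatmap_from_values(rep(1, 6), rows = 2, cols = 3)
  ft <- extract_features(hm)
  expect_identical(ncol(ft) - 2L, 36L)
  expect_equal(ft$tumor_mean, 1)
  expect_equal(ft$tumor_variance, 0)
  expect_equal(ft$tumor_sum, 6)
  expect_equal(ft$np_tumor_p_gt_0.999, 6)
  band_cols <- grep("^np_tumor", names(ft), value = TRUE)
  expect_equal(sum(ft[, band_cols]), 6)   # all mass in the top band
  expect_equal(ft$argmax_mean_label, 1)
  expect_equal(ft$argmax_count_label, 1)
})

test_that("the 2x2 worked example matches the hand computation", {
  hm <- heatmap_from_values(c(0.1, 0.4, 0.6, 0.95), rows = 2, cols = 2)
  ft <- extract_features(hm)
  expect_equal(ft$tumor_mean, 0.5125)
  expect_equal(ft$tumor_min, 0.1)
  expect_equal(ft$tumor_max, 0.95)
  expect_equal(ft$tumor_range, 0.85)
  expect_equal(ft$tumor_sum, 2.05)
  expect_equal(ft$tumor_median, 0.5)
  expect_equal(ft$`np_tumor_0.9_lt_p_le_0.95`, 1)
  expect_equal(ft$`np_tumor_0.5_lt_p_le_0.6`, 1)
  expect_equal(sum(ft[, grep("^np_tumor", names(ft))]), 2)
  # normal probabilities are 0.9, 0.6, 0.4, 0.05
  expect_equal(ft$`np_normal_0.8_lt_p_le_0.9`, 1)
  expect_equal(ft$`np_normal_0.5_lt_p_le_0.6`, 1)
  expect_equal(sum(ft[, grep("^np_normal", names(ft))]), 2)
  # per-cell argmax is tied 2 vs 2: the tie goes to tumor
  expect_equal(ft$argmax_count_label, 1)
  # mean p_tumor 0.5125 > mean p_normal
  expect_equal(ft$argmax_mean_label, 1)
})

test_that("normal and tumor statistics are linked by p_n = 1 - p_t", {
  for (s in 1:10) {
    hm <- random_heatmap(4, 5, seed = 100 + s)
    ft <- extract_features(hm)
    expect_equal(ft$normal_mean, 1 - ft$tumor_mean, tolerance = 1e-12)
    expect_equal(ft$normal_variance, ft$tumor_variance, tolerance = 1e-12)
    expect_equal(ft$normal_std, ft$tumor_std, tolerance = 1e-12)
    expect_equal(ft$normal_range, ft$tumor_range, tolerance = 1e-12)
    expect_equal(ft$normal_sum, ft$n_cells - ft$tumor_sum, tolerance = 1e-12)
    expect_equal(ft$normal_min, 1 - ft$tumor_max, tolerance = 1e-12)
    expect_equal(ft$normal_variance, ft$normal_std^2, tolerance = 1e-12)
  }
})

test_that("band counts equal a brute-force double loop on 100 heatmaps", {
  lower <- c(0.999, 0.99, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5)
  upper <- c(1, lower[-8])
  for (s in 1:100) {
    hm <- random_heatmap(3, 4, seed = 2000 + s)
    ft <- extract_features(hm)
    for (cls in c("normal", "tumor")) {
      p <- as.numeric(if (cls == "normal") hm$p_normal else hm$p_tumor)
      for (b in 1:8) {
        brute <- 0L
        for (v in p) if (v > lower[b] && v <= upper[b]) brute <- brute + 1L
        got <- ft[[paste0("np_", cls, "_",
                          slideheat:::band_labels()[b])]]
        expect_identical(as.integer(got), brute)
      }
    }
  }
})

test_that("each counted cell lands in at most one (class, band) pair", {
  for (s in 1:5) {
    hm <- random_heatmap(4, 4, seed = 300 + s)
    ft <- extract_features(hm)
    total_banded <- sum(ft[, grep("^np_", names(ft))])
    expect_lte(total_banded, ft$n_cells)
    # a cell misses both bands only when both probabilities equal 0.5
    n_unbanded <- sum(as.numeric(hm$p_tumor) == 0.5)
    expect_identical(as.integer(total_banded),
                     as.integer(ft$n_cells - n_unbanded))
  }
})

test_that("features are invariant to cell permutation", {
  vals <- c(0.12, 0.55, 0.87, 0.33, 0.91, 0.08)
  f1 <- extract_features(heatmap_from_values(vals, 2, 3))
  f2 <- extract_features(heatmap_from_values(sample(vals), 2, 3))
  expect_equal(f1[, heatmap_feature_names()], f2[, heatmap_feature_names()])
})

test_that("the mode uses 2-decimal rounding with ties to the smallest", {
  vals <- c(0.123, 0.118, 0.87, 0.873, 0.5, 0.2)  # 0.12 x2 and 0.87 x2
  ft <- extract_features(heatmap_from_values(vals, 2, 3))
  expect_equal(ft$tumor_mode, 0.12)
})

test_that("background cells are excluded unless requested", {
  preds <- tibble::tibble(slide_id = "s", x = c(0L, 64L), y = c(0L, 0L),
                          p_tumor = c(0.9, 0.1), p_normal = c(0.1, 0.9))
  hm <- assemble_heatmap(preds, 128, 64, patch_size = 64,
                         background = c(FALSE, TRUE))
  ft <- extract_features(hm)
  expect_identical(ft$n_cells, 1L)
  expect_equal(ft$tumor_mean, 0.9)
  ft_all <- extract_features(hm, include_background = TRUE)
  expect_identical(ft_all$n_cells, 2L)
  expect_equal(ft_all$tumor_mean, 0.5)
  # all cells background: explicit failure
  hm2 <- assemble_heatmap(preds, 128, 64, patch_size = 64,
                          background = c(TRUE, TRUE))
  expect_error(extract_features(hm2), "zero counted cells")
})
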