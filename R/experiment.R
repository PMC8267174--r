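# End-to-end experiment on synthetic slides: generate an annotated cohort,
# train the patch classifier, assemble heatmaps, extract the 36 features,
# train the slide-level booster, train the U-Net, and score everything on
# held-out slides. This is the driver used by the package's own
# experiments; all randomness descends from one integer seed.
#
# Slides are processed one at a time and reduced immediately (classifier
# patches are mean-pooled to the network input, segmentation tiles to
# quarter resolution), so the full-resolution canvas never has to be held
# for more than one slide.

#' Run the full two-stage pipeline on a synthetic cohort
#'
#' Generates `n_slides` slides (half normal, half cancerous, alternating),
#' splits them half/half into training and held-out testing slides, then:
#' trains the patch classifier on a balanced augmented manifest, assembles
#' per-slide probability heatmaps, trains the gradient-boosted slide
#' classifier on the 36 heatmap features, trains the U-Net on
#' half-overlap tiles from tumor-boundary patches, and evaluates patch
#' accuracy, slide-level accuracy/ROC, and stitched segmentation dice on
#' a held-out cancerous slide.
#'
#' With `crossfit = TRUE` (default) the training slides are split again:
#' the patch classifier learns on one half and the booster's training
#' features come from the other half, so the slide model never sees
#' heatmaps of slides the patch model was fitted on. `crossfit = FALSE`
#' reuses all training slides for both stages (the scheme that trains the
#' slide model on the same slides as the patch model).
#'
#' @param seed Master integer seed.
#' @param n_slides Cohort size (even; half per class).
#' @param slide_px Slide side in pixels (default 4,096: a 4 x 4 patch
#'   grid).
#' @param patch_size Patch side (default 1,024).
#' @param n_tumor_regions Tumor polygons per cancerous slide.
#' @param patch_epochs,unet_epochs Training epochs for the two networks.
#' @param n_seg_train_tiles,n_seg_val_tiles Segmentation tile budget.
#' @param crossfit Keep the booster's training heatmaps disjoint from the
#'   patch model's training slides.
#' @param verbose Print stage progress.
#' @return A `synthetic_experiment` list: `patch_val_accuracy`,
#'   `patch_test_accuracy`, `patch_auc`, `slide_accuracy_pct`,
#'   `slide_confusion`, `stitched_dice`, the fitted models, per-slide
#'   feature/prediction tables and the manifest counts.
#' @export
run_synthetic_experiment <- function(seed = 1L, n_slides = 24L,
                                     slide_px = 4096L, patch_size = 1024L,
                                     n_tumor_regions = 2L,
                                     patch_epochs = 5L, unet_epochs = 10L,
                                     n_seg_train_tiles = 120L,
                                     n_seg_val_tiles = 24L,
                                     crossfit = TRUE, verbose = TRUE) {
  stopifnot(n_slides %% 2L == 0L, n_slides >= 8L)
  if (crossfit && n_slides < 16L) {
    stop("cross-fitting needs at least 16 slides (2 per class in each ",
         "half of the training slides); use crossfit = FALSE or a larger ",
         "cohort", call. = FALSE)
  }
  say <- function(...) if (verbose) message(...)
  n_grid <- slide_px %/% patch_size
  q <- 4L                                   # seg tiles at quarter resolution
  seg_tile_px <- 256L %/% q
  cancerous <- rep(c(TRUE, FALSE), n_slides / 2L)
  # stratified half/half slide split, fixed before any pixels are drawn
  split_of <- ifelse(seq_len(n_slides) <= n_slides / 2L,
                     "training", "testing")
  set.seed(seed)
  model_half <- rep(TRUE, n_slides)
  if (crossfit) {
    tr_idx <- which(split_of == "training")
    for (lab in c(TRUE, FALSE)) {
      grp <- tr_idx[cancerous[tr_idx] == lab]
      model_half[grp] <- seq_along(grp) <= length(grp) / 2
    }
  }

  patch_tbls <- vector("list", n_slides)
  train_pool <- vector("list", n_slides)
  slide_labels <- ifelse(cancerous, "cancerous", "normal")
  seg_pool <- list()
  eval_seg <- NULL
  eval_slide_idx <- which(split_of == "testing" & cancerous)[1L]

  for (i in seq_len(n_slides)) {
    sid <- sprintf("slide_%03d", i)
    sl <- generate_slide(slide_px, slide_px,
                         if (cancerous[i]) n_tumor_regions else 0L,
                         seed = seed * 1000L + i, patch_size = patch_size,
                         slide_id = sid)
    pt <- tile_slide(sl, patch_size = patch_size, downscale_to = 32L)
    pt$split_slide <- split_of[i]
    patch_tbls[[i]] <- pt
    if (split_of[i] == "training" && model_half[i]) {
      # denser (half-stride) sampling feeds the classifier's manifest;
      # heatmap inference keeps the non-overlapping grid above
      train_pool[[i]] <- tile_slide(sl, patch_size = patch_size,
                                    stride = patch_size %/% 2L,
                                    downscale_to = 32L)
    }
    if (split_of[i] == "training" && cancerous[i]) {
      # boundary-rich patches feed the segmentation training pool
      cand <- which(pt$tumor_fraction > 0.1 & pt$tumor_fraction < 0.95)
      if (length(cand) > 2L) cand <- sample(cand, 2L)
      for (k in cand) {
        img <- downscale_mean(sl$image[(pt$y[k] + 1L):(pt$y[k] + patch_size),
                                       (pt$x[k] + 1L):(pt$x[k] + patch_size),
                                       , drop = FALSE], q)
        msk <- (downscale_mean(rasterize_mask(
          sl, c(pt$x[k], pt$y[k], patch_size, patch_size)), q) >= 0.5) * 1L
        seg_pool[[length(seg_pool) + 1L]] <-
          subsample_half_overlap(img, mask = msk, tile_size = seg_tile_px)
      }
    }
    if (!is.na(eval_slide_idx) && i == eval_slide_idx) {
      imgs <- lapply(seq_len(nrow(pt)), function(k) {
        downscale_mean(sl$image[(pt$y[k] + 1L):(pt$y[k] + patch_size),
                                (pt$x[k] + 1L):(pt$x[k] + patch_size),
                                , drop = FALSE], q)
      })
      eval_seg <- list(patches = pt[, c("x", "y")], images = imgs,
                       mask = (downscale_mean(rasterize_mask(sl), q) >= 0.5) * 1L,
                       slide_id = sid)
    }
    rm(sl)
    say(sid, " generated (", slide_labels[i], ", ", split_of[i], ")")
  }
  gc(verbose = FALSE)

  # ---- patch-level classifier ----
  pool <- dplyr::bind_rows(train_pool[!vapply(train_pool, is.null,
                                              logical(1))])
  manifest <- build_balanced_manifest(pool, target = NULL, seed = seed)
  say("manifest: ", paste(utils::capture.output(
    as.data.frame(manifest_counts(manifest))), collapse = " | "))
  pm <- build_classifier(patch_config("small_cnn", seed = seed))
  pm <- train_patch_classifier(pm, manifest, epochs = patch_epochs)
  say("patch model: best epoch ", pm$best_epoch, ", val accuracy ",
      round(pm$val_accuracy, 4))
  test_rows <- manifest[manifest$split == "testing", ]
  tp <- predict_patches(pm, test_rows)
  patch_test_acc <- mean(ifelse(tp$p_tumor >= 0.5, "carcinoma", "normal") ==
                           test_rows$label)
  patch_auc <- roc_auc(tp$p_tumor,
                       as.integer(test_rows$label == "carcinoma"))$auc

  # ---- heatmaps and features for every slide ----
  feats <- dplyr::bind_rows(lapply(seq_len(n_slides), function(i) {
    pt <- patch_tbls[[i]]
    hm <- assemble_heatmap(predict_patches(pm, pt), slide_px, slide_px,
                           patch_size = patch_size,
                           background = pt$background_flag,
                           slide_id = pt$slide_id[1])
    extract_features(hm)
  }))
  feats$label <- slide_labels
  feats$split <- split_of
  booster_rows <- if (crossfit) split_of == "training" & !model_half else
    split_of == "training"
  sm <- train_slide_classifier(feats[booster_rows, ], seed = seed)
  sp <- predict_slide(sm, feats[split_of == "testing", ])
  sp$true_label <- slide_labels[split_of == "testing"]
  cm <- confusion(sp$true_label, sp$predicted_label)
  slide_acc <- slide_accuracy(nrow(sp), cm$fp + cm$fn)
  say("slide model: ", round(slide_acc, 2), "% on ", nrow(sp),
      " held-out slides")

  # ---- segmentation ----
  seg <- dplyr::bind_rows(seg_pool)
  set.seed(seed + 7L)
  take <- sample.int(nrow(seg),
                     min(nrow(seg), n_seg_train_tiles + n_seg_val_tiles))
  seg <- seg[take, ]
  seg$split <- rep(c("training", "validation"),
                   c(min(n_seg_train_tiles, nrow(seg)),
                     max(0L, nrow(seg) - n_seg_train_tiles)))
  # quarter-resolution tiles are dominated by the tissue color contrast,
  # so a one-level U-Net converges reliably within the step budget
  um <- train_unet(seg, segmentation_config(
    depth = 1L, base_filters = 8L, input_size = seg_tile_px,
    epochs = unet_epochs, batch_size = 2L, learning_rate = 0.03,
    seed = seed))
  say("u-net: best epoch ", um$best_epoch, ", val dice ",
      round(um$val_dice, 4))

  # ---- stitched slide segmentation on the held-out cancerous slide ----
  stitched_dice <- NA_real_
  if (!is.null(eval_seg)) {
    qsz <- patch_size %/% q
    maps <- list(); offs <- list()
    for (k in seq_along(eval_seg$images)) {
      tl <- subsample_half_overlap(eval_seg$images[[k]],
                                   tile_size = seg_tile_px)
      pmaps <- predict_tiles(um, tl)
      maps[[k]] <- stitch(pmaps, tl[, c("offset_x", "offset_y")],
                          width = qsz, height = qsz)
      offs[[k]] <- c(eval_seg$patches$x[k] %/% q,
                     eval_seg$patches$y[k] %/% q)
    }
    om <- do.call(rbind, offs)
    slide_map <- stitch(maps, om, width = slide_px %/% q,
                        height = slide_px %/% q)
    stitched_dice <- dice_coefficient((slide_map >= 0.5) * 1,
                                      eval_seg$mask, epsilon = 0)
    say("stitched dice on ", eval_seg$slide_id, ": ",
        round(stitched_dice, 4))
  }

  structure(list(
    patch_val_accuracy = pm$val_accuracy,
    patch_test_accuracy = patch_test_acc,
    patch_auc = patch_auc,
    slide_accuracy_pct = slide_acc,
    slide_confusion = cm,
    stitched_dice = stitched_dice,
    patch_model = pm, slide_model = sm, unet = um,
    features = feats, slide_predictions = sp,
    manifest_counts = manifest_counts(manifest),
    n_slides = n_slides, seed = as.integer(seed),
    crossfit = crossfit),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", x$n_slides, " slides, seed ", x$seed,
      if (x$crossfit) ", cross-fitted" else "", "\n",
      "  patch val accuracy:  ", round(x$patch_val_accuracy, 4), "\n",
      "  patch test accuracy: ", round(x$patch_test_accuracy, 4),
      " (AUC ", round(x$patch_auc, 4), ")\n",
      "  slide accuracy:      ", round(x$slide_accuracy_pct, 2), "%\n",
      "  stitched dice:       ", round(x$stitched_dice, 4), "\n", sep = "")
  invisible(x)
}

#' @method glance synthetic_experiment
#' @export
glance.synthetic_experiment <- function(x, ...) {
  tibble::tibble(patch_val_accuracy = x$patch_val_accuracy,
                 patch_test_accuracy = x$patch_test_accuracy,
                 patch_auc = x$patch_auc,
                 slide_accuracy_pct = x$slide_accuracy_pct,
                 stitched_dice = x$stitched_dice,
                 n_slides = x$n_slides, seed = x$seed,
                 crossfit = x$crossfit)
}
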