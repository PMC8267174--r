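# Tiling: cut slides into labelled square patches, subsample 256-pixel
# half-overlap tiles for segmentation, and build class-balanced,
# leakage-free train/validation/test manifests via flip/rotation
# augmentation. All coordinates are 0-based, y-down, with half-open
# pixel windows [x, x + size).

#' Cut a slide into square patches
#'
#' Patches are enumerated row-major on a regular grid. With
#' `edge_policy = "drop"` only fully inside windows are kept, giving
#' `floor((W - patch)/stride + 1) * floor((H - patch)/stride + 1)` patches;
#' with `"pad"` edge windows are completed by mirror padding.
#'
#' When the slide carries tumor polygons, each patch is labelled
#' `"carcinoma"` if at least half its pixels fall inside a tumor region,
#' `"normal"` if none do, and `"unlabeled"` otherwise. Patches whose pixels
#' are more than 80% near-white (all channels > 220) are flagged
#' `background_flag = TRUE`; they are kept so the heatmap grid stays
#' complete, but balanced manifests exclude them.
#'
#' @param slide A `synthetic_slide`, or an RGB array (H x W x 3, 0..255).
#' @param patch_size Patch side in pixels (default 1,024).
#' @param stride Grid stride in pixels (default `patch_size`,
#'   i.e. non-overlapping).
#' @param edge_policy `"drop"` or `"pad"`.
#' @param annotate Compute labels from the slide's polygons (default TRUE
#'   for synthetic slides).
#' @param keep_images Store pixel data in the `image` list-column.
#' @param downscale_to Optional side length; stored images are mean-pooled
#'   to this size (coordinates still refer to the full-resolution slide).
#' @return Tibble with columns `slide_id`, `patch_id`, `x`, `y`, `size`,
#'   `label`, `tumor_fraction`, `background_flag`, `augmentation_tag`,
#'   and (if kept) `image`.
#' @examples
#' sl <- generate_slide(256, 256, 0, seed = 1, patch_size = 128)
#' nrow(tile_slide(sl, patch_size = 128))
#' @export
tile_slide <- function(slide, patch_size = 1024L, stride = patch_size,
                       edge_policy = c("drop", "pad"),
                       annotate = inherits(slide, "synthetic_slide"),
                       keep_images = TRUE, downscale_to = NULL) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(patch_size >= 1L, stride >= 1L)
  if (inherits(slide, "synthetic_slide")) {
    img <- slide$image
    slide_id <- slide$slide_id
  } else {
    img <- slide
    slide_id <- "slide"
    annotate <- FALSE
  }
  H <- dim(img)[1]; W <- dim(img)[2]
  if (edge_policy == "drop") {
    nx <- floor((W - patch_size) / stride) + 1
    ny <- floor((H - patch_size) / stride) + 1
    if (nx < 1 || ny < 1) {
      return(empty_patch_tbl(keep_images))
    }
    xs <- (seq_len(nx) - 1L) * stride
    ys <- (seq_len(ny) - 1L) * stride
  } else {
    xs <- seq(0L, max(W - 1L, 0L), by = stride)
    xs <- xs[xs < W]
    ys <- seq(0L, max(H - 1L, 0L), by = stride)
    ys <- ys[ys < H]
  }
  grid <- expand.grid(x = xs, y = ys)[, c("x", "y")]   # row-major: x fastest
  grid <- grid[order(grid$y, grid$x), ]
  full_mask <- if (annotate) rasterize_mask(slide) else NULL

  crop_one <- function(x, y) {
    x1 <- x + 1L; y1 <- y + 1L
    x2 <- min(x + patch_size, W); y2 <- min(y + patch_size, H)
    p <- img[y1:y2, x1:x2, , drop = FALSE]
    if (x2 - x < patch_size || y2 - y < patch_size) {
      p <- pad_reflect(p, bottom = patch_size - (y2 - y),
                       right = patch_size - (x2 - x))
    }
    p
  }
  n <- nrow(grid)
  images <- vector("list", n)
  tumor_frac <- numeric(n)
  bg_flag <- logical(n)
  for (k in seq_len(n)) {
    p <- crop_one(grid$x[k], grid$y[k])
    bg_flag[k] <- mean(p[, , 1] > 220 & p[, , 2] > 220 & p[, , 3] > 220) > 0.8
    if (annotate) {
      y2 <- min(grid$y[k] + patch_size, H); x2 <- min(grid$x[k] + patch_size, W)
      m <- full_mask[(grid$y[k] + 1L):y2, (grid$x[k] + 1L):x2, drop = FALSE]
      tumor_frac[k] <- mean(m)
    }
    if (keep_images) {
      if (!is.null(downscale_to) && downscale_to != patch_size) {
        p <- if (patch_size %% downscale_to == 0L) {
          downscale_mean(p, patch_size %/% downscale_to)
        } else {
          resize_bilinear(p, downscale_to, downscale_to)
        }
      }
      images[[k]] <- p
    }
  }
  label <- if (annotate) {
    ifelse(tumor_frac >= 0.5, "carcinoma",
           ifelse(tumor_frac == 0, "normal", "unlabeled"))
  } else {
    rep("unlabeled", n)
  }
  out <- tibble::tibble(
    slide_id = slide_id,
    patch_id = sprintf("%s_x%d_y%d", slide_id, grid$x, grid$y),
    x = as.integer(grid$x), y = as.integer(grid$y),
    size = as.integer(patch_size),
    label = label,
    tumor_fraction = if (annotate) tumor_frac else NA_real_,
    background_flag = bg_flag,
    augmentation_tag = "identity"
  )
  if (keep_images) out$image <- images
  out
}

empty_patch_tbl <- function(keep_images) {
  out <- tibble::tibble(
    slide_id = character(), patch_id = character(),
    x = integer(), y = integer(), size = integer(),
    label = character(), tumor_fraction = numeric(),
    background_flag = logical(), augmentation_tag = character()
  )
  if (keep_images) out$image <- list()
  out
}

#' Subsample a patch into half-overlapping 256-pixel tiles
#'
#' Tiles of side `tile_size` are taken at offsets `0, tile_size/2, ...`
#' along each axis, one offset per `tile_size/2` of patch side, so a
#' 1,024-pixel patch yields an 8 x 8 grid of 64 tiles. Tiles at the last
#' offset overhang the patch edge by `tile_size/2` and are completed by
#' mirror padding. A mask aligned to the patch is cut with identical
#' geometry.
#'
#' @param patch Square RGB array (side divisible by `tile_size/2`), or a
#'   one-row patch tibble from [tile_slide()].
#' @param mask Optional matrix aligned to the patch.
#' @param tile_size Tile side in pixels (default 256).
#' @return Tibble with columns `offset_x`, `offset_y`, `tile` and (when a
#'   mask is given) `mask_tile`.
#' @examples
#' p <- array(0, c(256, 256, 3))
#' nrow(subsample_half_overlap(p))   # 4
#' @export
subsample_half_overlap <- function(patch, mask = NULL, tile_size = 256L) {
  if (is.data.frame(patch)) {
    stopifnot(nrow(patch) == 1L, !is.null(patch$image))
    patch <- patch$image[[1L]]
  }
  d <- dim(patch)
  half <- tile_size %/% 2L
  if (d[1] != d[2] || d[1] %% half != 0L) {
    stop("patch must be square with side divisible by ", half,
         "; got ", d[1], "x", d[2], call. = FALSE)
  }
  side <- d[1]
  offsets <- seq(0L, side - half, by = half)
  padded <- pad_reflect(patch, bottom = half, right = half)
  padded_mask <- if (!is.null(mask)) {
    stopifnot(all(dim(mask)[1:2] == d[1:2]))
    pad_reflect(mask, bottom = half, right = half)
  }
  grid <- expand.grid(offset_x = offsets, offset_y = offsets)
  grid <- grid[order(grid$offset_y, grid$offset_x), ]
  tiles <- vector("list", nrow(grid))
  mtiles <- if (!is.null(mask)) vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    i <- grid$offset_y[k] + 1L; j <- grid$offset_x[k] + 1L
    tiles[[k]] <- padded[i:(i + tile_size - 1L), j:(j + tile_size - 1L), ,
                         drop = FALSE]
    if (!is.null(mask)) {
      mtiles[[k]] <- padded_mask[i:(i + tile_size - 1L),
                                 j:(j + tile_size - 1L)]
    }
  }
  out <- tibble::tibble(offset_x = as.integer(grid$offset_x),
                        offset_y = as.integer(grid$offset_y),
                        tile = tiles)
  if (!is.null(mask)) out$mask_tile <- mtiles
  out
}

# exact array transforms used for augmentation
rotate_image <- function(img, times) {
  # 90-degree clockwise rotations, `times` in 1:3; square images only
  for (t in seq_len(times)) {
    d <- dim(img)
    img <- if (length(d) == 3L) {
      aperm(img, c(2L, 1L, 3L))[, d[1]:1, , drop = FALSE]
    } else {
      t(img)[, d[1]:1, drop = FALSE]
    }
  }
  img
}

flip_image <- function(img, axis = c("h", "v")) {
  axis <- match.arg(axis)
  d <- dim(img)
  if (axis == "h") {
    if (length(d) == 3L) img[, d[2]:1, , drop = FALSE] else img[, d[2]:1, drop = FALSE]
  } else {
    if (length(d) == 3L) img[d[1]:1, , , drop = FALSE] else img[d[1]:1, , drop = FALSE]
  }
}

apply_augmentation <- function(img, tag) {
  switch(tag,
    identity = img,
    rot90 = rotate_image(img, 1L),
    rot180 = rotate_image(img, 2L),
    rot270 = rotate_image(img, 3L),
    fliph = flip_image(img, "h"),
    flipv = flip_image(img, "v"),
    stop("unknown augmentation: ", tag, call. = FALSE)
  )
}

#' Augment patches by rotation and flipping
#'
#' Returns one new record per requested operation; labels, coordinates and
#' split assignments are inherited from the parent patch, and
#' `augmentation_tag` records the transform.
#'
#' @param patches Patch tibble from [tile_slide()] (images required).
#' @param ops Subset of `c("rot90", "rot180", "rot270", "fliph", "flipv")`.
#' @return Tibble of augmented records (parents not included).
#' @export
augment <- function(patches,
                    ops = c("rot90", "rot180", "rot270", "fliph", "flipv")) {
  ops <- match.arg(ops, several.ok = TRUE)
  stopifnot(!is.null(patches$image))
  out <- lapply(ops, function(op) {
    aug <- patches
    aug$image <- lapply(patches$image, apply_augmentation, tag = op)
    aug$augmentation_tag <- op
    aug$patch_id <- paste0(patches$patch_id, "_", op)
    aug
  })
  dplyr::bind_rows(out)
}

#' Build a class-balanced split manifest
#'
#' Parent patches (background-flagged and unlabeled patches excluded) are
#' assigned to training/validation/testing splits first; augmentation then
#' tops each class up to the per-split targets, so no augmented descendant can
#' leak into a different split than its parent.
#'
#' @param patches Patch tibble from [tile_slide()] (possibly several slides
#'   bound together), identity records only.
#' @param target Named numeric vector of per-class patch counts per split,
#'   e.g. `c(training = 400, validation = 50, testing = 50)`. `NULL` picks
#'   the largest 8:1:1 target achievable with all six augmentation
#'   variants.
#' @param seed Integer seed for split assignment and augmentation choice.
#' @param by_slide Assign whole slides (rather than patches) to splits,
#'   preventing slide-level leakage. Default FALSE (patch-level, the
#'   parent-patch contract).
#' @return A `split_manifest` tibble: the patch columns plus `split` and
#'   `parent_id`.
#' @export
build_balanced_manifest <- function(patches, target = NULL, seed = 1L,
                                    by_slide = FALSE) {
  pool <- dplyr::filter(patches, !.data$background_flag,
                        .data$label %in% c("normal", "carcinoma"),
                        .data$augmentation_tag == "identity")
  if (nrow(pool) == 0L) stop("no labelled foreground patches", call. = FALSE)
  classes <- sort(unique(pool$label))
  splits <- c("training", "validation", "testing")
  n_min <- min(table(pool$label))
  if (is.null(target)) {
    # largest balanced target with full augmentation: ~8:1:1 at scale,
    # with at least one parent per split
    n_va <- max(1L, round(0.1 * n_min))
    n_tr <- n_min - 2L * n_va
    if (n_tr < 1L) {
      stop("too few parent patches (", n_min,
           " in the rarer class) to form three splits", call. = FALSE)
    }
    target <- 6L * c(training = n_tr, validation = n_va, testing = n_va)
  }
  stopifnot(all(names(target) %in% splits), all(target >= 0))
  target <- target[splits[splits %in% names(target)]]

  set.seed(seed)
  assign_split <- function(df, cl = "") {
    # every split must keep capacity (6 variants per parent) >= target;
    # leftover parents are spread proportionally to the targets
    n <- nrow(df)
    min_c <- ceiling(target / 6)
    if (sum(min_c) > n) {
      stop("targets ", paste(target, collapse = "/"),
           " unachievable for class '", cl, "': need at least ",
           sum(min_c), " parents, have ", n, " (deficit ",
           sum(min_c) - n, " parents)", call. = FALSE)
    }
    extra <- n - sum(min_c)
    add <- floor(target / sum(target) * extra)
    rem <- extra - sum(add)
    if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
    counts <- min_c + add
    df$split <- sample(rep(names(counts), counts))
    df
  }
  if (by_slide) {
    slides <- unique(pool$slide_id)
    sdf <- assign_split(tibble::tibble(slide_id = sample(slides)))
    pool <- dplyr::left_join(pool, sdf, by = "slide_id")
  } else {
    pool <- pool[sample.int(nrow(pool)), ]
    pool <- dplyr::bind_rows(lapply(
      split(pool, pool$label),
      function(df) assign_split(df, cl = df$label[1])))
  }
  pool$parent_id <- pool$patch_id

  ops_all <- c("rot90", "rot180", "rot270", "fliph", "flipv")
  pieces <- list()
  for (cl in classes) {
    for (sp in names(target)) {
      parents <- dplyr::filter(pool, .data$label == cl, .data$split == sp)
      t_need <- target[[sp]]
      n_par <- nrow(parents)
      if (t_need > 6L * n_par) {
        stop("target of ", t_need, " unachievable for class '", cl,
             "' in split '", sp, "': ", n_par, " parents x 6 variants = ",
             6L * n_par, " (deficit ", t_need - 6L * n_par, ")",
             call. = FALSE)
      }
      if (n_par == 0L) next
      keep_parents <- parents[seq_len(min(n_par, t_need)), , drop = FALSE]
      pieces[[paste(cl, sp)]] <- keep_parents
      extra <- t_need - nrow(keep_parents)
      if (extra > 0L) {
        per <- extra %/% n_par
        rem <- extra %% n_par
        n_ops <- rep(per, n_par) + (seq_len(n_par) <= rem)
        aug_rows <- lapply(seq_len(n_par), function(i) {
          if (n_ops[i] == 0L) return(NULL)
          rec <- parents[i, , drop = FALSE]
          aug(rec, ops_all[seq_len(n_ops[i])])
        })
        pieces[[paste(cl, sp, "aug")]] <- dplyr::bind_rows(aug_rows)
      }
    }
  }
  out <- dplyr::bind_rows(pieces)
  class(out) <- c("split_manifest", class(out))
  out
}

# augment a single record with inherited split/parent bookkeeping
aug <- function(rec, ops) {
  a <- augment(rec, ops)
  a$parent_id <- rec$parent_id
  a$split <- rec$split
  a
}

#' Per-class, per-split counts of a manifest
#'
#' @param manifest A `split_manifest`.
#' @return Tibble of counts, one row per (label, split).
#' @export
manifest_counts <- function(manifest) {
  dplyr::count(tibble::as_tibble(manifest), .data$label, .data$split)
}

#' Re-crop a patch record from its source slide
#'
#' Round-trip helper: extracts the pixels addressed by (`x`, `y`, `size`)
#' and re-applies the record's augmentation.
#'
#' @param record One-row patch tibble.
#' @param slide The source `synthetic_slide`.
#' @return RGB array.
#' @export
recrop_patch <- function(record, slide) {
  stopifnot(nrow(record) == 1L)
  img <- slide$image[(record$y + 1L):(record$y + record$size),
                     (record$x + 1L):(record$x + record$size), , drop = FALSE]
  apply_augmentation(img, record$augmentation_tag)
}
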