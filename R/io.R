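# Persistence: heatmaps as two-plane float TIFF with a JSON sidecar,
# masks as 0/255 PNG, model checkpoints as RDS with a JSON sidecar, patch
# manifests as CSV (+ optional PNG patch images).

#' Write / read a probability heatmap
#'
#' The heatmap is stored as a two-page floating-point TIFF (plane 1 =
#' p_normal, plane 2 = p_tumor) next to a `.json` sidecar carrying the
#' slide id, geometry and background flags.
#'
#' @param heatmap A `probability_heatmap`.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return Invisibly, `path` (write) or the heatmap (read).
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "probability_heatmap"))
  tiff::writeTIFF(list(heatmap$p_normal, heatmap$p_tumor), path,
                  bits.per.sample = 32L)
  sidecar <- list(slide_id = heatmap$slide_id,
                  patch_size = heatmap$patch_size,
                  stride = heatmap$stride,
                  width = heatmap$width, height = heatmap$height,
                  rows = nrow(heatmap$p_tumor), cols = ncol(heatmap$p_tumor),
                  background = as.logical(heatmap$background))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE)

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  bg <- matrix(meta$background, meta$rows, meta$cols)
  structure(list(slide_id = meta$slide_id,
                 p_normal = planes[[1]], p_tumor = planes[[2]],
                 background = bg,
                 patch_size = as.integer(meta$patch_size),
                 stride = as.integer(meta$stride),
                 width = as.integer(meta$width),
                 height = as.integer(meta$height)),
            class = "probability_heatmap")
}

#' Write a binary mask as PNG (0/255 grayscale)
#'
#' @param mask 0/1 matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The model object is serialized as RDS; a JSON sidecar records the
#' configuration, seed and (when trained) best epoch and validation score
#' for quick inspection without loading the checkpoint.
#'
#' @param model A `patch_classifier` or `unet_model`.
#' @param path Output path (typically `.rds`).
#' @return Invisibly, `path` (write) or the model (read).
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(class = class(model)[1],
               config = unclass(model$config),
               trained = model$trained,
               best_epoch = model$best_epoch,
               val_accuracy = model$val_accuracy,
               val_dice = model$val_dice)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Write a patch manifest (and optionally its images) to disk
#'
#' @param manifest Patch tibble, e.g. a `split_manifest`.
#' @param path CSV output path.
#' @param image_dir If given, each patch image is written there as PNG and
#'   the CSV's `path` column points at it.
#' @return Invisibly, `path`.
#' @export
write_patch_manifest <- function(manifest, path, image_dir = NULL) {
  df <- tibble::as_tibble(manifest)
  if (!is.null(image_dir) && !is.null(df$image)) {
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    df$path <- file.path(image_dir, paste0(df$patch_id, ".png"))
    purrr::walk2(df$image, df$path,
                 function(im, p) png::writePNG(im / 255, p))
  } else if (!"path" %in% names(df)) {
    df$path <- NA_character_
  }
  df$image <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
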