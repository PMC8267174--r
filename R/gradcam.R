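# Grad-CAM attention maps for the patch classifier: channel weights are
# the spatially averaged gradients of the target-class score at a chosen
# convolutional layer; the rectified weighted activation sum is upsampled
# bilinearly to the input size and min-max normalized.

#' Grad-CAM attention map
#'
#' Computes the gradient of the target class's pre-softmax score with
#' respect to the post-activation feature maps of a convolutional layer,
#' averages it spatially into per-channel weights, and returns the
#' rectified weighted sum of the activations, bilinearly upsampled to the
#' patch size and min-max normalized to `[0, 1]`. An everywhere-zero raw
#' map stays all zero.
#'
#' @param model A `patch_classifier` (trained or not).
#' @param image RGB patch array (0..255).
#' @param target_class `"tumor"`/`"carcinoma"` or `"normal"` (or index 1/2
#'   in (normal, tumor) order).
#' @param layer Index of the convolutional layer to inspect; default the
#'   backbone's last convolutional layer.
#' @param preprocess Resize/rescale the image to the network input
#'   (disable only when feeding network-ready arrays).
#' @return An `attention_map`: `values` matrix in `[0, 1]` at the image's
#'   resolution, plus `target_class` and `layer` fields.
#' @export
grad_cam <- function(model, image, target_class = "tumor", layer = NULL,
                     preprocess = TRUE) {
  stopifnot(inherits(model, "patch_classifier"))
  n_conv <- length(model$params$conv)
  layer <- layer %||% n_conv
  if (!is.numeric(layer) || layer < 1L || layer > n_conv ||
      layer != round(layer)) {
    stop("layer must index one of the ", n_conv,
         " convolutional layers (got ", deparse(layer), ")", call. = FALSE)
  }
  cls <- target_class_index(target_class)
  out_h <- dim(image)[1]; out_w <- dim(image)[2]
  x <- if (preprocess) preprocess_patch(image, model$config$input_size)
       else image
  fw <- forward_classifier(model, x, cache = TRUE)
  dlogits <- c(0, 0); dlogits[cls] <- 1      # gradient of the class score
  bw <- backward_classifier(model, fw$caches, dlogits, capture_layer = layer)
  act <- fw$caches$conv[[layer]]$act
  dA <- bw$d_act
  w <- colMeans(matrix(dA, prod(dim(dA)[1:2]), dim(dA)[3]))
  raw <- matrix(matrix(act, prod(dim(act)[1:2]), dim(act)[3]) %*% w,
                dim(act)[1], dim(act)[2])
  raw <- pmax(raw, 0)
  if (any(dim(raw) != c(out_h, out_w))) {
    raw <- resize_bilinear(raw, out_h, out_w)
    raw <- pmax(raw, 0)
  }
  rng <- range(raw)
  values <- if (rng[2] == 0) {
    raw                                      # all-zero map stays all zero
  } else if (rng[2] > rng[1]) {
    (raw - rng[1]) / (rng[2] - rng[1])
  } else {
    raw / rng[2]                             # constant positive map -> 1
  }
  structure(list(values = values,
                 target_class = c("normal", "tumor")[cls],
                 layer = paste0("conv", layer)),
            class = "attention_map")
}

target_class_index <- function(target_class) {
  if (is.numeric(target_class)) {
    stopifnot(target_class %in% c(1, 2))
    return(as.integer(target_class))
  }
  switch(target_class,
         normal = 1L,
         tumor = , carcinoma = , cancerous = 2L,
         stop("unknown target class: ", target_class, call. = FALSE))
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", nrow(x$values), "x", ncol(x$values),
      ", class = ", x$target_class, ", layer = ", x$layer, "\n", sep = "")
  invisible(x)
}

#' @method autoplot attention_map
#' @export
autoplot.attention_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$values)),
                    col = seq_len(ncol(object$values)))
  df$value <- as.numeric(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "attention") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Grad-CAM,", object$target_class, "@",
                                object$layer), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

gray_panel <- function(values) {
  v <- values * 255
  array(c(v, v, v), c(dim(values), 3L))
}

#' Four-panel comparison figure
#'
#' Composes (left to right) the raw patch, the annotation mask, the
#' Grad-CAM attention map, and the segmentation heatmap, separated by
#' white margins. All inputs must be aligned to the same patch; the
#' composite width is `4 * panel_width + 3 * margin`.
#'
#' @param patch RGB array (0..255).
#' @param mask Binary matrix aligned to the patch.
#' @param attention An `attention_map` (or its `values` matrix).
#' @param seg_heatmap Probability matrix from the segmenter (rendered with
#'   the dark-blue/crimson colormap).
#' @param margin Pixel gap between panels (default 8).
#' @return RGB array in 0..255.
#' @export
render_comparison <- function(patch, mask, attention, seg_heatmap,
                              margin = 8L) {
  if (inherits(attention, "attention_map")) attention <- attention$values
  d <- dim(patch)
  if (length(d) != 3L ||
      !all(dim(mask) == d[1:2]) || !all(dim(attention) == d[1:2]) ||
      !all(dim(seg_heatmap) == d[1:2])) {
    stop("all panels must be aligned to the same patch geometry (",
         d[1], "x", d[2], ")", call. = FALSE)
  }
  panels <- list(patch,
                 gray_panel(mask),
                 gray_panel(attention),
                 colorize(seg_heatmap, block_size = 1L))
  h <- d[1]; w <- d[2]
  out <- array(255, c(h, 4L * w + 3L * margin, 3L))
  for (k in seq_along(panels)) {
    x0 <- (k - 1L) * (w + margin)
    out[, (x0 + 1L):(x0 + w), ] <- panels[[k]]
  }
  out
}
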