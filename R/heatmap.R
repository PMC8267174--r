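# Malignant-probability heatmaps: patch predictions arranged on the slide
# grid, a dark-blue -> crimson colormap, and alpha overlays on the source
# slide.

DARK_BLUE <- c(0, 0, 139)
CRIMSON <- c(220, 20, 60)

#' Assemble patch predictions into a probability heatmap
#'
#' Grid cell (r, c) holds the prediction for the patch whose top-left
#' corner is at `((c-1) * stride, (r-1) * stride)`. Every cell must be
#' covered exactly once; missing or duplicated cells are an error naming
#' the offending coordinates.
#'
#' @param predictions Tibble from [predict_patches()] with `x`, `y`,
#'   `p_normal`, `p_tumor`.
#' @param width,height Slide dimensions in pixels.
#' @param patch_size,stride Tiling geometry used for the predictions.
#' @param background Optional logical vector (or tibble with `x`, `y`,
#'   `background_flag`) marking background cells.
#' @param slide_id Identifier stored on the heatmap.
#' @return A `probability_heatmap`: `p_normal` and `p_tumor` matrices
#'   (rows x cols), `background` logical matrix, geometry fields.
#' @export
assemble_heatmap <- function(predictions, width, height,
                             patch_size = 1024L, stride = patch_size,
                             background = NULL,
                             slide_id = predictions$slide_id[1]) {
  rows <- floor((height - patch_size) / stride) + 1L
  cols <- floor((width - patch_size) / stride) + 1L
  stopifnot(rows >= 1L, cols >= 1L)
  r <- predictions$y %/% stride + 1L
  c <- predictions$x %/% stride + 1L
  ok <- predictions$y %% stride == 0 & predictions$x %% stride == 0 &
    r >= 1 & r <= rows & c >= 1 & c <= cols
  if (any(!ok)) {
    stop("predictions at coordinates off the heatmap grid: ",
         paste(sprintf("(%d,%d)", predictions$x[!ok], predictions$y[!ok]),
               collapse = " "), call. = FALSE)
  }
  lin <- (c - 1L) * rows + r
  if (anyDuplicated(lin)) {
    dup <- lin[duplicated(lin)][1]
    stop("duplicate prediction for grid cell at x=",
         ((dup - 1L) %/% rows) * stride, ", y=",
         ((dup - 1L) %% rows) * stride, call. = FALSE)
  }
  if (length(lin) < rows * cols) {
    missing <- setdiff(seq_len(rows * cols), lin)
    stop("missing predictions for ", length(missing), " grid cell(s), e.g. x=",
         ((missing[1] - 1L) %/% rows) * stride, ", y=",
         ((missing[1] - 1L) %% rows) * stride, call. = FALSE)
  }
  pn <- matrix(NA_real_, rows, cols)
  pt <- matrix(NA_real_, rows, cols)
  pn[lin] <- predictions$p_normal
  pt[lin] <- predictions$p_tumor
  bg <- matrix(FALSE, rows, cols)
  if (!is.null(background)) {
    if (is.data.frame(background)) {
      rb <- background$y %/% stride + 1L
      cb <- background$x %/% stride + 1L
      bg[(cb - 1L) * rows + rb] <- background$background_flag
    } else {
      bg[lin] <- as.logical(background)
    }
  }
  structure(list(slide_id = slide_id, p_normal = pn, p_tumor = pt,
                 background = bg, patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 width = as.integer(width), height = as.integer(height)),
            class = "probability_heatmap")
}

#' @export
print.probability_heatmap <- function(x, ...) {
  cat("<probability_heatmap> ", x$slide_id, ": ", nrow(x$p_tumor), "x",
      ncol(x$p_tumor), " grid (patch ", x$patch_size, ", stride ", x$stride,
      "), mean p_tumor = ", round(mean(x$p_tumor), 4), ", ",
      sum(x$background), " background cell(s)\n", sep = "")
  invisible(x)
}

#' Map tumor probabilities to the dark-blue/crimson colormap
#'
#' `p_tumor = 0` maps to dark blue (0, 0, 139), `p_tumor = 1` to crimson
#' (220, 20, 60), linearly per channel. Background cells are rendered at
#' probability 0. Each grid cell becomes a `block_size` pixel block.
#'
#' @param heatmap A `probability_heatmap`, or a bare probability matrix.
#' @param block_size Rendered pixels per grid cell (default 1 for a bare
#'   matrix, `patch_size` for a heatmap; cap it for quick looks).
#' @return RGB array in 0..255 (unrounded doubles).
#' @export
colorize <- function(heatmap, block_size = NULL) {
  if (inherits(heatmap, "probability_heatmap")) {
    p <- heatmap$p_tumor
    p[heatmap$background] <- 0
    block_size <- block_size %||% heatmap$patch_size
  } else {
    p <- as.matrix(heatmap)
    block_size <- block_size %||% 1L
  }
  stopifnot(all(p >= 0 & p <= 1))
  out <- array(0, c(nrow(p), ncol(p), 3L))
  for (c in 1:3) {
    out[, , c] <- DARK_BLUE[c] + (CRIMSON[c] - DARK_BLUE[c]) * p
  }
  if (block_size > 1L) {
    idx_r <- rep(seq_len(nrow(p)), each = block_size)
    idx_c <- rep(seq_len(ncol(p)), each = block_size)
    out <- out[idx_r, idx_c, , drop = FALSE]
  }
  out
}

#' Alpha-blend a colorized heatmap over the slide image
#'
#' `out = (1 - alpha) * slide + alpha * heatmap`, per pixel and channel.
#'
#' @param slide_image RGB array (0..255).
#' @param heatmap_image RGB array of identical dimensions, e.g. from
#'   [colorize()].
#' @param alpha Blend weight in `[0, 1]` (default 0.5).
#' @return RGB array in 0..255.
#' @export
overlay <- function(slide_image, heatmap_image, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(slide_image) == dim(heatmap_image))) {
    stop("size mismatch: slide is ",
         paste(dim(slide_image), collapse = "x"), ", heatmap is ",
         paste(dim(heatmap_image), collapse = "x"), call. = FALSE)
  }
  (1 - alpha) * slide_image + alpha * heatmap_image
}

#' Tidy a probability heatmap into one row per grid cell
#'
#' @param x A `probability_heatmap`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x`, `y`, `p_normal`, `p_tumor`,
#'   `background`.
#' @method tidy probability_heatmap
#' @export
tidy.probability_heatmap <- function(x, ...) {
  rows <- nrow(x$p_tumor); cols <- ncol(x$p_tumor)
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  out <- tibble::tibble(slide_id = x$slide_id,
                        row = grid$row, col = grid$col)
  out$x <- (grid$col - 1L) * x$stride
  out$y <- (grid$row - 1L) * x$stride
  out$p_normal <- as.numeric(x$p_normal)
  out$p_tumor <- as.numeric(x$p_tumor)
  out$background <- as.logical(x$background)
  out
}

#' Plot a probability heatmap
#'
#' @param object A `probability_heatmap`.
#' @param ... Unused.
#' @return A ggplot object (blocky cell rendering, dark-blue to crimson).
#' @method autoplot probability_heatmap
#' @export
autoplot.probability_heatmap <- function(object, ...) {
  df <- tidy(object)
  df$p_shown <- ifelse(df$background, 0, df$p_tumor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$p_shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = grDevices::rgb(0, 0, 139, maxColorValue = 255),
                                 high = grDevices::rgb(220, 20, 60, maxColorValue = 255),
                                 limits = c(0, 1), name = "P(tumor)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$slide_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
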