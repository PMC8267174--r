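# Synthetic pseudo-WSI generator. Slides are RGB canvases carrying two
# statistically separable textures: dense dark "nuclei" blobs inside tumor
# polygons, sparse pale blobs elsewhere. Ground truth travels with the
# slide as simple polygons in 0-based, y-down pixel coordinates, so the
# whole pipeline (tiling, training, heatmaps, segmentation, evaluation)
# can run and be scored with no external data.

#' Texture parameters for one tissue class
#'
#' Describes the blob texture drawn for either the tumor or the normal
#' class of a synthetic slide.
#'
#' @param nucleus_density Expected number of nucleus blobs per 10^4 square
#'   pixels (a Poisson intensity).
#' @param nucleus_radius_range Length-2 positive interval of blob radii in
#'   pixels.
#' @param nucleus_color RGB triple in 0..255 used for the blobs.
#' @param background_color RGB triple in 0..255 used between blobs.
#' @param jitter_sd Per-channel Gaussian intensity noise SD.
#' @return A `texture_params` list.
#' @examples
#' tumor_texture_params()
#' @export
texture_params <- function(nucleus_density, nucleus_radius_range,
                           nucleus_color, background_color, jitter_sd = 6) {
  stopifnot(
    is.numeric(nucleus_density), length(nucleus_density) == 1L,
    nucleus_density >= 0,
    length(nucleus_radius_range) == 2L, all(nucleus_radius_range > 0),
    nucleus_radius_range[2] >= nucleus_radius_range[1],
    length(nucleus_color) == 3L, all(nucleus_color >= 0 & nucleus_color <= 255),
    length(background_color) == 3L,
    all(background_color >= 0 & background_color <= 255),
    jitter_sd >= 0
  )
  structure(list(nucleus_density = nucleus_density,
                 nucleus_radius_range = nucleus_radius_range,
                 nucleus_color = as.numeric(nucleus_color),
                 background_color = as.numeric(background_color),
                 jitter_sd = jitter_sd),
            class = "texture_params")
}

#' @rdname texture_params
#' @export
tumor_texture_params <- function() {
  texture_params(nucleus_density = 2.5, nucleus_radius_range = c(4, 8),
                 nucleus_color = c(70, 40, 100),
                 background_color = c(220, 185, 210), jitter_sd = 6)
}

#' @rdname texture_params
#' @export
normal_texture_params <- function() {
  texture_params(nucleus_density = 0.4, nucleus_radius_range = c(3, 6),
                 nucleus_color = c(170, 130, 190),
                 background_color = c(235, 210, 225), jitter_sd = 6)
}

# even-odd point-in-polygon for a pixel-centre grid.
# xs, ys are pixel-centre coordinates; returns a length(ys) x length(xs)
# logical matrix (rows = y, matching image row order).
poly_inside_grid <- function(poly, xs, ys) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  out <- matrix(FALSE, length(ys), length(xs))
  # scanline: a pixel centre is inside iff the number of edge crossings
  # strictly to its right is odd
  for (r in seq_along(ys)) {
    y <- ys[r]
    sp <- (y1 > y) != (y2 > y)
    if (!any(sp)) next
    xint <- sort((x2[sp] - x1[sp]) * (y - y1[sp]) / (y2[sp] - y1[sp]) +
                   x1[sp])
    out[r, ] <- ((length(xint) - findInterval(xs, xint)) %% 2L) == 1L
  }
  out
}

# random simple polygon: perturbed hull of points on a disc
random_region_polygon <- function(cx, cy, radius, n_vertices = 14L) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- radius * stats::runif(n_vertices, 0.75, 1.05)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

draw_blobs <- function(image, region_mask, params, want_inside) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_blob <- stats::rpois(1L, params$nucleus_density * h * w / 1e4)
  if (n_blob == 0L) return(image)
  cx <- stats::runif(n_blob, 0, w)
  cy <- stats::runif(n_blob, 0, h)
  rr <- stats::runif(n_blob, params$nucleus_radius_range[1],
                     params$nucleus_radius_range[2])
  for (b in seq_len(n_blob)) {
    ci <- floor(cy[b]) + 1L; cj <- floor(cx[b]) + 1L
    if (ci < 1L || ci > h || cj < 1L || cj > w) next
    if (region_mask[ci, cj] != want_inside) next
    i0 <- max(1L, floor(cy[b] - rr[b])); i1 <- min(h, ceiling(cy[b] + rr[b]))
    j0 <- max(1L, floor(cx[b] - rr[b])); j1 <- min(w, ceiling(cx[b] + rr[b]))
    ii <- i0:i1; jj <- j0:j1
    disc <- outer((ii - 0.5 - cy[b])^2, (jj - 0.5 - cx[b])^2, "+") <= rr[b]^2
    keep <- disc & (region_mask[ii, jj, drop = FALSE] == want_inside)
    if (!any(keep)) next
    for (c in 1:3) {
      plane <- image[ii, jj, c]
      plane[keep] <- params$nucleus_color[c]
      image[ii, jj, c] <- plane
    }
  }
  image
}

#' Generate an annotated synthetic slide
#'
#' Draws a two-texture pseudo-WSI: `n_tumor_regions` random simple polygons
#' receive the tumor texture, the remainder the normal texture. The slide
#' label is `"cancerous"` iff at least one tumor region was requested.
#' All randomness flows from `seed`, so equal arguments give byte-identical
#' images.
#'
#' @param width,height Slide dimensions in pixels; must be at least
#'   `patch_size`.
#' @param n_tumor_regions Number of tumor polygons (0 for a normal slide).
#' @param tumor_params,normal_params [texture_params()] for the two classes.
#' @param seed Integer seed driving every random choice.
#' @param patch_size Downstream tiling unit used to validate the canvas.
#' @param region_radius_range Radius interval for tumor regions, in pixels;
#'   defaults to 15--25% of the shorter slide side.
#' @param slide_id Identifier stored with the slide.
#' @return A `synthetic_slide`: list with `image` (height x width x 3 array,
#'   0..255), `tumor_polygons` (list of n x 2 matrices, 0-based x/y),
#'   `slide_label`, `seed`, `width`, `height`, `slide_id`.
#' @examples
#' sl <- generate_slide(256, 256, 1, seed = 1, patch_size = 128)
#' sl$slide_label
#' @export
generate_slide <- function(width, height, n_tumor_regions,
                           tumor_params = tumor_texture_params(),
                           normal_params = normal_texture_params(),
                           seed = 1L, patch_size = 1024L,
                           region_radius_range = NULL,
                           slide_id = sprintf("slide_%05d", seed)) {
  if (width < patch_size || height < patch_size) {
    stop("slide dimensions (", width, "x", height,
         ") are smaller than one patch (", patch_size, ")", call. = FALSE)
  }
  stopifnot(n_tumor_regions >= 0)
  set.seed(seed)
  if (is.null(region_radius_range)) {
    # large enough that a lesion fully covers at least one tiling patch
    region_radius_range <- c(0.28, 0.38) * min(width, height)
  }
  polys <- list()
  if (n_tumor_regions > 0L) {
    centers <- matrix(NA_real_, 0L, 2L)
    for (k in seq_len(n_tumor_regions)) {
      r <- stats::runif(1L, region_radius_range[1], region_radius_range[2])
      for (try in 1:200) {
        cx <- stats::runif(1L, r, width - r)
        cy <- stats::runif(1L, r, height - r)
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                1.6 * mean(region_radius_range))) break
      }
      centers <- rbind(centers, c(cx, cy))
      poly <- random_region_polygon(cx, cy, r)
      poly[, 1] <- pmin(pmax(poly[, 1], 1), width - 1)
      poly[, 2] <- pmin(pmax(poly[, 2], 1), height - 1)
      polys[[k]] <- poly
    }
  }
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  tumor_mask <- matrix(FALSE, height, width)
  for (poly in polys) tumor_mask <- tumor_mask | poly_inside_grid(poly, xs, ys)

  image <- array(0, c(height, width, 3L))
  for (c in 1:3) {
    plane <- matrix(normal_params$background_color[c], height, width)
    plane[tumor_mask] <- tumor_params$background_color[c]
    image[, , c] <- plane
  }
  image <- draw_blobs(image, tumor_mask, normal_params, want_inside = FALSE)
  if (any(tumor_mask)) {
    image <- draw_blobs(image, tumor_mask, tumor_params, want_inside = TRUE)
  }
  noise <- stats::rnorm(length(image))
  if (tumor_params$jitter_sd == normal_params$jitter_sd) {
    noise <- noise * normal_params$jitter_sd
  } else {
    sd_map <- normal_params$jitter_sd +
      tumor_mask * (tumor_params$jitter_sd - normal_params$jitter_sd)
    noise <- noise * as.numeric(array(sd_map, dim(image)))
  }
  image <- image + noise
  image[image < 0] <- 0
  image[image > 255] <- 255
  image <- round(image)

  structure(list(image = image, tumor_polygons = polys,
                 slide_label = if (length(polys) > 0L) "cancerous" else "normal",
                 seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height), slide_id = slide_id),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("<synthetic_slide> ", x$slide_id, ": ", x$width, "x", x$height,
      ", label = ", x$slide_label, ", ", length(x$tumor_polygons),
      " tumor region(s), seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Rasterize tumor polygons to a binary mask
#'
#' A pixel is 1 iff its centre falls inside any tumor polygon (even-odd
#' rule per polygon, union across polygons).
#'
#' @param slide A `synthetic_slide`, or a list of n x 2 polygon matrices
#'   (0-based pixel coordinates, y down).
#' @param window Integer vector `c(x, y, width, height)` (0-based origin)
#'   selecting the region to rasterize; defaults to the whole slide. For a
#'   bare polygon list the window is required.
#' @return Integer 0/1 matrix of dimension `height x width`.
#' @examples
#' tri <- list(cbind(c(0, 10, 0), c(0, 0, 10)))
#' sum(rasterize_mask(tri, window = c(0, 0, 10, 10)))
#' @export
rasterize_mask <- function(slide, window = NULL) {
  if (inherits(slide, "synthetic_slide")) {
    polys <- slide$tumor_polygons
    if (is.null(window)) window <- c(0L, 0L, slide$width, slide$height)
    if (window[1] < 0 || window[2] < 0 ||
        window[1] + window[3] > slide$width ||
        window[2] + window[4] > slide$height) {
      stop("window [", paste(window, collapse = ", "),
           "] lies outside the slide bounds", call. = FALSE)
    }
  } else {
    polys <- slide
    if (is.null(window)) stop("window is required for a bare polygon list",
                              call. = FALSE)
  }
  stopifnot(length(window) == 4L, window[3] >= 1, window[4] >= 1)
  xs <- window[1] + seq_len(window[3]) - 0.5
  ys <- window[2] + seq_len(window[4]) - 0.5
  mask <- matrix(FALSE, window[4], window[3])
  for (poly in polys) mask <- mask | poly_inside_grid(poly, xs, ys)
  mask * 1L
}

#' Write a synthetic slide to disk
#'
#' Writes the image as PNG (or float TIFF for `.tif`/`.tiff` paths) and,
#' when polygons are present, a GeoJSON FeatureCollection of the tumor
#' regions in 0-based pixel coordinates.
#'
#' @param slide A `synthetic_slide`.
#' @param image_path Output image path (`.png`, `.tif` or `.tiff`).
#' @param annotation_path Optional GeoJSON output path.
#' @return Invisibly, the slide.
#' @export
write_slide <- function(slide, image_path, annotation_path = NULL) {
  img <- slide$image / 255
  if (grepl("\\.tiff?$", image_path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, image_path)
  } else {
    png::writePNG(img, image_path)
  }
  if (!is.null(annotation_path)) {
    write_annotation_geojson(slide$tumor_polygons, annotation_path,
                             slide_id = slide$slide_id)
  }
  invisible(slide)
}

#' @rdname write_slide
#' @param polygons List of n x 2 polygon matrices.
#' @param path GeoJSON output path.
#' @param slide_id Identifier recorded on each feature.
#' @export
write_annotation_geojson <- function(polygons, path, slide_id = "slide") {
  features <- lapply(seq_along(polygons), function(i) {
    poly <- polygons[[i]]
    ring <- rbind(poly, poly[1L, , drop = FALSE])   # closed ring
    list(type = "Feature",
         properties = list(slide_id = slide_id, region = i,
                           class = "tumor"),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(r) as.numeric(ring[r, ]))))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons back from a GeoJSON annotation file
#'
#' @param path GeoJSON file written by [write_annotation_geojson()].
#' @return List of n x 2 polygon matrices (closing vertex dropped).
#' @export
read_annotation_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m[-nrow(m), , drop = FALSE]
  })
}

#' Build a slide manifest table
#'
#' @param slides List of `synthetic_slide` objects.
#' @param paths Optional character vector of image paths (one per slide).
#' @return Tibble with columns `slide_id`, `path`, `label`, `seed`,
#'   `width`, `height`.
#' @export
slide_manifest <- function(slides, paths = NA_character_) {
  tibble::tibble(
    slide_id = purrr::map_chr(slides, "slide_id"),
    path = paths,
    label = purrr::map_chr(slides, "slide_label"),
    seed = purrr::map_int(slides, "seed"),
    width = purrr::map_int(slides, "width"),
    height = purrr::map_int(slides, "height")
  )
}
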