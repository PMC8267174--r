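# U-Net tile segmentation. Tiles are the half-overlap 256-pixel crops
# from the tiling module; training minimizes 1 - dice (soft dice with a
# smoothing epsilon of 1), evaluation reports dice with epsilon 0, and
# predicted tile maps are stitched back to patch- or slide-level
# probability maps by per-pixel averaging. Convolutions use "same"
# padding, so each tile's output matches its input size exactly.

#' Soft dice coefficient
#'
#' `dice = (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`.
#' For binary `pred` this is the classic overlap dice; `1 - dice` is the
#' training loss. When both masks are empty and `epsilon = 0` the
#' coefficient is defined as 1 (perfect agreement).
#'
#' @param pred Probability mask in `[0, 1]`.
#' @param truth Binary mask (0/1) of the same shape.
#' @param epsilon Smoothing term (0 for evaluation, 1 during training).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice_coefficient(matrix(0.5, 4, 4), matrix(1, 4, 4))  # 2/3
#' @export
dice_coefficient <- function(pred, truth, epsilon = 0) {
  if (!all(dim(pred) == dim(truth))) {
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", truth is ", paste(dim(truth), collapse = "x"), call. = FALSE)
  }
  stopifnot(all(pred >= 0 & pred <= 1), all(truth %in% c(0, 1)),
            epsilon >= 0)
  denom <- sum(pred) + sum(truth) + epsilon
  if (denom == 0) return(1)
  (2 * sum(pred * truth) + epsilon) / denom
}

#' Configuration for the U-Net segmenter
#'
#' @param depth Encoder levels (default 4).
#' @param base_filters Channels of the first level (default 64; the
#'   desk-scale preset uses 16).
#' @param input_size Network input side; tiles are mean-pooled down to
#'   this size and predictions resized back (default 256, native tile
#'   resolution).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param epsilon_train Dice smoothing used in the loss (evaluation always
#'   uses 0).
#' @param augment Random horizontal flips and ±10% per-channel brightness
#'   jitter during training.
#' @param seed Integer seed for weights, shuffling and augmentation.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(depth = 4L, base_filters = 64L,
                                input_size = 256L, epochs = 10L,
                                batch_size = 4L, learning_rate = 0.01,
                                epsilon_train = 1, augment = TRUE,
                                seed = 1L) {
  stopifnot(depth >= 1L, base_filters >= 1L, input_size %% 2L^depth == 0L,
            epochs >= 0L, batch_size >= 1L, learning_rate > 0)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 loss = "dice",
                 epsilon_train = epsilon_train,
                 augment = augment,
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' @rdname segmentation_config
#' @details `unet_test_config()` is the desk-scale preset used throughout
#'   the package's own experiments: depth 2, 16 base filters, tiles
#'   mean-pooled to 64 px.
#' @export
unet_test_config <- function(epochs = 5L, seed = 1L) {
  segmentation_config(depth = 2L, base_filters = 16L, input_size = 64L,
                      epochs = epochs, batch_size = 2L,
                      learning_rate = 0.03, seed = seed)
}

#' Build an (untrained) U-Net
#'
#' @param config A [segmentation_config()].
#' @return A `unet_model` object.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "segmentation_config"))
  params <- init_unet_params(config$depth, config$base_filters, config$seed)
  structure(list(params = params, config = config, trained = FALSE,
                 best_epoch = NA_integer_, val_dice = NA_real_, log = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> depth ", x$config$depth, ", ", x$config$base_filters,
      " base filters, input ", x$config$input_size, " px, ",
      format(count_params(x$params), big.mark = ","), " parameters, ",
      if (x$trained) paste0("trained (best epoch ", x$best_epoch,
                            ", val dice ", round(x$val_dice, 4), ")")
      else "untrained", "\n", sep = "")
  invisible(x)
}

prep_tile <- function(tile, input_size) {
  d <- dim(tile)
  if (d[1] != input_size) {
    tile <- if (d[1] %% input_size == 0L) {
      downscale_mean(tile, d[1] %/% input_size)
    } else {
      resize_bilinear(tile, input_size, input_size)
    }
  }
  tile / 127.5 - 1
}

prep_mask <- function(mask, input_size) {
  d <- dim(mask)
  if (d[1] != input_size) {
    mask <- if (d[1] %% input_size == 0L) {
      downscale_mean(mask, d[1] %/% input_size)
    } else {
      resize_bilinear(mask, input_size, input_size)
    }
  }
  (mask >= 0.5) * 1
}

#' Train the U-Net on tiles and aligned masks
#'
#' Minimizes `1 - dice` with Adam, where the soft dice (smoothed by
#' `config$epsilon_train`) is computed over each minibatch jointly —
#' per-tile dice starves all-zero-truth tiles of gradient, so a per-tile
#' loss never learns to suppress tumor-free regions.
#' After every epoch the validation tiles are scored with unsmoothed dice
#' and the best-validation checkpoint (earliest epoch on ties) becomes the
#' final model; without a validation split the final epoch is kept.
#'
#' Dice loss has a trivial constant optimum (call everything positive)
#' that some initialisations fall into and cannot leave; a fit whose
#' validation predictions are essentially all positive is therefore
#' detected as collapsed and retrained from a shifted initialisation (up
#' to three attempts, best validation dice kept).
#'
#' @param tiles Tibble with `tile` and `mask_tile` list-columns (as
#'   produced by [subsample_half_overlap()]) and optionally a `split`
#'   column with training/validation values.
#' @param config A [segmentation_config()].
#' @return A trained `unet_model` with a per-epoch `log`.
#' @export
train_unet <- function(tiles, config = segmentation_config()) {
  stopifnot(is.data.frame(tiles), !is.null(tiles$tile),
            !is.null(tiles$mask_tile))
  if (!any(vapply(tiles$mask_tile, function(m) any(m > 0), logical(1)))) {
    stop("no positive pixels in any mask; nothing to segment", call. = FALSE)
  }
  split <- if ("split" %in% names(tiles)) tiles$split
           else rep("training", nrow(tiles))
  tr_idx <- which(split == "training")
  va_idx <- which(split == "validation")
  stopifnot(length(tr_idx) > 0L)
  isz <- config$input_size
  x_tr <- lapply(tiles$tile[tr_idx], prep_tile, input_size = isz)
  m_tr <- lapply(tiles$mask_tile[tr_idx], prep_mask, input_size = isz)
  x_va <- lapply(tiles$tile[va_idx], prep_tile, input_size = isz)
  m_va <- lapply(tiles$mask_tile[va_idx], prep_mask, input_size = isz)

  model <- build_unet(config)

  train_once <- function(attempt_seed) {
  params <- init_unet_params(config$depth, config$base_filters, attempt_seed)
  state <- adam_init(params)
  t_step <- 0L
  best <- list(params = params, dice = -Inf, epoch = NA_integer_)
  log <- vector("list", config$epochs)
  set.seed(attempt_seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(x_tr))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      # soft dice is computed over the whole minibatch: per-tile dice
      # gives all-zero-truth tiles vanishing gradients, so the model never
      # learns to suppress tumor-free regions
      fws <- vector("list", length(idx))
      masks <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        x <- x_tr[[idx[j]]]; m <- m_tr[[idx[j]]]
        if (config$augment) {
          if (stats::runif(1) < 0.5) {
            x <- flip_image(x, "h"); m <- flip_image(m, "h")
          }
          # per-channel brightness jitter, uniform within ±5% of range
          shift <- stats::runif(3L, -0.1, 0.1)
          x <- sweep(x, 3L, shift, "+")
        }
        fws[[j]] <- forward_unet(params, x, cache = TRUE)
        masks[[j]] <- m
      }
      s_p <- sum(vapply(fws, function(f) sum(f$prob), numeric(1)))
      s_t <- sum(vapply(masks, sum, numeric(1)))
      s_pt <- sum(mapply(function(f, m) sum(f$prob * m), fws, masks))
      denom <- s_p + s_t + config$epsilon_train
      batch_dice <- (2 * s_pt + config$epsilon_train) / denom
      gsum <- NULL
      for (j in seq_along(idx)) {
        dprob <- -(2 * masks[[j]] * denom - (2 * s_pt +
                                               config$epsilon_train)) /
          denom^2
        dz <- dprob * fws[[j]]$prob * (1 - fws[[j]]$prob) *
          fws[[j]]$grad_mask
        bw <- backward_unet(params, fws[[j]]$caches, dz)
        gsum <- if (is.null(gsum)) bw else tree_add(gsum, bw)
      }
      t_step <- t_step + 1L
      # short warmup: full-rate first steps can saturate the sigmoid
      # into an all-positive map the dice gradient cannot leave
      lr_t <- config$learning_rate * min(1, t_step / 20)
      upd <- adam_step(params, gsum, state, lr_t, t_step)
      params <- upd$p; state <- upd$s
      losses <- c(losses, 1 - batch_dice)
    }
    val_dice <- if (length(va_idx) > 0L) {
      mean(mapply(function(x, m) {
        dice_coefficient(forward_unet(params, x)$prob, m, epsilon = 0)
      }, x_va, m_va))
    } else NA_real_
    log[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                val_dice = val_dice)
    score <- if (is.na(val_dice)) ep else val_dice   # no val: keep last
    if (score > best$dice) best <- list(params = params, dice = score,
                                        epoch = ep)
  }
  # collapse check: a fit that calls essentially every validation pixel
  # positive has fallen into the dice loss's trivial constant optimum
  collapsed <- FALSE
  if (length(va_idx) > 0L && config$epochs > 0L) {
    pos_frac <- mean(vapply(x_va, function(x) {
      mean(forward_unet(best$params, x)$prob >= 0.5)
    }, numeric(1)))
    truth_frac <- mean(vapply(m_va, mean, numeric(1)))
    collapsed <- pos_frac > 0.95 && truth_frac < 0.8
  }
  list(best = best, log = log, collapsed = collapsed)
  }

  # multi-start: restart collapsed fits from a shifted initialisation and
  # keep the best-validation attempt
  result <- NULL
  for (attempt in seq_len(3L)) {
    r <- train_once(config$seed + (attempt - 1L) * 1009L)
    r$attempt <- attempt
    if (is.null(result) || r$best$dice > result$best$dice) result <- r
    if (!r$collapsed) break
  }

  if (config$epochs > 0L) {
    model$params <- result$best$params
    model$best_epoch <- result$best$epoch
    model$val_dice <- if (length(va_idx) > 0L) result$best$dice else NA_real_
    model$trained <- TRUE
    model$attempts <- result$attempt
  }
  model$log <- if (config$epochs > 0L) dplyr::bind_rows(result$log) else
    tibble::tibble(epoch = integer(), loss = numeric(), val_dice = numeric())
  model
}

#' @method tidy unet_model
#' @export
tidy.unet_model <- function(x, ...) {
  x$log %||% tibble::tibble(epoch = integer(), loss = numeric(),
                            val_dice = numeric())
}

#' @method glance unet_model
#' @export
glance.unet_model <- function(x, ...) {
  tibble::tibble(depth = x$config$depth,
                 base_filters = x$config$base_filters,
                 input_size = x$config$input_size,
                 n_params = count_params(x$params),
                 trained = x$trained,
                 best_epoch = x$best_epoch,
                 val_dice = x$val_dice)
}

#' Predict tile probability maps
#'
#' @param model A `unet_model`.
#' @param tiles Tibble with a `tile` list-column, or a list of RGB arrays.
#' @return List of probability matrices at the tiles' native resolution.
#' @export
predict_tiles <- function(model, tiles) {
  stopifnot(inherits(model, "unet_model"))
  imgs <- if (is.data.frame(tiles)) tiles$tile else tiles
  lapply(imgs, function(im) {
    side <- dim(im)[1]
    x <- prep_tile(im, model$config$input_size)
    prob <- forward_unet(model$params, x)$prob
    if (nrow(prob) != side) prob <- resize_bilinear(prob, side, side)
    prob
  })
}

#' Stitch tile probability maps by per-pixel averaging
#'
#' Every output pixel is the mean of all tile predictions covering it.
#' Tile regions that overhang the canvas (the mirror-padded half-overlap
#' edge tiles) are cropped before averaging. Uncovered pixels are an
#' error.
#'
#' @param maps List of square probability matrices.
#' @param offsets Tibble or matrix of 0-based `offset_x`, `offset_y` tile
#'   origins (one row per map).
#' @param width,height Canvas size in pixels.
#' @return `height` x `width` probability matrix.
#' @examples
#' m <- list(matrix(0.2, 4, 4), matrix(0.8, 4, 4))
#' off <- tibble::tibble(offset_x = c(0, 2), offset_y = c(0, 0))
#' stitch(m, off, width = 6, height = 4)[1, 3]   # 0.5 in the overlap
#' @export
stitch <- function(maps, offsets, width, height) {
  if (is.matrix(offsets)) {
    offsets <- tibble::tibble(offset_x = offsets[, 1], offset_y = offsets[, 2])
  }
  stopifnot(length(maps) == nrow(offsets))
  acc <- matrix(0, height, width)
  cnt <- matrix(0L, height, width)
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    ox <- offsets$offset_x[k]; oy <- offsets$offset_y[k]
    h <- min(nrow(m), height - oy)
    w <- min(ncol(m), width - ox)
    if (h <= 0L || w <= 0L) next
    ri <- (oy + 1L):(oy + h); cj <- (ox + 1L):(ox + w)
    acc[ri, cj] <- acc[ri, cj] + m[seq_len(h), seq_len(w)]
    cnt[ri, cj] <- cnt[ri, cj] + 1L
  }
  if (any(cnt == 0L)) {
    bad <- which(cnt == 0L, arr.ind = TRUE)[1L, ]
    stop("canvas pixel (x=", bad[2] - 1L, ", y=", bad[1] - 1L,
         ") is covered by no tile", call. = FALSE)
  }
  acc / cnt
}
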