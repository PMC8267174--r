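# Patch-level two-class classifier: a convolutional backbone followed by
# global average pooling, a 1,024-neuron fully connected layer and a 2-way
# softmax. Training uses Adam (learning rate 0.001), categorical
# cross-entropy, batches of eight, and keeps the checkpoint with the
# highest validation accuracy (earliest epoch on ties). The `small_cnn`
# backbone runs the whole protocol at desk scale; `inception_v3_class` is
# a larger preset with the same head for full-size experiments.

#' Training configuration for the patch classifier
#'
#' Defaults follow the reference training protocol: Adam, learning rate
#' 0.001, categorical cross-entropy, 100 epochs, batch size 8, checkpoint
#' selected by validation accuracy.
#'
#' @param backbone `"small_cnn"` (32 px input, ~100k parameters) or
#'   `"inception_v3_class"` (96 px input, a deeper preset).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @param input_size Network input side in pixels; `NULL` uses the
#'   backbone's native size (patches are resized on the way in).
#' @return A `training_config` list.
#' @export
patch_config <- function(backbone = "small_cnn", learning_rate = 0.001,
                         epochs = 100L, batch_size = 8L, seed = 1L,
                         input_size = NULL) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  spec <- backbone_spec(backbone)
  structure(list(backbone = backbone,
                 optimizer = "adam",
                 loss = "categorical_crossentropy",
                 checkpoint_metric = "validation_accuracy",
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 input_size = as.integer(input_size %||% spec$input_size)),
            class = "training_config")
}

#' Build a patch classifier
#'
#' Instantiates backbone -> global average pool -> 1,024-unit fully
#' connected layer -> 2-way softmax, with weights drawn from
#' `config$seed`. Class order is (normal, carcinoma).
#'
#' @param config A [patch_config()].
#' @return A `patch_classifier` object.
#' @examples
#' m <- build_classifier(patch_config("small_cnn", seed = 7))
#' glance(m)
#' @export
build_classifier <- function(config) {
  stopifnot(inherits(config, "training_config"))
  spec <- backbone_spec(config$backbone)
  params <- init_classifier_params(spec, config$seed)
  structure(list(spec = spec, params = params, config = config,
                 classes = c("normal", "carcinoma"),
                 trained = FALSE, best_epoch = NA_integer_,
                 val_accuracy = NA_real_, log = NULL),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("<patch_classifier> backbone = ", x$config$backbone,
      ", input ", x$config$input_size, " px, ",
      format(count_params(x$params), big.mark = ","), " parameters, ",
      if (x$trained) paste0("trained (best epoch ", x$best_epoch,
                            ", val acc ", round(x$val_accuracy, 4), ")")
      else "untrained", "\n", sep = "")
  invisible(x)
}

patch_label_to_index <- function(label) {
  idx <- match(label, c("normal", "carcinoma"))
  if (anyNA(idx)) stop("labels must be 'normal' or 'carcinoma'", call. = FALSE)
  idx
}

prep_images <- function(images, input_size) {
  lapply(images, preprocess_patch, size = input_size)
}

#' Train the patch classifier
#'
#' Minibatch Adam on categorical cross-entropy over the manifest's
#' training split; after every epoch the validation split is scored and
#' the parameter set with the highest validation accuracy (earliest epoch
#' on ties) is kept as the final model. With `epochs = 0` the returned
#' model equals the initialisation.
#'
#' @param model A `patch_classifier` from [build_classifier()].
#' @param manifest Patch tibble with `image`, `label` and `split` columns
#'   (training and validation splits required, both classes present in
#'   training).
#' @param epochs Override of `config$epochs` (handy for smoke runs).
#' @return The trained `patch_classifier`, with a `log` tibble of
#'   per-epoch mean loss and validation accuracy.
#' @export
train_patch_classifier <- function(model, manifest, epochs = NULL) {
  stopifnot(inherits(model, "patch_classifier"))
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  train <- manifest[manifest$split == "training", ]
  val <- manifest[manifest$split == "validation", ]
  if (nrow(train) == 0L || nrow(val) == 0L) {
    stop("manifest needs nonempty training and validation splits",
         call. = FALSE)
  }
  if (length(unique(train$label)) < 2L) {
    stop("training split contains a single class; cannot fit a two-class ",
         "model", call. = FALSE)
  }
  x_train <- prep_images(train$image, cfg$input_size)
  y_train <- patch_label_to_index(train$label)
  x_val <- prep_images(val$image, cfg$input_size)
  y_val <- patch_label_to_index(val$label)

  params <- model$params
  state <- adam_init(params)
  t_step <- 0L
  best <- list(params = params, acc = -Inf, epoch = NA_integer_)
  log <- vector("list", epochs)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(x_train))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gsum <- NULL
      bl <- 0
      for (i in idx) {
        fw <- forward_classifier(list(params = params, spec = model$spec),
                                 x_train[[i]], cache = TRUE)
        y1h <- c(0, 0); y1h[y_train[i]] <- 1
        bl <- bl - log(max(fw$probs[y_train[i]], 1e-12))
        bw <- backward_classifier(list(params = params, spec = model$spec),
                                  fw$caches, fw$probs - y1h)
        gsum <- if (is.null(gsum)) bw$grads else tree_add(gsum, bw$grads)
      }
      gavg <- tree_scale(gsum, 1 / length(idx))
      t_step <- t_step + 1L
      upd <- adam_step(params, gavg, state, cfg$learning_rate, t_step)
      params <- upd$p; state <- upd$s
      losses <- c(losses, bl / length(idx))
    }
    acc <- classifier_accuracy(params, model$spec, x_val, y_val)
    log[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                val_accuracy = acc)
    if (acc > best$acc) best <- list(params = params, acc = acc, epoch = ep)
  }
  if (epochs > 0L) {
    model$params <- best$params
    model$best_epoch <- best$epoch
    model$val_accuracy <- best$acc
    model$trained <- TRUE
  }
  model$log <- if (epochs > 0L) dplyr::bind_rows(log) else
    tibble::tibble(epoch = integer(), loss = numeric(),
                   val_accuracy = numeric())
  model
}

classifier_accuracy <- function(params, spec, xs, ys) {
  pred <- vapply(xs, function(x) {
    which.max(forward_classifier(list(params = params, spec = spec),
                                 x)$probs)
  }, integer(1))
  mean(pred == ys)
}

#' Score patches with a patch classifier
#'
#' Deterministic inference: one `(p_normal, p_tumor)` pair per patch, the
#' two probabilities summing to one. Background-flagged patches are scored
#' like any other; the flag is consumed downstream when the heatmap is
#' assembled.
#'
#' @param model A `patch_classifier`.
#' @param patches Patch tibble with an `image` list-column (or a list of
#'   RGB arrays).
#' @return Tibble with `slide_id`, `x`, `y`, `p_normal`, `p_tumor`.
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "patch_classifier"))
  if (!is.data.frame(patches)) {
    patches <- tibble::tibble(slide_id = "slide",
                              x = NA_integer_, y = NA_integer_,
                              image = patches)
  }
  imgs <- patches$image
  bad <- vapply(imgs, function(im) length(dim(im)) != 3L || dim(im)[3] != 3L,
                logical(1))
  if (any(bad)) {
    stop("patch images must be H x W x 3 arrays; offending rows: ",
         paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)
  }
  xs <- prep_images(imgs, model$config$input_size)
  probs <- t(vapply(xs, function(x) {
    forward_classifier(model, x)$probs
  }, numeric(2)))
  tibble::tibble(slide_id = patches$slide_id, x = patches$x, y = patches$y,
                 p_normal = probs[, 1], p_tumor = probs[, 2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy patch_classifier
#' @export
tidy.patch_classifier <- function(x, ...) {
  x$log %||% tibble::tibble(epoch = integer(), loss = numeric(),
                            val_accuracy = numeric())
}

#' @method glance patch_classifier
#' @export
glance.patch_classifier <- function(x, ...) {
  tibble::tibble(backbone = x$config$backbone,
                 input_size = x$config$input_size,
                 n_params = count_params(x$params),
                 trained = x$trained,
                 best_epoch = x$best_epoch,
                 val_accuracy = x$val_accuracy)
}
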