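# Slide-level classifier: gradient-boosted decision trees (xgboost) over
# the 36 heatmap features. Hyperparameters are pinned for reproducibility
# (100 trees, learning rate 0.1, single thread, fixed seed); the decision
# threshold defaults to 0.5 and is configurable.

slide_feature_matrix <- function(features) {
  nms <- heatmap_feature_names()
  missing <- setdiff(nms, names(features))
  if (length(missing) > 0L) {
    stop("feature table is missing ", length(missing),
         " of the 36 heatmap features (", paste(utils::head(missing, 3),
                                                collapse = ", "),
         if (length(missing) > 3) ", ..." else "", ")", call. = FALSE)
  }
  m <- as.matrix(features[, nms])
  storage.mode(m) <- "double"
  m
}

#' Train the slide-level gradient-boosted classifier
#'
#' Fits a boosted decision-tree ensemble on the 36 heatmap features.
#' Fitting is single-threaded and seeded, so refits are deterministic and
#' invariant to training-row order.
#'
#' @param features Tibble with the 36 feature columns (see
#'   [heatmap_feature_names()]), a `label` column (`"normal"` /
#'   `"cancerous"`, or 0/1), and optionally `slide_id`.
#' @param params Booster overrides merged over the defaults
#'   `list(nrounds = 100, eta = 0.1, max_depth = 6, min_child_weight = 0,
#'   tree_method = "exact")` (exact greedy splits: histogram binning can
#'   misplace cut points on cohorts of only tens of slides).
#' @param seed Integer seed.
#' @param threshold Decision threshold on `p_cancerous`.
#' @return A `slide_classifier` object.
#' @export
train_slide_classifier <- function(features, params = list(), seed = 1L,
                                   threshold = 0.5) {
  y <- slide_label_to_binary(features$label)
  if (length(unique(y)) < 2L) {
    stop("slide training data contains a single class", call. = FALSE)
  }
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("need at least 2 slides per class; got ", sum(y == 1),
         " cancerous / ", sum(y == 0), " normal", call. = FALSE)
  }
  X <- slide_feature_matrix(features)
  # identical feature vectors with conflicting labels can only be fit to
  # chance level; flag them rather than fail silently
  key <- apply(X, 1L, paste, collapse = "\r")
  conflict <- any(vapply(split(y, key), function(g) length(unique(g)) > 1L,
                         logical(1)))
  if (conflict) {
    warning("identical feature vectors appear in both classes; ",
            "the model cannot do better than chance on them",
            call. = FALSE)
  }
  defaults <- list(nrounds = 100L, eta = 0.1, max_depth = 6L,
                   min_child_weight = 0, tree_method = "exact")
  prm <- utils::modifyList(defaults, params)
  nrounds <- prm$nrounds; prm$nrounds <- NULL
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = c(prm, list(objective = "binary:logistic", nthread = 1L,
                         seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, feature_names = heatmap_feature_names(),
                 threshold = threshold, seed = as.integer(seed),
                 n_train = nrow(X), n_rounds = nrounds,
                 class_counts = table(y), conflict_flag = conflict),
            class = "slide_classifier")
}

slide_label_to_binary <- function(label) {
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(0, 1)))
    return(as.numeric(label))
  }
  y <- match(label, c("normal", "cancerous")) - 1
  if (anyNA(y)) stop("labels must be 'normal' or 'cancerous'", call. = FALSE)
  y
}

#' @export
print.slide_classifier <- function(x, ...) {
  cat("<slide_classifier> boosted trees on 36 heatmap features, ",
      x$n_rounds, " rounds, trained on ", x$n_train,
      " slides, threshold = ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict slide labels from heatmap features
#'
#' @param model A `slide_classifier`.
#' @param features Tibble with the 36 feature columns (and optionally
#'   `slide_id`), or a bare numeric vector of length 36.
#' @return Tibble with `slide_id`, `p_cancerous`, `predicted_label`
#'   (`"cancerous"` iff `p_cancerous >= threshold`).
#' @export
predict_slide <- function(model, features) {
  stopifnot(inherits(model, "slide_classifier"))
  if (is.numeric(features) && is.null(dim(features))) {
    if (length(features) != 36L) {
      stop("feature vector must have length 36, got ", length(features),
           call. = FALSE)
    }
    features <- tibble::as_tibble(as.list(stats::setNames(
      features, heatmap_feature_names())))
  }
  X <- slide_feature_matrix(features)
  p <- stats::predict(model$booster, X)
  tibble::tibble(
    slide_id = if ("slide_id" %in% names(features)) features$slide_id
               else sprintf("slide_%d", seq_len(nrow(X))),
    p_cancerous = as.numeric(p),
    predicted_label = ifelse(p >= model$threshold, "cancerous", "normal")
  )
}

#' Feature importances of the slide classifier
#'
#' Total split gain per feature, summed over all trees. All 36 features
#' are reported (unused ones with importance 0), sorted by decreasing
#' importance with ties broken by feature index.
#'
#' @param model A trained `slide_classifier`.
#' @return Tibble with `feature`, `index`, `importance`.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "slide_classifier")) {
    stop("feature_importances requires a trained slide_classifier",
         call. = FALSE)
  }
  nms <- model$feature_names
  gain <- stats::setNames(rep(0, length(nms)), nms)
  trees <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  splits <- trees[trees$Feature != "Leaf", , drop = FALSE]
  if (nrow(splits) > 0L) {
    agg <- tapply(splits$Gain, splits$Feature, sum)
    gain[names(agg)] <- agg
  }
  out <- tibble::tibble(feature = nms, index = seq_along(nms),
                        importance = unname(gain))
  out[order(-out$importance, out$index), ]
}

#' @method tidy slide_classifier
#' @export
tidy.slide_classifier <- function(x, ...) feature_importances(x)

#' @method glance slide_classifier
#' @export
glance.slide_classifier <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 n_rounds = x$n_rounds,
                 threshold = x$threshold,
                 seed = x$seed,
                 conflicting_duplicates = x$conflict_flag)
}
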