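# The 36 heatmap summary statistics that feed the slide-level classifier:
# nine moment/order statistics of the normal probabilities, the same nine
# of the tumor probabilities, sixteen N_p band counts (eight half-open
# probability bands times two classes), and two winner labels. Feature
# names and order are stable and documented in `heatmap_feature_names()`.

BAND_BREAKS <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 0.999, 1)

#' Probability band of the N_p counting scheme
#'
#' Bands are half-open and cover (0.5, 1]: band 1 is (0.999, 1], band 2 is
#' (0.99, 0.999], ..., band 8 is (0.5, 0.6]. Probabilities at or below 0.5
#' belong to no band. Boundaries belong to the lower band, so
#' `band_of(0.999)` is band 2.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @return Integer band index 1..8, or `NA` for `p <= 0.5`.
#' @examples
#' band_of(c(0.9995, 0.999, 0.5))
#' @export
band_of <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  # ascending interval index 1..8 for (0.5,0.6], ..., (0.999,1]
  asc <- findInterval(p, BAND_BREAKS, left.open = TRUE,
                      rightmost.closed = TRUE)
  asc[p <= 0.5 | p > 1] <- NA_integer_
  9L - asc
}

band_labels <- function() {
  c("p_gt_0.999", "0.99_lt_p_le_0.999", "0.95_lt_p_le_0.99",
    "0.9_lt_p_le_0.95", "0.8_lt_p_le_0.9", "0.7_lt_p_le_0.8",
    "0.6_lt_p_le_0.7", "0.5_lt_p_le_0.6")
}

#' Names of the 36 heatmap features, in table order
#'
#' @return Character vector of length 36: `f1`..`f9` statistics of the
#'   normal probabilities, `f10`..`f18` of the tumor probabilities,
#'   `f19`..`f34` the per-band N_p counts (normal then tumor within each
#'   band, bands from (0.999, 1] down to (0.5, 0.6]), `f35` the class with
#'   the larger mean probability, `f36` the class with the most patches.
#' @export
heatmap_feature_names <- function() {
  stats <- c("mean", "variance", "std", "median", "mode", "min", "max",
             "range", "sum")
  c(paste0("normal_", stats), paste0("tumor_", stats),
    as.vector(t(outer(band_labels(), c("np_normal_", "np_tumor_"),
                      function(b, p) paste0(p, b)))),
    "argmax_mean_label", "argmax_count_label")
}

# mode of probabilities rounded to 2 decimals; ties -> smallest value
prob_mode <- function(v) {
  r <- round(v, 2)
  vals <- sort(unique(r))
  vals[which.max(tabulate(match(r, vals)))]   # first max = smallest value
}

nine_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  va <- mean((v - m)^2)                    # population moment
  c(mean = m, variance = va, std = sqrt(va), median = stats::median(v),
    mode = prob_mode(v), min = min(v), max = max(v),
    range = max(v) - min(v), sum = sum(v))
}

#' Extract the 36 heatmap features
#'
#' Computes the full feature vector of a malignant-probability heatmap
#' over its counted cells. Background cells are excluded by default (set
#' `include_background = TRUE` to keep them). Class labels are encoded
#' 0 = normal, 1 = tumor; the two winner features break ties toward tumor.
#'
#' @param heatmap A `probability_heatmap`, or a list of them.
#' @param include_background Count background-flagged cells too.
#' @return Tibble with `slide_id`, `n_cells`, and the 36 feature columns of
#'   [heatmap_feature_names()] (one row per heatmap).
#' @examples
#' hm <- assemble_heatmap(
#'   tibble::tibble(slide_id = "s", x = c(0, 64), y = c(0, 0),
#'                  p_tumor = c(0.2, 0.97), p_normal = c(0.8, 0.03)),
#'   width = 128, height = 64, patch_size = 64)
#' extract_features(hm)
#' @export
extract_features <- function(heatmap, include_background = FALSE) {
  if (!inherits(heatmap, "probability_heatmap") && is.list(heatmap)) {
    return(dplyr::bind_rows(lapply(heatmap, extract_features,
                                   include_background = include_background)))
  }
  stopifnot(inherits(heatmap, "probability_heatmap"))
  keep <- if (include_background) rep(TRUE, length(heatmap$p_tumor)) else
    !as.logical(heatmap$background)
  pn <- as.numeric(heatmap$p_normal)[keep]
  pt <- as.numeric(heatmap$p_tumor)[keep]
  if (length(pt) == 0L) {
    stop("heatmap ", heatmap$slide_id,
         " has zero counted cells after background exclusion", call. = FALSE)
  }
  sn <- nine_stats(pn)
  st <- nine_stats(pt)
  bn <- tabulate(band_of(pn), nbins = 8L)
  bt <- tabulate(band_of(pt), nbins = 8L)
  bands <- as.numeric(rbind(bn, bt))       # per band: normal then tumor
  f35 <- as.numeric(st[["mean"]] >= sn[["mean"]])
  n_tumor_cells <- sum(pt >= pn)           # tie cells credited to tumor
  f36 <- as.numeric(n_tumor_cells >= length(pt) - n_tumor_cells)
  vec <- c(unname(sn), unname(st), bands, f35, f36)
  out <- tibble::as_tibble(as.list(stats::setNames(vec,
                                                   heatmap_feature_names())))
  dplyr::bind_cols(tibble::tibble(slide_id = heatmap$slide_id,
                                  n_cells = length(pt)), out)
}
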