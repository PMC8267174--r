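# Shared fixtures, built in code and memoised for the session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small annotated cohort: 4 slides of 512 px, 128-px patches
small_slides <- function() {
  memo("small_slides", lapply(1:4, function(s) {
    generate_slide(512, 512, if (s %% 2 == 1) 1L else 0L, seed = s,
                   patch_size = 128)
  }))
}

small_pool <- function() {
  memo("small_pool", {
    pool <- dplyr::bind_rows(lapply(small_slides(), tile_slide,
                                    patch_size = 128))
    pool[pool$label %in% c("normal", "carcinoma"), ]
  })
}

small_manifest <- function() {
  memo("small_manifest",
       build_balanced_manifest(small_pool(),
                               target = c(training = 18, validation = 6,
                                          testing = 6),
                               seed = 5))
}

# a patch classifier trained on the small cohort (shared across tests)
small_patch_model <- function() {
  memo("small_patch_model", {
    m <- build_classifier(patch_config("small_cnn", seed = 2))
    train_patch_classifier(m, small_manifest(), epochs = 5)
  })
}

# random valid heatmap of given grid size
random_heatmap <- function(rows, cols, seed, slide_id = "hm") {
  set.seed(seed)
  pt <- matrix(runif(rows * cols), rows, cols)
  grid <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  preds <- tibble::tibble(slide_id = slide_id,
                          x = (grid$c - 1L) * 64L, y = (grid$r - 1L) * 64L,
                          p_tumor = pt[cbind(grid$r, grid$c)])
  preds$p_normal <- 1 - preds$p_tumor
  assemble_heatmap(preds, width = cols * 64L, height = rows * 64L,
                   patch_size = 64L)
}

# heatmap with prescribed p_tumor values (row-major fill)
heatmap_from_values <- function(p_tumor_values, rows, cols,
                                slide_id = "hm") {
  grid <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  preds <- tibble::tibble(slide_id = slide_id,
                          x = (grid$c - 1L) * 64L, y = (grid$r - 1L) * 64L,
                          p_tumor = p_tumor_values)
  preds$p_normal <- 1 - preds$p_tumor
  assemble_heatmap(preds, width = cols * 64L, height = rows * 64L,
                   patch_size = 64L)
}
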