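# shared fixture builders; all randomness is locally seeded

random_rgb <- function(h = 16, w = 16, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3, lo, hi), dim = c(h, w, 3)))
}

uniform_rgb <- function(value, h = 16, w = 16) {
  rgb_image(array(value, dim = c(h, w, 3)))
}

random_box <- function(xmax = 100, ymax = 100, min_side = 1) {
  repeat {
    x <- sort(runif(2, 0, xmax)); y <- sort(runif(2, 0, ymax))
    if (x[2] - x[1] >= min_side && y[2] - y[1] >= min_side)
      return(c(x[1], y[1], x[2], y[2]))
  }
}

# One shared smoke-training run (dataset generation, enhancement, 250-epoch
# training) reused by every test that needs a trained miniature detector.
smoke_model_cache <- new.env(parent = emptyenv())

get_smoke_model <- function() {
  if (!is.null(smoke_model_cache$model)) return(smoke_model_cache$model)
  ds_dir <- file.path(tempdir(), "thermoroi-smoke-train")
  unlink(ds_dir, recursive = TRUE)
  manifest <- generate_dataset(200, ds_dir,
                               params = scene_params(width = 160,
                                                     height = 120),
                               seed = 29)
  rp <- retinex_params(); cp <- clahe_params()
  load_split <- function(split) {
    out <- list()
    for (s in manifest$scenes) {
      if (!identical(s$split, split)) next
      img <- read_rgb_image(file.path(ds_dir, "images",
                                      paste0(s$stem, ".png")))
      enh <- enhance_auto(img, rp, cp)
      boxes <- read_annotations(file.path(ds_dir, "labels",
                                          paste0(s$stem, ".txt")),
                                "yolo_txt", image_size = c(160, 120))
      out[[length(out) + 1]] <- list(image = enh$image, boxes = boxes,
                                     stem = s$stem)
    }
    out
  }
  train <- load_split("train")
  test <- load_split("test")
  bank <- load_text_bank()
  weights <- train_tiny_detector(train, bank, epochs = 250, lr = 0.05,
                                 seed = 30)
  unlink(ds_dir, recursive = TRUE)
  smoke_model_cache$model <- list(weights = weights, test = test,
                                  bank = bank)
  smoke_model_cache$model
}

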