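#' Run the full pipeline over a dataset directory
#'
#' For every scene of the requested split: gate-and-enhance the RGB frame,
#' run the detector, then evaluate detections against the annotations and
#' extract ROI temperatures (the within-box maximum of the radiometric
#' map, taken from the highest-scoring detection of each ROI class) for
#' comparison with the planted reference temperatures in the manifest.
#'
#' @param config A `pipeline_config` (see [load_config()]).
#' @param input_dir Dataset directory produced by [generate_dataset()].
#' @param weights A trained `tiny_detector` (or a checkpoint path).
#' @param split Which partition to process (default `"test"`).
#' @return Report list with `n_images`, `detection` (precision, recall,
#'   mAP50, per-class AP), `temperature` (per-ROI error statistics on
#'   TMax) and `skipped`.
#' @export
pipeline_run <- function(config, input_dir, weights, split = "test") {
  if (is.character(weights)) weights <- load_detector(weights)
  manifest_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in ", input_dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  gts <- read_annotations(file.path(input_dir, "annotations.json"),
                          format = "coco_json")
  scenes <- Filter(function(s) identical(s$split, split), manifest$scenes)
  if (length(scenes) == 0L)
    stop("no scenes in split '", split, "'", call. = FALSE)
  rp <- retinex_params(config$enhancement$mu_init,
                       config$enhancement$alpha_reg,
                       config$enhancement$beta_reg,
                       config$enhancement$gamma_pen,
                       config$enhancement$lambda_pen,
                       config$enhancement$stages, config$enhancement$omega)
  cp <- clahe_params(config$enhancement$clip_limit,
                     config$enhancement$grid_rows,
                     config$enhancement$grid_cols, config$enhancement$bins)
  dets <- NULL
  skipped <- character(0)
  extracted <- list()
  for (s in scenes) {
    img_path <- file.path(input_dir, "images", paste0(s$stem, ".png"))
    th_path <- file.path(input_dir, "thermal", paste0(s$stem, ".tif"))
    if (!file.exists(img_path) || !file.exists(th_path)) {
      warning("missing pair for ", s$stem, "; skipped", call. = FALSE)
      skipped <- c(skipped, s$stem)
      next
    }
    enh <- enhance_auto(read_rgb_image(img_path), rp, cp,
                        config$enhancement$t_low, config$enhancement$t_high)
    d <- tiny_detector_forward(enh$image, weights)
    if (nrow(d) > 0) {
      d$image <- paste0(s$stem, ".png")
      dets <- rbind(dets, d[, c("image", "category", "score",
                                "x1", "y1", "x2", "y2")])
    }
    thermal <- read_radiometric(th_path)
    for (cl in config$eval$classes) {
      ref <- s$planted[[cl]]
      if (is.null(ref)) next
      dc <- d[d$category == cl, , drop = FALSE]
      if (nrow(dc) == 0) next
      best <- dc[which.max(dc$score), ]
      roi <- extract_roi_temperatures(
        thermal, c(best$x1, best$y1, best$x2, best$y2))
      extracted[[cl]] <- rbind(extracted[[cl]],
                               c(extracted = roi$t_max, reference = ref))
    }
  }
  if (is.null(dets))
    dets <- data.frame(image = character(0), category = character(0),
                       score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0))
  keep_imgs <- vapply(scenes, function(s) paste0(s$stem, ".png"),
                      character(1))
  det_report <- evaluate_detections(dets,
                                    gts[gts$image %in% keep_imgs, ,
                                        drop = FALSE],
                                    classes = config$eval$classes,
                                    iou_thr = config$eval$iou_thr)
  temp_report <- lapply(extracted, function(mat)
    temperature_errors(mat[, 1], mat[, 2]))
  list(n_images = length(scenes) - length(skipped),
       detection = det_report, temperature = temp_report,
       skipped = skipped)
}
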