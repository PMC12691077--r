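#' Read an RGB image from PNG or JPEG
#'
#' @param path File path (`.png` only; the package writes PNG).
#' @return An `rgb_image` with values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(array(px * 255, dim = dim(px)))
}

#' Write an RGB image as PNG
#'
#' @param img An `rgb_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  px <- as_pixel_array(img) / 255
  png::writePNG(pmax(pmin(px, 1), 0), path)
  invisible(path)
}

#' Read a radiometric temperature map
#'
#' Accepts a 32-bit float TIFF or a headerless CSV grid with one row per
#' pixel row.  TIFF values are stored normalized to the instrument
#' measurement range \[-20, 250\] degC (float TIFF readers expect
#' \[0, 1\] data); the mapping is inverted on read and resolves better
#' than 1e-4 degC.  CSV grids hold plain degC values.
#'
#' @param path `.tif`/`.tiff` or `.csv` file.
#' @return H x W numeric matrix in degC.
#' @export
read_radiometric <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    return(m * 270 - 20)
  }
  if (ext == "csv") {
    return(as.matrix(utils::read.csv(path, header = FALSE)))
  }
  stop("unsupported radiometric format: ", ext, call. = FALSE)
}

#' Write a radiometric temperature map
#'
#' @param temps H x W matrix in degC (within the instrument range
#'   \[-20, 250\] for TIFF output).
#' @param path `.tif`/`.tiff` (32-bit float, range-normalized; see
#'   [read_radiometric()]) or `.csv` output path.
#' @return `path`, invisibly.
#' @export
write_radiometric <- function(temps, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (min(temps) < -20 || max(temps) > 250)
      stop("TIFF storage covers the instrument range [-20, 250] degC",
           call. = FALSE)
    tiff::writeTIFF((temps + 20) / 270, path, bits.per.sample = 32L,
                    reduce = FALSE)
  } else if (ext == "csv") {
    utils::write.table(temps, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported radiometric format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read box annotations
#'
#' Supports normalized YOLO text files (`class cx cy w h`, one box per
#' line, class ids 0-based into `categories`) and COCO-style JSON
#' (absolute `bbox = [x, y, w, h]`).  Boxes are returned in the package's
#' corner format.
#'
#' @param path Annotation file.
#' @param format `"yolo_txt"` or `"coco_json"`.
#' @param image_size `c(width, height)` in pixels; required for YOLO.
#' @param categories Category names in class-id order (default: the five
#'   bank categories).
#' @return For YOLO, a data frame `category, x1, y1, x2, y2`; for COCO, a
#'   data frame with an additional leading `image` column (the file_name).
#' @export
read_annotations <- function(path, format = c("yolo_txt", "coco_json"),
                             image_size = NULL,
                             categories = TEXT_CATEGORIES) {
  format <- match.arg(format)
  if (format == "yolo_txt") {
    if (is.null(image_size))
      stop("`image_size` is required for YOLO annotations", call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- data.frame(category = character(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    for (ln in seq_along(lines)) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]),
                                                "[[:space:]]+")[[1]]))
      if (length(f) != 5L || anyNA(f))
        stop(sprintf("malformed YOLO line %d in %s", ln, path), call. = FALSE)
      cls <- f[1] + 1
      if (cls < 1 || cls > length(categories) || cls != round(cls))
        stop(sprintf("unknown class id on line %d in %s", ln, path),
             call. = FALSE)
      W <- image_size[1]; H <- image_size[2]
      out[nrow(out) + 1L, ] <- list(categories[cls],
                                    (f[2] - f[4] / 2) * W,
                                    (f[3] - f[5] / 2) * H,
                                    (f[2] + f[4] / 2) * W,
                                    (f[3] + f[5] / 2) * H)
    }
    return(out)
  }
  coco <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  cat_names <- vapply(coco$categories, function(x) as.character(x$name),
                      character(1))
  cat_ids <- vapply(coco$categories, function(x) as.integer(x$id), integer(1))
  img_names <- stats::setNames(
    vapply(coco$images, function(x) as.character(x$file_name), character(1)),
    vapply(coco$images, function(x) as.character(x$id), character(1)))
  n <- length(coco$annotations)
  out <- data.frame(image = character(n), category = character(n),
                    x1 = numeric(n), y1 = numeric(n),
                    x2 = numeric(n), y2 = numeric(n))
  for (i in seq_len(n)) {
    a <- coco$annotations[[i]]
    b <- as.numeric(a$bbox)
    if (length(b) != 4L || anyNA(b))
      stop(sprintf("malformed bbox in annotation record %d", i), call. = FALSE)
    out$image[i] <- img_names[[as.character(a$image_id)]]
    out$category[i] <- cat_names[match(a$category_id, cat_ids)]
    out$x1[i] <- b[1]; out$y1[i] <- b[2]
    out$x2[i] <- b[1] + b[3]; out$y2[i] <- b[2] + b[4]
  }
  out
}

#' Write box annotations
#'
#' @param boxes Data frame `category, x1, y1, x2, y2` (plus `image` for
#'   COCO output, defaulting to a single unnamed image).
#' @inheritParams read_annotations
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path,
                              format = c("yolo_txt", "coco_json"),
                              image_size = NULL,
                              categories = TEXT_CATEGORIES) {
  format <- match.arg(format)
  if (format == "yolo_txt") {
    if (is.null(image_size))
      stop("`image_size` is required for YOLO annotations", call. = FALSE)
    W <- image_size[1]; H <- image_size[2]
    lines <- vapply(seq_len(nrow(boxes)), function(i) {
      cls <- match(boxes$category[i], categories) - 1L
      if (is.na(cls)) stop("category not in `categories`: ",
                           boxes$category[i], call. = FALSE)
      sprintf("%d %.10g %.10g %.10g %.10g", cls,
              (boxes$x1[i] + boxes$x2[i]) / 2 / W,
              (boxes$y1[i] + boxes$y2[i]) / 2 / H,
              (boxes$x2[i] - boxes$x1[i]) / W,
              (boxes$y2[i] - boxes$y1[i]) / H)
    }, character(1))
    writeLines(lines, path)
    return(invisible(path))
  }
  imgs <- if ("image" %in% names(boxes)) boxes$image else
    rep("image_0001.png", nrow(boxes))
  uimg <- unique(imgs)
  coco <- list(
    images = lapply(seq_along(uimg), function(i)
      c(list(id = i, file_name = uimg[i]),
        if (!is.null(image_size)) list(width = image_size[1],
                                       height = image_size[2]))),
    annotations = lapply(seq_len(nrow(boxes)), function(i)
      list(id = i, image_id = match(imgs[i], uimg),
           category_id = match(boxes$category[i], categories),
           bbox = c(boxes$x1[i], boxes$y1[i],
                    boxes$x2[i] - boxes$x1[i], boxes$y2[i] - boxes$y1[i]))),
    categories = lapply(seq_along(categories), function(k)
      list(id = k, name = categories[k])))
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
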