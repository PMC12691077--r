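#' Synthetic cow-scene generation
#'
#' Seeded generator of paired RGB + radiometric fixtures that emulate the
#' study conditions: black-and-white patched cow bodies seen from the rear
#' or the side, five annotated anatomical regions whose layout follows the
#' text-bank descriptions, three illumination regimes, and a per-animal
#' temperature gradient in which the rectal reference is warmest, the
#' perianal surface (AA) next and the lower udder (LU) coolest.
#'
#' @name synthetic_data
NULL

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

# separable Gaussian blur with border renormalization
gauss_blur <- function(m, sigma) {
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Scene generator parameters
#'
#' Temperature defaults follow the field ranges for lactating cows: LU in
#' \[35.2, 37.5\] degC and AA in \[36.9, 38.5\] degC, with background,
#' general body surface, LU and AA ranges strictly ordered.  Region
#' temperatures are coupled through a per-animal rectal temperature (RT
#' about 38.7 +/- 0.35 degC) from which AA and LU fall by about 1.3 and
#' 2.3 degC, so the RT > AA > LU gradient holds by construction.
#'
#' @param width,height Image size in pixels (default 640 x 480, the
#'   native RGB resolution of a handheld thermographic camera).
#' @param regime Target illumination regime: `"low"`, `"normal"` or
#'   `"over"`.
#' @param view `"side"`, `"rear"` or `"random"`.
#' @param texture_scale Gaussian smoothing radius (pixels) of the
#'   black/white patch field; default `max(2, width / 40)`.
#' @param noise_sd Pixel noise of the radiometric map in degC
#'   (default 0.1).
#' @param bg_temp,body_temp,lu_temp,aa_temp Temperature ranges in degC.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(width = 640L, height = 480L, regime = "normal",
                         view = "random", texture_scale = NULL,
                         noise_sd = 0.1,
                         bg_temp = c(16, 22), body_temp = c(30, 34),
                         lu_temp = c(35.2, 37.5), aa_temp = c(36.9, 38.5),
                         seed = 1L) {
  if (width < 32 || height < 32)
    stop("scene must be at least 32 x 32", call. = FALSE)
  regime <- match.arg(regime, c("low", "normal", "over"))
  view <- match.arg(view, c("side", "rear", "random"))
  if (is.null(texture_scale)) texture_scale <- max(2, width / 40)
  ordered <- bg_temp[2] < body_temp[1] && body_temp[2] < lu_temp[1] &&
    lu_temp[1] < aa_temp[1]
  if (!ordered)
    stop("temperature ranges must be ordered background < body < LU < AA",
         call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 regime = regime, view = view,
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 bg_temp = bg_temp, body_temp = body_temp,
                 lu_temp = lu_temp, aa_temp = aa_temp,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# pixel rows/cols whose centres fall in the half-open box (shared with
# extract_roi_temperatures so painted regions and extraction agree exactly)
box_pixel_range <- function(box, h, w) {
  list(rows = which(seq_len(h) - 0.5 >= box[2] & seq_len(h) - 0.5 < box[4]),
       cols = which(seq_len(w) - 0.5 >= box[1] & seq_len(w) - 0.5 < box[3]))
}

# centre/size (fractions) to an absolute corner box, clipped to the image
frac_box <- function(cx, cy, bw, bh, W, H) {
  c(x1 = max(0, (cx - bw / 2) * W), y1 = max(0, (cy - bh / 2) * H),
    x2 = min(W, (cx + bw / 2) * W), y2 = min(H, (cy + bh / 2) * H))
}

scene_layout <- function(view, W, H) {
  j <- function(s) stats::runif(1, -s, s)
  sc <- stats::runif(1, 0.9, 1.1)
  if (view == "rear") {
    aa <- frac_box(0.50 + j(0.02), 0.33 + j(0.02), 0.14 * sc, 0.14 * sc, W, H)
    ru <- frac_box(0.50 + j(0.02), 0.55 + j(0.02), 0.18 * sc, 0.18 * sc, W, H)
    ll <- frac_box(0.32 + j(0.015), 0.62 + j(0.02), 0.10, 0.30, W, H)
    lr <- frac_box(0.68 + j(0.015), 0.62 + j(0.02), 0.10, 0.30, W, H)
    inner <- rbind(aa, ru, ll, lr)
    hq <- c(max(0, min(inner[, 1]) - 0.04 * W),
            max(0, min(inner[, 2]) - 0.04 * H),
            min(W, max(inner[, 3]) + 0.04 * W),
            min(H, max(inner[, 4]) + 0.04 * H))
    boxes <- data.frame(
      category = c("AA", "RU", "hind_legs", "hind_legs", "hind_quarters"),
      rbind(aa, ru, ll, lr, hq), row.names = NULL)
  } else {
    leg <- frac_box(0.60 + j(0.02), 0.62 + j(0.02), 0.10, 0.30, W, H)
    lu <- frac_box(0.47 + j(0.015), 0.70 + j(0.015), 0.16 * sc, 0.14 * sc, W, H)
    inner <- rbind(leg, lu)
    hq <- c(max(0, min(inner[, 1]) - 0.05 * W),
            max(0, min(inner[, 2]) - 0.05 * H),
            min(W, max(inner[, 3]) + 0.05 * W),
            min(H, max(inner[, 4]) + 0.05 * H))
    boxes <- data.frame(
      category = c("LU", "hind_legs", "hind_quarters"),
      rbind(lu, leg, hq), row.names = NULL)
  }
  names(boxes) <- c("category", "x1", "y1", "x2", "y2")
  boxes
}

# region fill colours (normalized RGB): distinct, consistent signatures so
# a miniature detection head can learn the anatomy from colour + layout
REGION_COLOURS <- list(
  LU = c(0.94, 0.56, 0.62),          # pink udder skin
  AA = c(0.48, 0.24, 0.20),          # dark perianal skin
  RU = c(0.82, 0.66, 0.58),          # lighter udder skin
  hind_legs = c(0.28, 0.26, 0.25))   # dark limbs

#' Generate one synthetic scene
#'
#' Renders the cow body as an ellipse of thresholded smoothed-noise
#' black/white patches, paints each annotated region with its colour
#' signature, rescales the global luminance until the requested
#' illumination regime band is hit, and builds the co-registered
#' radiometric map by assigning each region its planted temperature plus
#' Gaussian pixel noise.  Fully deterministic given `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return List with `image` (`rgb_image`), `thermal` (H x W degC
#'   matrix) and `annotation` (list with `boxes`, `view`, `regime`,
#'   `planted` temperatures, `rt`, `seed`).
#' @export
generate_scene <- function(params = scene_params()) {
  with_seed(params$seed, {
    W <- params$width; H <- params$height
    view <- if (params$view == "random")
      sample(c("side", "rear"), 1) else params$view

    # --- per-animal temperature draws first, so two scenes built from the
    # same seed but different views describe the same animal
    rt <- stats::rnorm(1, 38.7, 0.35)
    clamp <- function(x, r) min(max(x, r[1]), r[2])
    aa_t <- clamp(rt - 1.3 + stats::rnorm(1, 0, 0.2), params$aa_temp)
    lu_t <- clamp(rt - 2.3 + stats::rnorm(1, 0, 0.2), params$lu_temp)
    body_t <- stats::runif(1, params$body_temp[1], params$body_temp[2])
    bg_t <- stats::runif(1, params$bg_temp[1], params$bg_temp[2])

    boxes <- scene_layout(view, W, H)

    # --- RGB rendering (normalized [0,1], column = x, row = y)
    base <- 0.55 + matrix(stats::rnorm(H * W, 0, 0.02), H, W)
    px <- array(0, dim = c(H, W, 3))
    px[, , 1] <- base * 1.02; px[, , 2] <- base; px[, , 3] <- base * 0.93
    cx0 <- (0.5 + stats::runif(1, -0.02, 0.02)) * W
    cy0 <- (0.48 + stats::runif(1, -0.02, 0.02)) * H
    rx <- 0.40 * W; ry <- 0.31 * H
    xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
    ys <- matrix(seq_len(H) - 0.5, H, W)
    body <- ((xs - cx0) / rx)^2 + ((ys - cy0) / ry)^2 <= 1
    patch <- gauss_blur(matrix(stats::rnorm(H * W), H, W),
                        params$texture_scale) > 0
    white <- c(0.93, 0.92, 0.90); black <- c(0.10, 0.10, 0.12)
    for (k in 1:3) {
      ch <- px[, , k]
      ch[body] <- ifelse(patch[body], white[k], black[k])
      px[, , k] <- ch
    }
    for (i in seq_len(nrow(boxes))) {
      cat_i <- boxes$category[i]
      col <- REGION_COLOURS[[cat_i]]
      if (is.null(col)) next  # hind_quarters is a frame, not a fill
      rng <- box_pixel_range(as.numeric(boxes[i, 2:5]), H, W)
      for (k in 1:3)
        px[rng$rows, rng$cols, k] <- col[k] +
          matrix(stats::rnorm(length(rng$rows) * length(rng$cols), 0, 0.015),
                 length(rng$rows), length(rng$cols))
    }
    px <- pmax(pmin(px, 1), 0)

    # --- luminance rescaling into the requested regime band
    target <- switch(params$regime, low = 40, normal = 105, over = 175)
    band_ok <- function(mu) switch(params$regime,
                                   low = mu < 60,
                                   normal = mu >= 60 && mu < 150,
                                   over = mu >= 150)
    f <- target / max(mean_luminance(rgb_to_gray(px * 255)), 1e-6)
    img255 <- NULL
    for (attempt in 1:15) {
      img255 <- pmax(pmin(px * 255 * f, 255), 0)
      mu <- mean_luminance(rgb_to_gray(img255))
      if (band_ok(mu)) break
      f <- f * target / max(mu, 1e-6)
      img255 <- NULL
    }
    if (is.null(img255))
      stop("could not reach the requested illumination regime", call. = FALSE)
    img <- rgb_image(array(img255, dim = c(H, W, 3)))

    # --- radiometric map with the per-animal coupled temperature gradient
    leg_t <- body_t - 2
    ru_t <- body_t + 1.5
    temps <- matrix(bg_t, H, W)
    temps[body] <- body_t
    planted <- list(RT = rt, body = body_t, background = bg_t)
    region_temp <- c(hind_legs = leg_t, RU = ru_t, AA = aa_t, LU = lu_t)
    for (cat_i in names(region_temp)) {
      rows_i <- which(boxes$category == cat_i)
      for (i in rows_i) {
        rng <- box_pixel_range(as.numeric(boxes[i, 2:5]), H, W)
        temps[rng$rows, rng$cols] <- region_temp[[cat_i]]
      }
      if (length(rows_i) > 0 && cat_i %in% c("AA", "LU"))
        planted[[cat_i]] <- region_temp[[cat_i]]
    }
    if (params$noise_sd > 0)
      temps <- temps + matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W)
    temps <- pmax(pmin(temps, 250), -20)

    list(image = img, thermal = temps,
         annotation = list(boxes = boxes, view = view,
                           regime = params$regime, planted = planted,
                           rt = rt, seed = params$seed))
  })
}

# deterministic per-scene seed below 2^31
derive_seed <- function(seed, i) {
  ((as.numeric(seed) * 131071 + i * 7919) %% 2147483629) + 1
}

#' Generate a dataset directory of synthetic scenes
#'
#' Writes PNG images, float TIFF radiometric maps, YOLO-format label
#' files, a COCO-style annotation JSON and a manifest recording every
#' per-scene seed so the dataset can be regenerated exactly.  Scenes are
#' split into train/validation/test partitions (default 6:2:2) and the
#' illumination regimes follow the requested mixture to within rounding.
#'
#' @param n Number of scenes (>= 5).
#' @param out_dir Output directory (created if needed).
#' @param params A [scene_params()] template; per-scene seed, regime and
#'   view are filled in by the generator.
#' @param split Named proportions for train/val/test (default
#'   `c(train = .6, val = .2, test = .2)`).
#' @param regimes Named mixture over `low`, `normal`, `over`.
#' @param seed Master seed.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
generate_dataset <- function(n, out_dir, params = scene_params(),
                             split = c(train = 0.6, val = 0.2, test = 0.2),
                             regimes = c(low = 0.33, normal = 0.34,
                                         over = 0.33),
                             seed = 1L) {
  if (n < 5) stop("`n` must be >= 5", call. = FALSE)
  for (d in file.path(out_dir, c("images", "thermal", "labels")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  # regime counts by largest remainder, shuffled deterministically
  want <- regimes / sum(regimes) * n
  cnt <- floor(want)
  rest <- order(-(want - cnt))
  k <- n - sum(cnt)
  if (k > 0) cnt[rest[seq_len(k)]] <- cnt[rest[seq_len(k)]] + 1
  regime_vec <- rep(names(cnt), cnt)
  regime_vec <- with_seed(seed, sample(regime_vec))
  # exact 50/50 side/rear mixture unless the template pins a view
  view_vec <- if (params$view == "random")
    with_seed(seed + 1, sample(rep(c("side", "rear"), length.out = n)))
  else rep(params$view, n)
  # split counts: remainder goes to train, then val
  ns <- floor(split / sum(split) * n)
  left <- n - sum(ns)
  for (nm in c("train", "val", "test")) {
    if (left == 0) break
    ns[nm] <- ns[nm] + 1; left <- left - 1
  }
  split_vec <- rep(names(ns), ns)

  bank_order <- TEXT_CATEGORIES
  records <- vector("list", n)
  coco_images <- vector("list", n)
  coco_anns <- list()
  ann_id <- 0L
  for (i in seq_len(n)) {
    p_i <- params
    p_i$seed <- derive_seed(seed, i)
    p_i$regime <- regime_vec[i]
    p_i$view <- view_vec[i]
    scn <- generate_scene(p_i)
    stem <- sprintf("scene_%04d", i)
    png_path <- file.path(out_dir, "images", paste0(stem, ".png"))
    write_rgb_image(scn$image, png_path)
    tif_path <- file.path(out_dir, "thermal", paste0(stem, ".tif"))
    write_radiometric(scn$thermal, tif_path)
    write_annotations(scn$annotation$boxes,
                      file.path(out_dir, "labels", paste0(stem, ".txt")),
                      format = "yolo_txt",
                      image_size = c(p_i$width, p_i$height),
                      categories = bank_order)
    coco_images[[i]] <- list(id = i, file_name = paste0(stem, ".png"),
                             width = p_i$width, height = p_i$height)
    bx <- scn$annotation$boxes
    for (r in seq_len(nrow(bx))) {
      ann_id <- ann_id + 1L
      coco_anns[[ann_id]] <- list(
        id = ann_id, image_id = i,
        category_id = match(bx$category[r], bank_order),
        bbox = c(bx$x1[r], bx$y1[r], bx$x2[r] - bx$x1[r], bx$y2[r] - bx$y1[r]))
    }
    records[[i]] <- list(stem = stem, seed = p_i$seed, regime = p_i$regime,
                         view = scn$annotation$view, split = split_vec[i],
                         planted = scn$annotation$planted)
  }
  coco <- list(
    images = coco_images,
    annotations = coco_anns,
    categories = lapply(seq_along(bank_order), function(k)
      list(id = k, name = bank_order[k])))
  jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(n = n, seed = seed,
                   width = params$width, height = params$height,
                   noise_sd = params$noise_sd,
                   regimes = as.list(regimes), split = as.list(split),
                   scenes = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a rectal/surface temperature table
#'
#' Emulates a per-animal temperature table: rectal temperature RT around
#' 38.7 +/- 0.35 degC, the perianal surface AA at RT minus about 1.3 degC
#' and the lower udder LU at RT minus about 2.3 degC, each with
#' independent measurement noise, so RT > AA > LU holds for essentially
#' every animal at moderate noise.  Optional extra sites are only weakly
#' coupled to RT, for exercising correlation-based ROI selection.
#'
#' @param n_cows Number of animals (>= 3).
#' @param delta_aa,delta_lu Mean offsets below RT in degC.
#' @param noise_sd Measurement noise sd in degC (default 0.2).
#' @param rt_mean,rt_sd RT distribution parameters.
#' @param extra_sites Character vector of additional, weakly correlated
#'   site names (e.g. `c("FH", "NE")`).
#' @param seed Integer seed.
#' @return Data frame with columns `cow_id`, `RT`, `LU`, `AA` and any
#'   extra sites.
#' @export
generate_temperature_table <- function(n_cows = 10L, delta_aa = 1.3,
                                       delta_lu = 2.3, noise_sd = 0.2,
                                       rt_mean = 38.7, rt_sd = 0.35,
                                       extra_sites = character(0),
                                       seed = 1L) {
  if (n_cows < 3) stop("`n_cows` must be >= 3", call. = FALSE)
  with_seed(seed, {
    rt <- round(stats::rnorm(n_cows, rt_mean, rt_sd), 1)
    tab <- data.frame(
      cow_id = sprintf("Cow %d", seq_len(n_cows)),
      RT = rt,
      LU = round(rt - delta_lu + stats::rnorm(n_cows, 0, noise_sd), 1),
      AA = round(rt - delta_aa + stats::rnorm(n_cows, 0, noise_sd), 1))
    for (site in extra_sites)
      tab[[site]] <- round(34 + 0.15 * (rt - rt_mean) +
                             stats::rnorm(n_cows, 0, 0.8), 1)
    tab
  })
}
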