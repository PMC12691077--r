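#' CLAHE parameters
#'
#' @param clip_limit Contrast limit as a multiple of the uniform bin count
#'   (default 3.0); the per-tile clip count is
#'   `ceiling(clip_limit * tile_pixels / bins)`.
#' @param grid_rows,grid_cols Tile grid dimensions (default 8 x 8).
#' @param bins Histogram bins over the 8-bit range (default 256).
#' @return A list of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 3.0, grid_rows = 8L, grid_cols = 8L,
                         bins = 256L) {
  if (clip_limit < 1) stop("`clip_limit` must be >= 1", call. = FALSE)
  if (grid_rows < 1 || grid_cols < 1)
    stop("grid dimensions must be >= 1", call. = FALSE)
  if (bins < 2) stop("`bins` must be >= 2", call. = FALSE)
  structure(list(clip_limit = clip_limit, grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), bins = as.integer(bins)),
            class = "clahe_params")
}

#' Clip a histogram and redistribute the excess
#'
#' Caps every bin at `clip_count` and spreads the removed mass uniformly
#' over all bins; the integer remainder goes one count each to the
#' lowest-index bins.  Redistribution is repeated until no bin exceeds the
#' cap (with any final remainder placed deterministically in the
#' lowest-index bins that still have capacity), so the total mass is
#' conserved exactly and the cap holds whenever `sum(hist) <= bins *
#' clip_count`.
#'
#' @param hist Integer vector of non-negative bin counts.
#' @param clip_count Per-bin cap (>= 1).
#' @return Integer vector of the same length with the same sum.
#' @export
clip_redistribute <- function(hist, clip_count) {
  if (clip_count < 1) stop("`clip_count` must be >= 1", call. = FALSE)
  if (any(hist < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  h <- as.numeric(hist)
  nb <- length(h)
  if (sum(h) > nb * clip_count) {
    # infeasible cap: fall back to a flat histogram with remainder in front
    total <- sum(h)
    h <- rep(floor(total / nb), nb)
    r <- total - sum(h)
    if (r > 0) h[seq_len(r)] <- h[seq_len(r)] + 1
    return(as.integer(h))
  }
  repeat {
    excess <- sum(pmax(h - clip_count, 0))
    if (excess == 0) break
    h <- pmin(h, clip_count)
    base <- floor(excess / nb)
    r <- excess - base * nb
    h <- h + base
    if (r > 0) h[seq_len(r)] <- h[seq_len(r)] + 1
    new_excess <- sum(pmax(h - clip_count, 0))
    if (new_excess >= excess) {
      # remainder keeps landing on saturated bins: place it by capacity
      h <- pmin(h, clip_count)
      left <- new_excess
      cap <- clip_count - h
      i <- 1L
      while (left > 0 && i <= nb) {
        take <- min(cap[i], left)
        h[i] <- h[i] + take
        left <- left - take
        i <- i + 1L
      }
      break
    }
  }
  as.integer(round(h))
}

#' Convert between 8-bit RGB and Lab
#'
#' D65 white point; L is rescaled from \[0, 100\] to \[0, 255\] so it can be
#' histogrammed like an 8-bit channel.
#'
#' @param img An `rgb_image` or H x W x 3 array in \[0, 255\].
#' @return For [rgb_to_lab()], a list with matrices `L` (in \[0, 255\]),
#'   `a` and `b`.
#' @export
rgb_to_lab <- function(img) {
  px <- as_pixel_array(img)
  d <- dim(px)
  lab <- grDevices::convertColor(matrix(px / 255, ncol = 3), from = "sRGB",
                                 to = "Lab", scale.in = 1)
  list(L = matrix(lab[, 1] * 255 / 100, d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

#' @rdname rgb_to_lab
#' @param L,a,b Lab component matrices as produced by [rgb_to_lab()].
#' @return For [lab_to_rgb()], an H x W x 3 array in \[0, 255\] (real
#'   valued; quantize with the caller's policy).
#' @export
lab_to_rgb <- function(L, a, b) {
  lab <- cbind(as.vector(L) * 100 / 255, as.vector(a), as.vector(b))
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB",
                                  scale.in = NULL, scale.out = 1)
  array(c(srgb[, 1], srgb[, 2], srgb[, 3]) * 255,
        dim = c(nrow(L), ncol(L), 3))
}

# tile index boundaries: `n` pixels into `k` groups, last group absorbs
# the remainder
tile_breaks <- function(n, k) {
  base <- n %/% k
  starts <- (0:(k - 1)) * base + 1L
  ends <- c(starts[-1] - 1L, n)
  cbind(start = starts, end = ends)
}

# per-axis bilinear interpolation setup between tile centres; returns for
# each pixel the lower/upper tile index and the weight of the lower tile
axis_weights <- function(n, brk) {
  centres <- (brk[, "start"] - 1 + brk[, "end"]) / 2
  pos <- seq_len(n) - 0.5
  k <- nrow(brk)
  lo <- findInterval(pos, centres)           # 0 .. k
  lo_cl <- pmin(pmax(lo, 1L), k - (k > 1))   # clamp for interpolation
  hi <- pmin(lo_cl + 1L, k)
  w_lo <- rep(1, n)
  if (k > 1) {
    span <- centres[hi] - centres[lo_cl]
    inside <- lo >= 1 & lo < k & span > 0
    w_lo[inside] <- (centres[hi][inside] - pos[inside]) / span[inside]
    w_lo[lo >= k] <- 1
    lo_cl[lo >= k] <- k
    hi[lo >= k] <- k
    w_lo[lo < 1] <- 1
    lo_cl[lo < 1] <- 1L
    hi[lo < 1] <- 1L
  }
  list(lo = lo_cl, hi = hi, w_lo = w_lo)
}

#' Contrast-limited adaptive histogram equalization of a luminance channel
#'
#' Splits the channel into a tile grid, builds a clipped-and-redistributed
#' histogram per tile, maps each tile's normalized CDF to 0-255, and blends
#' every pixel bilinearly between the mappings of its (up to) four
#' neighbouring tiles, with weights derived from the distances to the tile
#' centres.  Weights are non-negative and sum to one; pixels outside the
#' outermost tile centres fall back to the edge tile's mapping.
#'
#' @param L Luminance matrix with values in \[0, 255\].
#' @param params A [clahe_params()] object.
#' @return Equalized luminance matrix in \[0, 255\].
#' @export
clahe_luminance <- function(L, params = clahe_params()) {
  h <- nrow(L); w <- ncol(L)
  gr <- params$grid_rows; gc <- params$grid_cols; nb <- params$bins
  if (gr > h || gc > w)
    stop("tile grid larger than the image", call. = FALSE)
  rbrk <- tile_breaks(h, gr)
  cbrk <- tile_breaks(w, gc)
  bin_of <- pmin(pmax(floor(L * nb / 256), 0), nb - 1)  # 0-based bin index
  lut <- array(0, dim = c(gr, gc, nb))
  for (ti in seq_len(gr)) {
    for (tj in seq_len(gc)) {
      bins_tile <- bin_of[rbrk[ti, 1]:rbrk[ti, 2], cbrk[tj, 1]:cbrk[tj, 2]]
      n_tile <- length(bins_tile)
      hist <- tabulate(as.vector(bins_tile) + 1L, nbins = nb)
      clip_count <- ceiling(params$clip_limit * n_tile / nb)
      hist <- clip_redistribute(hist, clip_count)
      lut[ti, tj, ] <- round(cumsum(hist) / n_tile * 255)
    }
  }
  rw <- axis_weights(h, rbrk)
  cw <- axis_weights(w, cbrk)
  bin1 <- as.vector(bin_of) + 1L
  ri <- rep(seq_len(h), times = w)
  ci <- rep(seq_len(w), each = h)
  out <- rw$w_lo[ri] * cw$w_lo[ci] * lut[cbind(rw$lo[ri], cw$lo[ci], bin1)] +
    rw$w_lo[ri] * (1 - cw$w_lo[ci]) * lut[cbind(rw$lo[ri], cw$hi[ci], bin1)] +
    (1 - rw$w_lo[ri]) * cw$w_lo[ci] * lut[cbind(rw$hi[ri], cw$lo[ci], bin1)] +
    (1 - rw$w_lo[ri]) * (1 - cw$w_lo[ci]) * lut[cbind(rw$hi[ri], cw$hi[ci], bin1)]
  matrix(out, h, w)
}

#' Enhance an overexposed image with CLAHE
#'
#' Converts to Lab, equalizes the L channel with [clahe_luminance()], and
#' recombines with the untouched a and b chrominance channels before
#' converting back to RGB.
#'
#' @param img An `rgb_image` (assumed already gated as overexposed).
#' @param params A [clahe_params()] object.
#' @return Enhanced `rgb_image`.
#' @export
enhance_overexposed <- function(img, params = clahe_params()) {
  lab <- rgb_to_lab(img)
  L2 <- clahe_luminance(lab$L, params)
  finalize_rgb(lab_to_rgb(L2, lab$a, lab$b))
}

#' Illumination-adaptive enhancement
#'
#' Gates the image by mean luminance and applies the matching path:
#' Retinex decomposition for low light, CLAHE on the Lab luminance for
#' overexposure, identity for normal light.
#'
#' @param img An `rgb_image`.
#' @param retinex A [retinex_params()] object.
#' @param clahe A [clahe_params()] object.
#' @param t_low,t_high Gate thresholds (defaults 60 and 150).
#' @return A list with `image` (the enhanced `rgb_image`) and `label`
#'   (the `illumination_label` that drove the routing).
#' @export
enhance_auto <- function(img, retinex = retinex_params(),
                         clahe = clahe_params(), t_low = 60, t_high = 150) {
  mu <- mean_luminance(rgb_to_gray(img))
  label <- classify_illumination(mu, t_low, t_high)
  out <- switch(label$label,
                low_light = enhance_lowlight(img, retinex),
                overexposed = enhance_overexposed(img, clahe),
                normal_light = img)
  list(image = out, label = label)
}
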