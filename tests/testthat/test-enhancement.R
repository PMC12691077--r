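test_that("grayscale conversion uses the BT.601 weights and stays real-valued", {
  expect_equal(rgb_to_gray(uniform_rgb(255, 2, 2))[1, 1], 255)
  green <- rgb_image(array(rep(c(0, 255, 0), each = 4), dim = c(2, 2, 3)))
  expect_equal(rgb_to_gray(green)[1, 1], 0.587 * 255)
  # brute-force per-pixel oracle
  img <- random_rgb(16, 16, seed = 42)
  g <- rgb_to_gray(img)
  px <- unclass(img)
  for (i in c(1, 7, 16)) for (j in c(1, 9, 16))
    expect_equal(g[i, j],
                 0.299 * px[i, j, 1] + 0.587 * px[i, j, 2] + 0.114 * px[i, j, 3])
  expect_error(rgb_to_gray(array(0, dim = c(2, 2, 2))), "RGB")
})

test_that("mean luminance is the plain pixel average", {
  expect_equal(mean_luminance(matrix(100, 5, 5)), 100)
  expect_equal(mean_luminance(matrix(c(0, 255), 1, 2)), 127.5)
  set.seed(3)
  m <- matrix(runif(64, 0, 255), 8, 8)
  acc <- 0
  for (v in m) acc <- acc + v
  expect_equal(mean_luminance(m), acc / 64)
  expect_error(mean_luminance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("illumination gate thresholds and exhaustiveness", {
  expect_equal(classify_illumination(59.9)$label, "low_light")
  expect_equal(classify_illumination(150)$label, "overexposed")
  expect_equal(classify_illumination(100)$label, "normal_light")
  expect_equal(classify_illumination(60)$label, "normal_light")
  for (mu in seq(0, 255, by = 0.5)) {
    lab <- classify_illumination(mu)$label
    expect_true(lab %in% c("low_light", "normal_light", "overexposed"))
    expected <- if (mu < 60) "low_light" else if (mu >= 150) "overexposed"
                else "normal_light"
    expect_identical(lab, expected)
  }
  expect_error(classify_illumination(100, t_low = 200, t_high = 150), "t_low")
})

test_that("Retinex initialization reconstructs the input", {
  u <- array(0.5, dim = c(8, 8, 3))
  d <- retinex_init(u)
  expect_equal(d$illumination, matrix(0.5, 8, 8))
  expect_true(all(abs(d$reflectance - 1) < 1e-12))
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 0.8
  d2 <- retinex_init(red)
  expect_equal(d2$illumination[1, 1], 0.8)
  expect_equal(d2$reflectance[1, 1, ], c(1, 0, 0))
  set.seed(9)
  img <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
  d3 <- retinex_init(img)
  recon <- d3$reflectance * as.vector(d3$illumination)
  mask <- d3$illumination > 1e-4
  expect_lt(max(abs((recon - img)[rep(mask, 3)])), 1e-6)
})

test_that("Retinex unfolding does not increase the energy and T=0 is identity", {
  set.seed(21)
  img <- array(runif(14 * 12 * 3, 0, 0.4), dim = c(14, 12, 3))
  p0 <- retinex_params(stages = 0)
  init <- retinex_init(img, p0)
  expect_identical(retinex_unfold(init, img, p0)[1:2], init[1:2])
  p <- retinex_params(stages = 4)
  for (s in 1:10) {
    set.seed(100 + s)
    im <- array(runif(10 * 10 * 3), dim = c(10, 10, 3))
    dec <- retinex_unfold(retinex_init(im, p), im, p)
    e <- attr(dec, "energy")
    expect_length(e, 5)
    expect_true(all(diff(e) <= 1e-8 * pmax(abs(e[-length(e)]), 1) + 1e-12))
  }
  # uniform image: illumination stays uniform (no gradients to penalize)
  u <- array(0.3, dim = c(8, 8, 3))
  pu <- retinex_params(stages = 3)
  du <- retinex_unfold(retinex_init(u, pu), u, pu)
  expect_lt(diff(range(du$illumination)), 1e-9)
})

test_that("illumination adjustment is a monotone gamma map", {
  expect_equal(adjust_illumination(matrix(1, 2, 2), 0.7), matrix(1, 2, 2))
  expect_equal(adjust_illumination(matrix(0.25, 1, 1), 0.5), matrix(0.5, 1, 1))
  set.seed(5)
  a <- matrix(runif(50, 0.01, 1), 5, 10)
  b <- pmin(a + runif(50, 0, 0.5), 1)
  expect_true(all(adjust_illumination(a, 0.5) <= adjust_illumination(b, 0.5)))
  expect_error(adjust_illumination(a, 0), "omega")
})

test_that("low-light enhancement brightens dim scenes and stays 8-bit", {
  set.seed(2)
  dim_img <- rgb_image(array(runif(20 * 20 * 3, 0, 110), dim = c(20, 20, 3)))
  mu_in <- mean_luminance(rgb_to_gray(dim_img))
  expect_lt(mu_in, 60)
  out <- enhance_lowlight(dim_img)
  expect_gt(mean_luminance(rgb_to_gray(out)), mu_in)
  expect_true(all(out >= 0 & out <= 255))
  # an already-bright image passes through almost unchanged
  bright <- rgb_image(array(runif(16 * 16 * 3, 230, 255), dim = c(16, 16, 3)))
  out_b <- enhance_lowlight(bright, retinex_params(omega = 1))
  expect_lt(mean(abs(unclass(out_b) - unclass(bright))), 12)
})

test_that("histogram clipping conserves mass and caps every bin", {
  h <- c(3L, 5L, 2L, 0L, 4L)
  expect_identical(clip_redistribute(h, 10), h)
  set.seed(8)
  for (i in 1:50) {
    hist <- as.integer(rpois(64, 30))
    clip <- max(ceiling(sum(hist) / 64), sample(20:60, 1))
    out <- clip_redistribute(hist, clip)
    expect_identical(sum(out), sum(hist))
    if (sum(hist) <= 64 * clip) expect_true(all(out <= clip))
  }
  # single spike: hand-computed redistribution
  spike <- c(100L, 0L, 0L, 0L)
  out <- clip_redistribute(spike, 40)
  # 60 excess -> +15 each -> spike capped at 40, then remaining excess 15
  # goes to the bins with capacity
  expect_identical(sum(out), 100L)
  expect_true(all(out <= 40L))
  expect_error(clip_redistribute(h, 0), "clip_count")
})

test_that("CLAHE keeps constant images constant and chroma untouched", {
  const <- uniform_rgb(180, 32, 32)
  out <- enhance_overexposed(const, clahe_params(grid_rows = 4, grid_cols = 4))
  expect_length(unique(as.vector(unclass(out))[1:1024]), 1)
  # the overexposure path equals CLAHE-on-L recombined with the original a,b
  img <- random_rgb(40, 48, seed = 12, lo = 120, hi = 255)
  p <- clahe_params(grid_rows = 4, grid_cols = 4)
  lab <- rgb_to_lab(img)
  manual <- lab_to_rgb(clahe_luminance(lab$L, p), lab$a, lab$b)
  manual <- rgb_image(array(pmin(255, pmax(0, round(manual))), dim = dim(manual)))
  expect_equal(unclass(enhance_overexposed(img, p)), unclass(manual))
  expect_error(clahe_luminance(matrix(1, 4, 4), clahe_params(grid_rows = 8)),
               "grid")
})

test_that("bilinear tile weights are a partition of unity", {
  brk <- thermoroi:::tile_breaks(37, 4)
  expect_equal(unname(brk[1, "start"]), 1)
  expect_equal(unname(brk[4, "end"]), 37)   # last tile absorbs the remainder
  aw <- thermoroi:::axis_weights(37, brk)
  expect_true(all(aw$w_lo >= 0 & aw$w_lo <= 1))
  # at an interior tile centre the tile's own mapping has weight 1
  centres <- (brk[, "start"] - 1 + brk[, "end"]) / 2
  pos <- seq_len(37) - 0.5
  at_centre <- which(abs(pos - centres[2]) < 1e-9)
  if (length(at_centre) == 1) expect_equal(aw$w_lo[at_centre], 1)
  expect_lt(max(abs(aw$w_lo + (1 - aw$w_lo) - 1)), 1e-12)
})

test_that("grid (1,1) with unbounded clip reduces to global equalization", {
  img <- random_rgb(24, 30, seed = 77, lo = 100, hi = 255)
  L <- rgb_to_lab(img)$L
  got <- clahe_luminance(L, clahe_params(clip_limit = 1e9, grid_rows = 1,
                                         grid_cols = 1))
  # independent global histogram-equalization oracle
  bins <- pmin(pmax(floor(L), 0), 255)
  cdf <- cumsum(tabulate(as.vector(bins) + 1L, nbins = 256)) / length(L)
  lut <- round(cdf * 255)
  want <- matrix(lut[as.vector(bins) + 1L], nrow(L), ncol(L))
  expect_equal(got, want)
})

test_that("the dual-path router picks the regime-matched enhancer", {
  r <- enhance_auto(uniform_rgb(100, 20, 20))
  expect_equal(r$label$label, "normal_light")
  expect_identical(unclass(r$image), unclass(uniform_rgb(100, 20, 20)))
  dim_scene <- generate_scene(scene_params(width = 96, height = 72,
                                           regime = "low", seed = 31))
  r_low <- enhance_auto(dim_scene$image)
  expect_equal(r_low$label$label, "low_light")
  expect_gt(mean_luminance(rgb_to_gray(r_low$image)),
            r_low$label$mean_luminance)
  bright_scene <- generate_scene(scene_params(width = 96, height = 72,
                                              regime = "over", seed = 32))
  r_over <- enhance_auto(bright_scene$image)
  expect_equal(r_over$label$label, "overexposed")
  expect_false(identical(unclass(r_over$image), unclass(bright_scene$image)))
})
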