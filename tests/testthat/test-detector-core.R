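test_that("joint attention matches a brute-force broadcast product", {
  X0 <- array(0, dim = c(1, 3, 4, 4))
  expect_equal(spatial_channel_attention(X0), X0)   # sigmoid(0)=0.5, X=0
  set.seed(11)
  X <- array(rnorm(2 * 5 * 3 * 4), dim = c(2, 5, 3, 4))
  got <- spatial_channel_attention(X)
  expect_identical(dim(got), dim(X))
  sig <- function(x) 1 / (1 + exp(-x))
  for (b in 1:2) for (ci in 1:5) for (h in 1:3) for (w in 1:4) {
    a_s <- sig(mean(X[b, , h, w]))
    a_c <- sig(mean(X[b, ci, , ]))
    expect_equal(got[b, ci, h, w], X[b, ci, h, w] * a_s * a_c)
  }
})

test_that("text modulation applies the scale/shift arithmetic exactly", {
  set.seed(12)
  Xp <- array(rnorm(1 * 4 * 3 * 3), dim = c(1, 4, 3, 3))
  ident <- list(gs = 1, gb = 0, cs = rep(1, 4), cb = rep(0, 4))
  expect_equal(edc_modulate(Xp, ident), Xp)
  shift <- list(gs = 0, gb = 0, cs = rep(1, 4), cb = c(1, 2, 3, 4))
  got <- edc_modulate(Xp, shift)
  for (ci in 1:4) expect_true(all(got[1, ci, , ] == ci))
  mod <- list(gs = 2, gb = 0.5, cs = c(1, -1, 0.5, 2), cb = c(0, 1, 0, -1))
  got2 <- edc_modulate(Xp, mod)
  for (ci in 1:4) for (h in 1:3) for (w in 1:3)
    expect_equal(got2[1, ci, h, w],
                 Xp[1, ci, h, w] * 2 * mod$cs[ci] + 0.5 + mod$cb[ci])
  expect_error(edc_modulate(Xp, list(gs = 1, gb = 0, cs = 1:3, cb = 1:3)),
               "channel")
})

test_that("EDC block is the exact identity at zero initialization", {
  bank <- load_text_bank()
  pooled <- encode_text(bank[[2]], 32, 0)$pooled
  params <- edc_params_init(32, 6, seed = 5)
  set.seed(13)
  X <- array(runif(2 * 6 * 5 * 4, -10, 10), dim = c(2, 6, 5, 4))
  Y <- edc_forward(X, pooled, params)
  expect_identical(Y, X)
  # with non-zero modulation the output differs but stays finite, and the
  # pre-GELU normalized tensor has per-position mean 0, variance ~1
  params$w2 <- matrix(0.3, nrow(params$w2), ncol(params$w2))
  params$b2 <- seq(-0.5, 0.5, length.out = length(params$b2))
  Y2 <- edc_forward(X, pooled, params)
  expect_false(identical(Y2, X))
  expect_true(all(is.finite(Y2)))
  mod <- edc_modulation(params, pooled)
  Xm <- matrix(X[1, , , ], nrow = 6)
  Z <- thermoroi:::layer_norm_core(thermoroi:::edc_modulate_core(
    thermoroi:::sca_core(Xm), mod))
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_true(all(abs(colMeans(Z^2) - 1) < 0.05))
})

test_that("fast-normalized fusion is a convex combination", {
  A <- array(1, dim = c(1, 2, 3, 3)); B <- array(3, dim = c(1, 2, 3, 3))
  expect_equal(db_fuse(list(A, B), fusion_node(c(1, 1), epsilon = 0)),
               array(2, dim = dim(A)))
  near_first <- db_fuse(list(A, B), fusion_node(c(1, 0), epsilon = 1e-4))
  expect_lt(max(abs(near_first - A)), 1e-3)
  set.seed(14)
  ins <- lapply(1:3, function(i) array(rnorm(2 * 2 * 4), dim = c(1, 2, 2, 4)))
  w <- runif(3)
  out <- db_fuse(ins, fusion_node(w, epsilon = 1e-4))
  lo <- pmin(pmin(ins[[1]], ins[[2]]), ins[[3]])
  hi <- pmax(pmax(ins[[1]], ins[[2]]), ins[[3]])
  slack <- 1e-4 / (1e-4 + sum(w)) * max(abs(hi))
  expect_true(all(out >= lo - slack - 1e-9 & out <= hi + slack + 1e-9))
  # normalized weights sum below 1, approaching 1 as epsilon vanishes
  expect_lt(sum(pmax(w, 0) / (1e-4 + sum(w))), 1)
  expect_equal(sum(pmax(w, 0) / (0 + sum(w))), 1)
  expect_error(db_fuse(list(A, array(0, dim = c(1, 2, 3, 2))),
                       fusion_node(c(1, 1))), "shape")
})

test_that("detector forward is deterministic, confidence = max class score", {
  sc <- generate_scene(scene_params(width = 96, height = 72,
                                    regime = "normal", seed = 41))
  bank <- load_text_bank()
  w <- tiny_detector_init(bank, dim = 32, stride = 4, seed = 2)
  d1 <- tiny_detector_forward(sc$image, w, score_thr = 0.01)
  d2 <- tiny_detector_forward(sc$image, w, score_thr = 0.01)
  expect_identical(d1, d2)
  raw <- attr(d1, "raw")
  expect_equal(apply(raw$scores, 2, max),
               apply(raw$scores, 2, function(s) confidence(s)))
  if (nrow(d1) > 0) expect_true(all(d1$confidence >= d1$score - 1e-12))
})

test_that("changing the text bank changes scores but not boxes", {
  sc <- generate_scene(scene_params(width = 96, height = 72,
                                    regime = "normal", seed = 42))
  bank <- load_text_bank()
  w5 <- tiny_detector_init(bank, dim = 32, stride = 4, seed = 2)
  w2 <- tiny_detector_init(subset_text_bank(bank, c("LU", "AA")),
                           dim = 32, stride = 4, seed = 2)
  # give the EDC a non-zero modulation so the text path is active
  w5$edc$w2[] <- 0.1; w2$edc$w2[] <- 0.1
  r5 <- attr(tiny_detector_forward(sc$image, w5, score_thr = 0.01), "raw")
  r2 <- attr(tiny_detector_forward(sc$image, w2, score_thr = 0.01), "raw")
  expect_identical(r5$boxes, r2$boxes)       # geometry is text-independent
  expect_false(identical(r5$scores[1:2, ], r2$scores))
})

test_that("forward ops preserve shapes over randomized dims", {
  set.seed(15)
  for (i in 1:5) {
    d <- as.integer(c(1, sample(2:6, 1), sample(2:5, 1), sample(2:5, 1)))
    X <- array(rnorm(prod(d)), dim = d)
    expect_identical(dim(spatial_channel_attention(X)), d)
    pooled <- encode_text(load_text_bank()[[1]], 32, 0)$pooled
    p <- edc_params_init(32, d[2], seed = i)
    expect_identical(dim(edc_forward(X, pooled, p)), d)
    expect_identical(dim(db_fuse(list(X, X), fusion_node(c(2, 1)))), d)
  }
})
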