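test_that("ROI extraction matches an exhaustive pixel scan", {
  u <- matrix(35, 10, 10)
  r <- extract_roi_temperatures(u, c(2, 2, 8, 8))
  expect_equal(c(r$t_max, r$t_min, r$t_avg), c(35, 35, 35))
  m <- matrix(c(35, 36, 37), 1, 3)
  r2 <- extract_roi_temperatures(m, c(0, 0, 3, 1))
  expect_equal(c(r2$t_max, r2$t_min, r2$t_avg, r2$n_pixels), c(37, 35, 36, 3))
  set.seed(301)
  for (i in 1:1000) {
    h <- sample(4:20, 1); w <- sample(4:20, 1)
    temps <- matrix(runif(h * w, 20, 40), h, w)
    box <- c(sort(runif(2, 0, w)), sort(runif(2, 0, h)))[c(1, 3, 2, 4)]
    rows <- which(seq_len(h) - 0.5 >= box[2] & seq_len(h) - 0.5 < box[4])
    cols <- which(seq_len(w) - 0.5 >= box[1] & seq_len(w) - 0.5 < box[3])
    if (length(rows) == 0 || length(cols) == 0 ||
        box[1] >= box[3] || box[2] >= box[4]) next
    vals <- c()
    for (rr in rows) for (cc in cols) vals <- c(vals, temps[rr, cc])
    got <- extract_roi_temperatures(temps, box)
    expect_equal(got$t_max, max(vals))
    expect_equal(got$t_min, min(vals))
    expect_equal(got$t_avg, mean(vals))
    expect_equal(got$n_pixels, length(vals))
  }
  expect_error(extract_roi_temperatures(u, c(20, 20, 21, 21)), "pixel centre")
})

test_that("temperature error statistics are absolute with a signed secondary", {
  e <- temperature_errors(c(36.5, 36.7), c(36.5, 36.7))
  expect_equal(c(e$max_error, e$min_error, e$mean_error), c(0, 0, 0))
  e2 <- temperature_errors(c(36.4, 36.7), c(36.5, 36.7))
  expect_equal(c(e2$max_error, e2$min_error, e2$mean_error), c(0.1, 0, 0.05))
  expect_equal(e2$signed_mean_error, -0.05)
  set.seed(302)
  a <- runif(20, 30, 40); b <- runif(20, 30, 40)
  got <- temperature_errors(a, b)
  errs <- c(); for (i in 1:20) errs <- c(errs, abs(a[i] - b[i]))
  expect_equal(got$max_error, max(errs))
  expect_equal(got$mean_error, mean(errs))
  expect_true(got$min_error <= got$mean_error &&
                got$mean_error <= got$max_error)
  expect_error(temperature_errors(1:3, 1:2), "equal length")
})

test_that("Spearman matrix has unit diagonal and handles reversals and ties", {
  tab <- data.frame(RT = c(38, 38.5, 39, 39.5), X = c(1, 2, 3, 4),
                    Y = c(4, 3, 2, 1))
  m <- spearman_matrix(tab)
  expect_equal(diag(m), c(RT = 1, X = 1, Y = 1))
  expect_equal(m["RT", "X"], 1)
  expect_equal(m["RT", "Y"], -1)
  expect_equal(m, t(m))
  expect_warning(spearman_matrix(data.frame(A = 1:4, B = rep(2, 4))),
                 "constant")
})

test_that("Spearman on the bundled ten-cow table matches a rank-then-Pearson oracle", {
  tab <- utils::read.csv(system.file("extdata", "cow_temperatures_example.csv",
                                     package = "thermoroi"))
  m <- spearman_matrix(tab)
  oracle <- function(x, y) {
    rk <- function(v) {
      r <- numeric(length(v))
      for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 +
                                         sum(v <= v[i])) / 2
      r
    }
    rx <- rk(x); ry <- rk(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(m["RT", "AA"], oracle(tab$RT, tab$AA), tolerance = 1e-12)
  expect_equal(m["RT", "LU"], oracle(tab$RT, tab$LU), tolerance = 1e-12)
  expect_gt(m["RT", "AA"], 0.7)   # both ROIs track the rectal reference
  expect_gt(m["RT", "LU"], 0.7)
  # invariance under a strictly monotone transform of a column
  tab2 <- tab
  tab2$AA <- exp(tab2$AA / 5)
  expect_equal(spearman_matrix(tab2)["RT", "AA"], m["RT", "AA"])
})

test_that("ROI selection recovers a planted correlation ordering", {
  tab <- generate_temperature_table(400, noise_sd = 0.15,
                                    extra_sites = c("FH", "NE", "AD"),
                                    seed = 11)
  m <- spearman_matrix(tab)
  expect_identical(sort(select_rois(m, "RT", 2)), c("AA", "LU"))
  expect_length(select_rois(m, "RT", 1), 1)
  expect_error(select_rois(m, "RT", 10), "exceeds")
  expect_error(select_rois(m, "XX", 1), "not in the matrix")
})

test_that("generated temperature tables honour the RT > AA > LU gradient", {
  tab <- generate_temperature_table(10, noise_sd = 0.05, seed = 2)
  expect_true(all(tab$RT > tab$AA))
  expect_true(all(tab$AA > tab$LU))
  expect_identical(tab, generate_temperature_table(10, noise_sd = 0.05,
                                                   seed = 2))
  big <- generate_temperature_table(1000, extra_sites = "FH", seed = 3)
  m <- spearman_matrix(big)
  expect_gt(m["RT", "AA"], m["RT", "FH"])
})

test_that("extracted TMax preserves the AA > LU gradient across paired views", {
  ok <- 0; n <- 40
  for (i in seq_len(n)) {
    pr <- scene_params(width = 96, height = 72, regime = "normal",
                       view = "rear", seed = 7000 + i)
    ps <- pr; ps$view <- "side"
    rear <- generate_scene(pr); side <- generate_scene(ps)
    expect_equal(rear$annotation$rt, side$annotation$rt)  # same animal
    baa <- rear$annotation$boxes
    baa <- as.numeric(baa[baa$category == "AA", 2:5])
    blu <- side$annotation$boxes
    blu <- as.numeric(blu[blu$category == "LU", 2:5])
    t_aa <- extract_roi_temperatures(rear$thermal, baa)$t_max
    t_lu <- extract_roi_temperatures(side$thermal, blu)$t_max
    if (t_aa > t_lu) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("noise-free scenes return the planted temperature exactly", {
  sc <- generate_scene(scene_params(width = 96, height = 72, view = "rear",
                                    regime = "normal", noise_sd = 0,
                                    seed = 99))
  b <- sc$annotation$boxes
  aa <- as.numeric(b[b$category == "AA", 2:5])
  expect_identical(extract_roi_temperatures(sc$thermal, aa)$t_max,
                   sc$annotation$planted$AA)
})
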