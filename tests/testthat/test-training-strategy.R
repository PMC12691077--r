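test_that("IoU family matches analytic anchors", {
  b <- c(0, 0, 2, 2)
  expect_equal(box_iou(b, b), 1)
  expect_equal(box_giou(b, b), 1)
  expect_equal(box_ciou(b, b), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_giou(c(0, 0, 1, 1), c(2, 0, 3, 1)), -1 / 3)
  # concentric, equal aspect ratio: CIoU collapses to IoU
  expect_equal(box_ciou(c(0, 0, 4, 4), c(1, 1, 3, 3)),
               box_iou(c(0, 0, 4, 4), c(1, 1, 3, 3)))
  expect_error(box_iou(c(0, 0, 0, 1), b), "degenerate")
})

test_that("IoU family agrees with independent implementations and is ordered", {
  set.seed(101)
  for (i in 1:2000) {
    a <- random_box(); b <- random_box()
    expect_equal(box_iou(a, b), iou_oracle(a, b), tolerance = 1e-12)
    expect_equal(box_giou(a, b), giou_oracle(a, b), tolerance = 1e-12)
    expect_equal(box_ciou(a, b), ciou_oracle(a, b), tolerance = 1e-12)
    expect_lte(box_giou(a, b), box_iou(a, b) + 1e-12)
    expect_lte(box_ciou(a, b), box_iou(a, b) + 1e-12)
  }
})

test_that("hybrid loss reduces to its components and is bounded", {
  b <- c(1, 1, 4, 5)
  expect_equal(hybrid_iou_loss(b, b, 0.3), 0)
  set.seed(102)
  for (i in 1:200) {
    a <- random_box(); g <- random_box()
    expect_equal(hybrid_iou_loss(a, g, 1), 1 - box_ciou(a, g))
    expect_equal(hybrid_iou_loss(a, g, 0), 1 - box_giou(a, g))
    lam <- runif(1)
    l <- hybrid_iou_loss(a, g, lam)
    expect_gte(l, 0)
    expect_lt(l, 2)
  }
  expect_error(hybrid_iou_loss(b, b, 1.5), "lambda")
})

test_that("hybrid loss decreases under gradient descent back to the target", {
  set.seed(103)
  ok <- 0
  for (trial in 1:100) {
    gt <- random_box(min_side = 5)
    box <- gt + rnorm(4, 0, 2)
    if (box[1] >= box[3]) box[c(1, 3)] <- sort(box[c(1, 3)]) + c(-1, 1)
    if (box[2] >= box[4]) box[c(2, 4)] <- sort(box[c(2, 4)]) + c(-1, 1)
    l0 <- hybrid_iou_loss(box, gt)
    for (step in 1:25) {
      g <- thermoroi:::hybrid_loss_box_grad(box, gt, 0.5)
      box <- box - 0.5 * g
    }
    if (hybrid_iou_loss(box, gt) < l0 - 1e-6 || l0 < 1e-9) ok <- ok + 1
  }
  expect_equal(ok, 100)
})

test_that("task alignment score follows p^alpha u^beta and is monotone", {
  expect_equal(task_alignment_score(1, 1), 1)
  expect_equal(task_alignment_score(0.5, 0.5, alpha = 1, beta = 1), 0.25)
  grid <- seq(0, 1, by = 0.1)
  for (a in c(0.5, 1, 2)) for (b in c(1, 3, 6)) {
    v <- outer(grid, grid, function(p, u) task_alignment_score(p, u, a, b))
    expect_true(all(diff(v) >= -1e-12))          # monotone in p
    expect_true(all(t(diff(t(v))) >= -1e-12))    # monotone in u
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(task_alignment_score(-0.1, 0.5), "non-negative")
})

test_that("Gaussian centre weight peaks at the centre and decays", {
  gt <- c(0, 0, 10, 10)
  expect_equal(gaussian_center_weight(c(5, 5), gt), 1)
  # at normalized distance sigma the weight is exp(-1)
  half_diag <- sqrt(200) / 2
  sig <- 0.5
  d_px <- sig * half_diag
  expect_equal(gaussian_center_weight(c(5 + d_px, 5), gt, sigma = sig),
               exp(-1))
  ds <- seq(0, 8, by = 0.5)
  w <- vapply(ds, function(d) gaussian_center_weight(c(5 + d, 5), gt, 0.5),
              numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(gaussian_center_weight(c(0, 0), gt, sigma = 0), "sigma")
})


test_that("assignment handles the canonical easy cases", {
  gt <- matrix(c(10, 10, 30, 30), 1, 4)
  anchors <- matrix(c(20, 20), 1, 2)
  scores <- matrix(1, 1, 1)
  pb <- gt
  a <- assign_targets(anchors, gt, scores, pb)
  expect_identical(a$assigned_gt, 1L)
  # two far-apart targets with one anchor at each centre: no cross talk
  gts <- rbind(c(0, 0, 10, 10), c(200, 200, 220, 220))
  anchors2 <- rbind(c(5, 5), c(210, 210))
  pb2 <- rbind(c(1, 1, 9, 9), c(202, 202, 218, 218))
  sc2 <- matrix(0.9, 2, 2)
  a2 <- assign_targets(anchors2, gts, sc2, pb2)
  expect_identical(a2$assigned_gt, c(1L, 2L))
  # empty ground truth is a valid, empty assignment
  a3 <- assign_targets(anchors, NULL, matrix(0, 1, 0),
                       matrix(c(0, 0, 1, 1), 1, 4))
  expect_true(all(is.na(a3$assigned_gt)))
})

test_that("assignment matches the brute-force oracle on random instances", {
  set.seed(104)
  ap <- assigner_params(alpha = 1, beta = 6, sigma = 0.5, topk = 3)
  for (trial in 1:1000) {
    n <- sample(1:8, 1); m <- sample(1:3, 1)
    anchors <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    gts <- t(vapply(seq_len(m), function(j) random_box(50, 50, 2),
                    numeric(4)))
    scores <- matrix(runif(n * m), n, m)
    pboxes <- t(vapply(seq_len(n), function(i) {
      c(anchors[i, 1] - runif(1, 1, 6), anchors[i, 2] - runif(1, 1, 6),
        anchors[i, 1] + runif(1, 1, 6), anchors[i, 2] + runif(1, 1, 6))
    }, numeric(4)))
    got <- assign_targets(anchors, gts, scores, pboxes, ap)$assigned_gt
    want <- assign_oracle(anchors, gts, scores, pboxes, ap)
    expect_identical(got, want)
  }
})

test_that("assignment is deterministic", {
  set.seed(105)
  anchors <- cbind(runif(6, 0, 40), runif(6, 0, 40))
  gts <- rbind(random_box(40, 40, 3), random_box(40, 40, 3))
  scores <- matrix(runif(12), 6, 2)
  pb <- cbind(anchors[, 1] - 3, anchors[, 2] - 3,
              anchors[, 1] + 3, anchors[, 2] + 3)
  a1 <- assign_targets(anchors, gts, scores, pb)
  a2 <- assign_targets(anchors, gts, scores, pb)
  expect_identical(a1, a2)
})

test_that("a miniature head trained with the assigner and hybrid loss recovers boxes", {
  sm <- get_smoke_model()
  w <- sm$weights
  held <- sm$test
  # recovery is judged per ground-truth ROI box: the best IoU any
  # detection of its category achieves against it
  ious <- c()
  for (s in held) {
    d <- tiny_detector_forward(s$image, w)
    gg <- s$boxes[s$boxes$category %in% c("LU", "AA"), , drop = FALSE]
    for (i in seq_len(nrow(gg))) {
      dd <- d[d$category == gg$category[i], , drop = FALSE]
      best <- 0
      if (nrow(dd) > 0)
        best <- max(thermoroi:::iou_matrix(
          as.matrix(dd[, c("x1", "y1", "x2", "y2")]),
          as.matrix(gg[i, c("x1", "y1", "x2", "y2")])))
      ious <- c(ious, best)
    }
  }
  expect_gte(length(ious), 4)
  expect_gte(mean(ious), 0.7)
})
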