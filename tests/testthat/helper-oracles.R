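# independent scalar re-implementations used as oracles ------------------

iou_oracle <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

giou_oracle <- function(a, b) {
  cx1 <- min(a[1], b[1]); cy1 <- min(a[2], b[2])
  cx2 <- max(a[3], b[3]); cy2 <- max(a[4], b[4])
  cc <- (cx2 - cx1) * (cy2 - cy1)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / un - (cc - un) / cc
}

ciou_oracle <- function(a, b) {
  i <- iou_oracle(a, b)
  rho2 <- ((a[1] + a[3]) / 2 - (b[1] + b[3]) / 2)^2 +
    ((a[2] + a[4]) / 2 - (b[2] + b[4]) / 2)^2
  c2 <- (max(a[3], b[3]) - min(a[1], b[1]))^2 +
    (max(a[4], b[4]) - min(a[2], b[2]))^2
  v <- 4 / pi^2 *
    (atan((b[3] - b[1]) / (b[4] - b[2])) -
       atan((a[3] - a[1]) / (a[4] - a[2])))^2
  al <- if (v > 0) v / (1 - i + v) else 0
  i - rho2 / c2 - al * v
}

assign_oracle <- function(anchors, gts, scores, pboxes, ap) {
  n <- nrow(anchors); m <- nrow(gts)
  M <- matrix(0, n, m); U <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    u <- iou_oracle(pboxes[i, ], gts[j, ])
    cx <- (gts[j, 1] + gts[j, 3]) / 2; cy <- (gts[j, 2] + gts[j, 4]) / 2
    hd <- sqrt((gts[j, 3] - gts[j, 1])^2 + (gts[j, 4] - gts[j, 2])^2) / 2
    d <- sqrt((anchors[i, 1] - cx)^2 + (anchors[i, 2] - cy)^2) / hd
    M[i, j] <- scores[i, j]^ap$alpha * u^ap$beta * exp(-d^2 / ap$sigma^2)
    U[i, j] <- u
  }
  cand <- matrix(FALSE, n, m)
  k <- min(ap$topk, n)
  for (j in seq_len(m)) {
    ord <- order(M[, j], decreasing = TRUE)[seq_len(k)]
    for (i in ord) if (M[i, j] > 0) cand[i, j] <- TRUE
  }
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    js <- which(cand[i, ])
    if (length(js) == 0) next
    best <- js[1]
    for (j in js[-1]) {
      if (M[i, j] > M[i, best] ||
          (M[i, j] == M[i, best] && U[i, j] > U[i, best])) best <- j
    }
    out[i] <- best
  }
  out
}
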