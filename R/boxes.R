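#' Bounding boxes
#'
#' Boxes are corner-format `(x1, y1, x2, y2)` in continuous pixel
#' coordinates, origin at the top-left, x to the right, y down; x1 < x2
#' and y1 < y2 are required so the area is strictly positive.
#'
#' @param x1,y1,x2,y2 Box corners.
#' @return Numeric vector `c(x1, y1, x2, y2)` of class `bbox`.
#' @export
bbox <- function(x1, y1, x2, y2) {
  b <- c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  check_bbox(b)
  structure(b, class = "bbox")
}

check_bbox <- function(b) {
  if (length(b) != 4L || anyNA(b))
    stop("a box is four finite numbers (x1, y1, x2, y2)", call. = FALSE)
  if (b[[1]] >= b[[3]] || b[[2]] >= b[[4]])
    stop("degenerate box: need x1 < x2 and y1 < y2", call. = FALSE)
  invisible(b)
}

box_area <- function(b) (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])

#' Intersection over union of two boxes
#'
#' @param a,b Boxes (`bbox` or plain `(x1, y1, x2, y2)` vectors).
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  check_bbox(a); check_bbox(b)
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  inter <- max(iw, 0) * max(ih, 0)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Generalized IoU
#'
#' `IoU - (|C| - |A union B|) / |C|` where C is the smallest enclosing
#' box; penalizes non-overlapping pairs by their enclosing slack.  Range
#' (-1, 1].
#'
#' @inheritParams box_iou
#' @return GIoU value.
#' @export
box_giou <- function(a, b) {
  check_bbox(a); check_bbox(b)
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  inter <- max(iw, 0) * max(ih, 0)
  uni <- box_area(a) + box_area(b) - inter
  cw <- max(a[[3]], b[[3]]) - min(a[[1]], b[[1]])
  ch <- max(a[[4]], b[[4]]) - min(a[[2]], b[[2]])
  encl <- cw * ch
  inter / uni - (encl - uni) / encl
}

#' Complete IoU
#'
#' `IoU - rho^2 / c^2 - alpha v` with rho the distance between the box
#' centres, c the diagonal of the enclosing box, v the squared
#' arctan-scaled aspect-ratio gap `(4 / pi^2) (atan(w_b / h_b) -
#' atan(w_a / h_a))^2`, and `alpha = v / ((1 - IoU) + v)` (alpha taken as 0
#' when v = 0, so concentric boxes of equal aspect ratio give CIoU = IoU).
#'
#' @inheritParams box_iou
#' @return CIoU value.
#' @export
box_ciou <- function(a, b) {
  check_bbox(a); check_bbox(b)
  iou <- box_iou(a, b)
  acx <- (a[[1]] + a[[3]]) / 2; acy <- (a[[2]] + a[[4]]) / 2
  bcx <- (b[[1]] + b[[3]]) / 2; bcy <- (b[[2]] + b[[4]]) / 2
  rho2 <- (acx - bcx)^2 + (acy - bcy)^2
  cw <- max(a[[3]], b[[3]]) - min(a[[1]], b[[1]])
  ch <- max(a[[4]], b[[4]]) - min(a[[2]], b[[2]])
  c2 <- cw^2 + ch^2
  wa <- a[[3]] - a[[1]]; ha <- a[[4]] - a[[2]]
  wb <- b[[3]] - b[[1]]; hb <- b[[4]] - b[[2]]
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- if (v > 0) v / ((1 - iou) + v) else 0
  iou - rho2 / c2 - alpha * v
}

#' Hybrid CIoU/GIoU regression loss
#'
#' The regression objective blends the two IoU generalizations,
#' `lambda * CIoU + (1 - lambda) * GIoU`; since that blend is a similarity
#' (1 for a perfect box), the minimized loss is its complement
#' `1 - (lambda CIoU + (1 - lambda) GIoU)`, which is 0 exactly when the
#' boxes coincide.
#'
#' @inheritParams box_iou
#' @param lambda_mix Mixing weight in \[0, 1\]; 1 gives pure `1 - CIoU`,
#'   0 pure `1 - GIoU`.  Default 0.5.
#' @return Non-negative loss value (< 2).
#' @export
hybrid_iou_loss <- function(a, b, lambda_mix = 0.5) {
  if (lambda_mix < 0 || lambda_mix > 1)
    stop("`lambda_mix` must lie in [0, 1]", call. = FALSE)
  1 - (lambda_mix * box_ciou(a, b) + (1 - lambda_mix) * box_giou(a, b))
}

# row-paired vectorized IoU family: A[i, ] against B[i, ]
pair_iou_parts <- function(A, B) {
  iw <- pmax(pmin(A[, 3], B[, 3]) - pmax(A[, 1], B[, 1]), 0)
  ih <- pmax(pmin(A[, 4], B[, 4]) - pmax(A[, 2], B[, 2]), 0)
  inter <- iw * ih
  uni <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  list(iou = inter / uni, uni = uni)
}

pair_hybrid_loss <- function(A, B, lambda_mix = 0.5) {
  p <- pair_iou_parts(A, B)
  cw <- pmax(A[, 3], B[, 3]) - pmin(A[, 1], B[, 1])
  ch <- pmax(A[, 4], B[, 4]) - pmin(A[, 2], B[, 2])
  encl <- cw * ch
  giou <- p$iou - (encl - p$uni) / encl
  rho2 <- ((A[, 1] + A[, 3]) / 2 - (B[, 1] + B[, 3]) / 2)^2 +
    ((A[, 2] + A[, 4]) / 2 - (B[, 2] + B[, 4]) / 2)^2
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) *
    (atan((B[, 3] - B[, 1]) / (B[, 4] - B[, 2])) -
       atan((A[, 3] - A[, 1]) / (A[, 4] - A[, 2])))^2
  alpha <- ifelse(v > 0, v / ((1 - p$iou) + v), 0)
  ciou <- p$iou - rho2 / c2 - alpha * v
  1 - (lambda_mix * ciou + (1 - lambda_mix) * giou)
}

# vectorized IoU between every row of A (n x 4) and every row of B (m x 4)
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  x1 <- pmax(matrix(A[, 1], n, m), matrix(B[, 1], n, m, byrow = TRUE))
  y1 <- pmax(matrix(A[, 2], n, m), matrix(B[, 2], n, m, byrow = TRUE))
  x2 <- pmin(matrix(A[, 3], n, m), matrix(B[, 3], n, m, byrow = TRUE))
  y2 <- pmin(matrix(A[, 4], n, m), matrix(B[, 4], n, m, byrow = TRUE))
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  area_a <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  area_b <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (matrix(area_a, n, m) + matrix(area_b, n, m, byrow = TRUE) - inter)
}
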