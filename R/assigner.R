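#' Assigner hyper-parameters
#'
#' @param alpha,beta Exponents of the task-alignment metric
#'   `p_cls^alpha * IoU^beta` (defaults 1 and 6, the task-aligned
#'   assignment convention).
#' @param sigma Width of the Gaussian centre-sampling kernel in units of
#'   normalized centre distance (default 0.5).
#' @param topk Positive candidates retained per ground-truth box
#'   (default 10, clipped to the anchor count).
#' @return A list of class `assigner_params`.
#' @export
assigner_params <- function(alpha = 1.0, beta = 6.0, sigma = 0.5,
                            topk = 10L) {
  if (alpha <= 0 || beta <= 0) stop("`alpha`, `beta` must be > 0", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (topk < 1) stop("`topk` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 topk = as.integer(topk)),
            class = "assigner_params")
}

#' Task-alignment score
#'
#' Joint classification/localization quality `p^alpha * u^beta`, monotone
#' non-decreasing in both the classification score `p` and the IoU `u`.
#'
#' @param p_cls Classification score(s) in \[0, 1\].
#' @param iou_val IoU value(s) in \[0, 1\].
#' @param alpha,beta Positive exponents.
#' @return Alignment score(s) in \[0, 1\].
#' @export
task_alignment_score <- function(p_cls, iou_val, alpha = 1.0, beta = 6.0) {
  if (any(p_cls < 0) || any(iou_val < 0))
    stop("scores and IoU must be non-negative", call. = FALSE)
  p_cls^alpha * iou_val^beta
}

#' Gaussian soft-constrained centre weight
#'
#' The anchor-to-target distance is normalized by half the target's
#' diagonal, and the weight is `exp(-d^2 / sigma^2)`: 1 at the centre,
#' decaying smoothly so off-centre anchors can still compete for positive
#' samples when the region is deformed.
#'
#' @param anchor_xy Length-2 `(x, y)` anchor point, or an n x 2 matrix.
#' @param gt Ground-truth box `(x1, y1, x2, y2)`.
#' @param sigma Positive kernel width.
#' @return Centre weight(s) in (0, 1\].
#' @export
gaussian_center_weight <- function(anchor_xy, gt, sigma = 0.5) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  check_bbox(gt)
  pts <- if (is.matrix(anchor_xy)) anchor_xy else matrix(anchor_xy, ncol = 2)
  cx <- (gt[[1]] + gt[[3]]) / 2
  cy <- (gt[[2]] + gt[[4]]) / 2
  half_diag <- sqrt((gt[[3]] - gt[[1]])^2 + (gt[[4]] - gt[[2]])^2) / 2
  d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) / half_diag
  w <- exp(-d^2 / sigma^2)
  if (is.matrix(anchor_xy)) w else w[[1]]
}

#' Task-aligned positive-sample assignment
#'
#' Combines the task-alignment score `A_ij = p_ij^alpha u_ij^beta` with the
#' Gaussian centre weight `w_ij` into the metric `m_ij = A_ij * w_ij`.
#' Each ground-truth box selects its top-k anchors by the metric
#' (candidates with zero metric are never positives); an anchor claimed by
#' several ground truths goes to the one with larger metric, ties broken
#' by larger IoU and then lower ground-truth index.
#'
#' @param anchors n x 2 matrix of anchor points `(x, y)`.
#' @param gts m x 4 matrix of ground-truth boxes (rows `(x1, y1, x2, y2)`),
#'   or a list of boxes; may be empty.
#' @param cls_scores n x m matrix: each anchor's classification score for
#'   the category of each ground truth.
#' @param pred_boxes n x 4 matrix of the anchors' current predicted boxes
#'   (used for the IoU term of the alignment metric).
#' @param params An [assigner_params()] object.
#' @return A list of class `assignment` with `assigned_gt` (length-n
#'   integer vector, `NA` for negatives), and the n x m matrices
#'   `alignment`, `center_weight`, `metric`, `iou`.
#' @export
assign_targets <- function(anchors, gts, cls_scores, pred_boxes,
                           params = assigner_params()) {
  anchors <- if (is.matrix(anchors)) anchors else matrix(anchors, ncol = 2)
  n <- nrow(anchors)
  if (n < 1L) stop("need at least one anchor", call. = FALSE)
  if (is.list(gts) && !is.matrix(gts))
    gts <- do.call(rbind, lapply(gts, as.numeric))
  m <- if (is.null(gts)) 0L else nrow(gts)
  if (m == 0L) {
    return(structure(list(assigned_gt = rep(NA_integer_, n),
                          alignment = matrix(0, n, 0),
                          center_weight = matrix(0, n, 0),
                          metric = matrix(0, n, 0),
                          iou = matrix(0, n, 0)),
                     class = "assignment"))
  }
  u <- iou_matrix(pred_boxes, gts)
  A <- task_alignment_score(cls_scores, u, params$alpha, params$beta)
  W <- vapply(seq_len(m), function(j)
    gaussian_center_weight(anchors, gts[j, ], params$sigma), numeric(n))
  W <- matrix(W, n, m)
  M <- A * W
  k <- min(params$topk, n)
  # candidate sets per ground truth: top-k anchors with positive metric
  claimed <- vector("list", n)
  for (j in seq_len(m)) {
    ord <- order(M[, j], decreasing = TRUE)
    cand <- ord[seq_len(k)]
    cand <- cand[M[cand, j] > 0]
    for (i in cand) claimed[[i]] <- c(claimed[[i]], j)
  }
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    js <- claimed[[i]]
    if (is.null(js)) next
    if (length(js) > 1L) {
      o <- order(-M[i, js], -u[i, js], js)
      js <- js[o]
    }
    assigned[i] <- js[[1]]
  }
  structure(list(assigned_gt = assigned, alignment = A, center_weight = W,
                 metric = M, iou = u),
            class = "assignment")
}
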