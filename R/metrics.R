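#' Match detections to ground truths
#'
#' Greedy matching in descending confidence order: each detection claims
#' the still-unmatched ground truth of its own category with the highest
#' IoU at or above the threshold, otherwise it is a false positive.
#' Each ground truth is matched at most once, so TP + FN equals the number
#' of ground truths.
#'
#' @param dets Data frame with columns `category`, `score`, `x1`, `y1`,
#'   `x2`, `y2` (zero rows allowed).
#' @param gts Data frame with columns `category`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thr IoU threshold (default 0.5).
#' @return A list of class `match_result` with `det_tp` (logical per
#'   detection, in decreasing-score order), `det_order` (row indices of
#'   `dets` in that order), `gt_matched` (logical per ground truth) and
#'   counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  nd <- if (is.null(dets)) 0L else nrow(dets)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  ord <- if (nd > 0) order(-dets$score) else integer(0)
  det_tp <- logical(nd)
  gt_matched <- logical(ng)
  for (pos in seq_len(nd)) {
    i <- ord[pos]
    best_j <- 0L; best_iou <- -1
    if (ng > 0) {
      for (j in seq_len(ng)) {
        if (gt_matched[j] || gts$category[j] != dets$category[i]) next
        v <- box_iou(c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i]),
                     c(gts$x1[j], gts$y1[j], gts$x2[j], gts$y2[j]))
        if (v >= iou_thr && v > best_iou) { best_iou <- v; best_j <- j }
      }
    }
    if (best_j > 0L) { det_tp[pos] <- TRUE; gt_matched[best_j] <- TRUE }
  }
  tp <- sum(det_tp)
  structure(list(det_tp = det_tp, det_order = ord, gt_matched = gt_matched,
                 tp = tp, fp = nd - tp, fn = ng - tp),
            class = "match_result")
}

#' Precision and recall (percent)
#'
#' `P = 100 TP / (TP + FP)` and `R = 100 TP / (TP + FN)`; a zero
#' denominator yields 0 rather than NaN so empty detection sets degrade
#' gracefully.
#'
#' @param m A `match_result` (or any list with `tp`, `fp`, `fn`).
#' @return Named numeric vector `c(precision = , recall = )` in \[0, 100\].
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp > 0) 100 * m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) 100 * m$tp / (m$tp + m$fn) else 0
  c(precision = p, recall = r)
}

#' Average precision from ranked true/false-positive flags
#'
#' All-point interpolation: the precision envelope is made monotone
#' non-increasing from the right and integrated over the recall
#' increments.
#'
#' @param flags Logical vector, TRUE for a true positive, ranked by
#'   decreasing confidence.
#' @param n_gt Number of ground-truth instances of the class.
#' @return AP in \[0, 1\], or `NA_real_` when `n_gt` is 0 (class excluded
#'   from the mean).
#' @export
average_precision <- function(flags, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (length(flags) == 0L) return(0)
  tp_cum <- cumsum(flags)
  prec <- tp_cum / seq_along(flags)
  rec <- tp_cum / n_gt
  prec_env <- rev(cummax(rev(prec)))
  rec_prev <- c(0, rec[-length(rec)])
  sum((rec - rec_prev) * prec_env)
}

#' Mean average precision (percent)
#'
#' @param per_class_ap Numeric vector of per-class AP values in \[0, 1\];
#'   `NA` entries (classes without ground truth) are dropped.
#' @return 100 times the mean of the defined APs.
#' @export
map50 <- function(per_class_ap) {
  ap <- per_class_ap[!is.na(per_class_ap)]
  if (length(ap) == 0L) stop("no class has a defined AP", call. = FALSE)
  100 * mean(ap)
}

#' Detection confidence
#'
#' The confidence of a detection is the maximum of its per-class scores.
#'
#' @param class_scores Numeric vector of per-class scores (K >= 1).
#' @return The maximum score.
#' @export
confidence <- function(class_scores) {
  if (length(class_scores) == 0L)
    stop("need at least one class score", call. = FALSE)
  max(class_scores)
}

#' Evaluate detections over a dataset
#'
#' Pools detections across images, ranks them per class by score, matches
#' greedily within each image at the IoU threshold and reports precision,
#' recall, per-class AP and mAP50.
#'
#' @param dets Data frame with columns `image`, `category`, `score`,
#'   `x1`, `y1`, `x2`, `y2`.
#' @param gts Data frame with columns `image`, `category`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @param classes Character vector of categories to evaluate (default:
#'   all categories present in `gts`).
#' @param iou_thr IoU threshold (default 0.5).
#' @return List with `precision`, `recall`, `map50` (percent) and
#'   `per_class_ap` (named, in \[0, 1\]).
#' @export
evaluate_detections <- function(dets, gts, classes = NULL, iou_thr = 0.5) {
  if (is.null(classes)) classes <- sort(unique(gts$category))
  per_class_ap <- stats::setNames(rep(NA_real_, length(classes)), classes)
  tp <- 0L; fp <- 0L; n_gt_total <- 0L
  for (cl in classes) {
    dc <- dets[dets$category == cl, , drop = FALSE]
    gc_ <- gts[gts$category == cl, , drop = FALSE]
    n_gt <- nrow(gc_)
    n_gt_total <- n_gt_total + n_gt
    if (nrow(dc) == 0L) { per_class_ap[cl] <- average_precision(logical(0), n_gt); next }
    dc <- dc[order(-dc$score), , drop = FALSE]
    matched <- new.env(parent = emptyenv())
    flags <- logical(nrow(dc))
    for (i in seq_len(nrow(dc))) {
      img <- as.character(dc$image[i])
      gi <- which(gc_$image == dc$image[i])
      taken <- if (is.null(matched[[img]])) integer(0) else matched[[img]]
      best_j <- 0L; best_iou <- -1
      for (j in setdiff(gi, taken)) {
        v <- box_iou(c(dc$x1[i], dc$y1[i], dc$x2[i], dc$y2[i]),
                     c(gc_$x1[j], gc_$y1[j], gc_$x2[j], gc_$y2[j]))
        if (v >= iou_thr && v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0L) {
        flags[i] <- TRUE
        matched[[img]] <- c(taken, best_j)
      }
    }
    per_class_ap[cl] <- average_precision(flags, n_gt)
    tp <- tp + sum(flags)
    fp <- fp + sum(!flags)
  }
  pr <- precision_recall(list(tp = tp, fp = fp, fn = n_gt_total - tp))
  list(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       map50 = map50(per_class_ap), per_class_ap = per_class_ap)
}
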