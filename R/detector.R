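#' Miniature text-conditioned detector
#'
#' A deliberately small, CPU-trainable detection head that exercises the
#' full stack end to end: fixed two-scale pooled visual features, a
#' learnable-weight fusion node, EDC text-guided modulation on the
#' classification branch, a per-anchor box regressor, task-aligned
#' assignment with Gaussian centre sampling and the hybrid CIoU/GIoU
#' regression loss.  Per-category scores are the sigmoid of the dot
#' product between each anchor's visual embedding and the category's
#' pooled text embedding, so the class set is defined entirely by the
#' text bank.  The box branch reads the fused features before text
#' modulation, so changing the bank changes scores but never box
#' geometry.
#'
#' @name tiny_detector
NULL

# mean-pool a matrix over s x s cells (image cropped to a whole grid)
pool_cells <- function(m, s) {
  h1 <- nrow(m) %/% s; w1 <- ncol(m) %/% s
  mc <- m[seq_len(h1 * s), seq_len(w1 * s), drop = FALSE]
  r <- rowsum(mc, rep(seq_len(h1), each = s))
  t(rowsum(t(r), rep(seq_len(w1), each = s))) / (s * s)
}

shift_clamp <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# fixed feature extractor at one stride; returns C x N (positions
# column-major: row index fastest) plus the anchor grid.  Directional
# context uses an R-G chroma plane: skin-region boundaries are chroma
# edges, whereas the black/white coat makes luminance context noisy.
extract_scale <- function(px, s) {
  gray <- rgb_to_gray(px) / 255
  chroma <- (px[, , 1] - px[, , 2]) / 255
  h1 <- nrow(gray) %/% s; w1 <- ncol(gray) %/% s
  mR <- pool_cells(px[, , 1] / 255, s)
  mG <- pool_cells(px[, , 2] / 255, s)
  mB <- pool_cells(px[, , 3] / 255, s)
  mGy <- pool_cells(gray, s)
  mCh <- pool_cells(chroma, s)
  vGy <- pmax(pool_cells(gray^2, s) - mGy^2, 0)
  half <- max(1L, s %/% 2L)
  ch_half <- pool_cells(chroma, half)
  q <- function(dr, dc)
    ch_half[cbind(pmin(2 * (seq_len(h1)) - 1 + dr, nrow(ch_half))[
                  rep(seq_len(h1), times = w1)],
                  pmin(2 * (seq_len(w1)) - 1 + dc, ncol(ch_half))[
                  rep(seq_len(w1), each = h1)])]
  cxs <- (seq_len(w1) - 0.5) * s
  cys <- (seq_len(h1) - 0.5) * s
  feat <- rbind(as.vector(mR), as.vector(mG), as.vector(mB),
             as.vector(sqrt(vGy)),
             q(0, 0), q(0, 1), q(1, 0), q(1, 1),
             as.vector(shift_clamp(mCh, -1L, 0L)),
             as.vector(shift_clamp(mCh, 1L, 0L)),
             as.vector(shift_clamp(mCh, 0L, -1L)),
             as.vector(shift_clamp(mCh, 0L, 1L)),
             as.vector(shift_clamp(mCh, -2L, 0L)),
             as.vector(shift_clamp(mCh, 2L, 0L)),
             as.vector(shift_clamp(mCh, 0L, -2L)),
             as.vector(shift_clamp(mCh, 0L, 2L)),
             as.vector(shift_clamp(mGy, -1L, 0L)),
             as.vector(shift_clamp(mGy, 1L, 0L)),
             as.vector(shift_clamp(mGy, 0L, -1L)),
             as.vector(shift_clamp(mGy, 0L, 1L)),
             rep(cxs, each = h1) / ncol(gray),
             rep(cys, times = w1) / nrow(gray))
  list(F = feat, h1 = h1, w1 = w1,
       cx = rep(cxs, each = h1), cy = rep(cys, times = w1))
}

DETECTOR_CHANNELS <- 22L

#' Two-scale pooled features for the miniature detector
#'
#' Per-cell colour means, gray texture spread, intra-cell chroma
#' quadrants, directional chroma and luminance context (neighbouring
#' cells at offsets of one and two cells) and normalized cell
#' coordinates, at the native stride and at twice the stride (the coarse
#' map is upsampled back onto the fine anchor grid for fusion).
#'
#' @param img An `rgb_image`.
#' @param stride Fine cell size in pixels (default 4).
#' @return List with `fine`, `coarse` (both C x N matrices over the fine
#'   grid) and the anchor grid (`cx`, `cy`, `h1`, `w1`, `stride`).
#' @export
detector_features <- function(img, stride = 4L) {
  px <- as_pixel_array(img)
  f1 <- extract_scale(px, stride)
  f2 <- extract_scale(px, 2L * stride)
  # nearest-neighbour upsample of the coarse map onto the fine grid
  i2 <- pmin((seq_len(f1$h1) + 1L) %/% 2L, f2$h1)
  j2 <- pmin((seq_len(f1$w1) + 1L) %/% 2L, f2$w1)
  idx <- as.vector(outer(i2, (j2 - 1L) * f2$h1, "+"))
  list(fine = f1$F, coarse = f2$F[, idx, drop = FALSE],
       cx = f1$cx, cy = f1$cy, h1 = f1$h1, w1 = f1$w1, stride = stride)
}

#' Initialize miniature-detector weights
#'
#' @param bank A `text_bank` defining the categories.
#' @param dim Text embedding dimension (default 64).
#' @param stride Fine anchor stride in pixels (default 4).
#' @param hidden Hidden width of the EDC modulation MLP.
#' @param seed Deterministic initialization seed.
#' @return A list of class `tiny_detector`.
#' @export
tiny_detector_init <- function(bank, dim = 64L, stride = 4L, hidden = 16L,
                               seed = 0L) {
  emb <- encode_text_bank(bank, dim, seed)
  pooled <- rowMeans(emb)
  pooled <- pooled / sqrt(sum(pooled^2))
  C <- DETECTOR_CHANNELS
  w_v <- matrix(hash_normal(string_hash("det_wv", seed), dim * C),
                nrow = dim) * (0.5 / sqrt(C))
  structure(list(
    bank = bank, dim = as.integer(dim), stride = as.integer(stride),
    seed = as.integer(seed),
    channels = C, categories = colnames(emb),
    text_emb = emb, pooled_bank = pooled,
    edc = edc_params_init(dim, C, hidden, seed),
    fusion_raw = c(1, 1), fusion_eps = 1e-4,
    w_v = w_v, b_v = numeric(dim),
    b_cls = rep(-2, ncol(emb)),
    w_b = matrix(0, 4, C), b_b = numeric(4),
    box_base = 2 * stride, logit_scale = 4,
    score_thr = 0.25, nms_iou = 0.5),
    class = "tiny_detector")
}

# raw forward pass over cached features; returns everything the training
# loop and the decoder need
detector_forward_raw <- function(w, feats, mod = NULL) {
  if (is.null(mod)) mod <- edc_modulation(w$edc, w$pooled_bank)
  wf <- pmax(w$fusion_raw, 0)
  # per-image, per-channel standardization (moments of the fine map):
  # absorbs the global photometric shifts left over from the three
  # illumination regimes and their enhancement paths
  ctr <- rowMeans(feats$fine)
  scl <- pmax(sqrt(rowMeans(feats$fine^2) - ctr^2), 1e-3)
  fine <- (feats$fine - ctr) / scl
  coarse <- (feats$coarse - ctr) / scl
  denom <- w$fusion_eps + sum(wf)
  X <- (fine * wf[1] + coarse * wf[2]) / denom
  a_s <- sigmoid(colMeans(X))
  a_c <- sigmoid(rowMeans(X))
  Xp <- X * outer(a_c, a_s)
  Xh <- edc_modulate_core(Xp, mod)
  mu <- colMeans(Xh)
  sdv <- sqrt(pmax(colMeans(Xh^2) - mu^2, 0) + 1e-5)
  Z <- sweep(sweep(Xh, 2, mu, "-"), 2, sdv, "/")
  Ycls <- X + gelu(Z)
  E <- w$w_v %*% Ycls + w$b_v
  logits <- w$logit_scale * crossprod(w$text_emb, E) + w$b_cls
  S <- sigmoid(logits)
  U <- pmin(pmax(w$w_b %*% X + w$b_b, -6), 6)
  D <- exp(U) * w$box_base
  boxes <- cbind(feats$cx - D[1, ], feats$cy - D[2, ],
                 feats$cx + D[3, ], feats$cy + D[4, ])
  list(X = X, Xp = Xp, Z = Z, sdv = sdv, Ycls = Ycls, E = E,
       S = S, D = D, U = U, boxes = boxes,
       a_s = a_s, a_c = a_c, fine = fine, coarse = coarse, denom = denom)
}

# class-wise greedy non-maximum suppression; returns kept indices
nms_keep <- function(boxes, scores, iou_thr = 0.5) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- iou_matrix(boxes[i, , drop = FALSE],
                       boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[ious <= iou_thr]
  }
  keep
}

#' Run the miniature detector on an image
#'
#' Deterministic for a fixed (image, weights, bank) triple.  Detections
#' below `score_thr` are dropped and class-wise greedy non-maximum
#' suppression at `nms_iou` removes duplicates; each surviving detection
#' carries its per-class score vector and its confidence (the maximum
#' class score).
#'
#' @param img An `rgb_image`.
#' @param weights A `tiny_detector` (trained or freshly initialized).
#' @param score_thr,nms_iou Optional overrides of the stored thresholds.
#' @return Data frame with columns `category`, `score`, `confidence`,
#'   `x1`, `y1`, `x2`, `y2`; the pre-NMS tensors are attached as
#'   attribute `"raw"` (list with `boxes`, `scores`, `anchors`).
#' @export
tiny_detector_forward <- function(img, weights, score_thr = NULL,
                                  nms_iou = NULL) {
  if (is.null(score_thr)) score_thr <- weights$score_thr
  if (is.null(nms_iou)) nms_iou <- weights$nms_iou
  feats <- detector_features(img, weights$stride)
  fwd <- detector_forward_raw(weights, feats)
  H <- dim(as_pixel_array(img))[1]; W <- dim(as_pixel_array(img))[2]
  boxes <- fwd$boxes
  boxes[, 1] <- pmax(boxes[, 1], 0); boxes[, 2] <- pmax(boxes[, 2], 0)
  boxes[, 3] <- pmin(boxes[, 3], W); boxes[, 4] <- pmin(boxes[, 4], H)
  conf <- apply(fwd$S, 2, max)
  out <- NULL
  for (k in seq_along(weights$categories)) {
    sel <- which(fwd$S[k, ] > score_thr)
    if (length(sel) == 0) next
    keep <- sel[nms_keep(boxes[sel, , drop = FALSE], fwd$S[k, sel], nms_iou)]
    out <- rbind(out, data.frame(
      category = weights$categories[k], score = fwd$S[k, keep],
      confidence = conf[keep],
      x1 = boxes[keep, 1], y1 = boxes[keep, 2],
      x2 = boxes[keep, 3], y2 = boxes[keep, 4]))
  }
  if (is.null(out))
    out <- data.frame(category = character(0), score = numeric(0),
                      confidence = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "raw") <- list(boxes = fwd$boxes, scores = fwd$S,
                           anchors = cbind(feats$cx, feats$cy))
  out
}

# stable binary cross-entropy from logits
bce_from_logits <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))

# numeric gradient of the hybrid loss w.r.t. the four box coordinates
hybrid_loss_box_grad <- function(box, gt, lambda_mix, h = 1e-3) {
  g <- numeric(4)
  for (d in 1:4) {
    bp <- box; bm <- box
    bp[d] <- bp[d] + h; bm[d] <- bm[d] - h
    g[d] <- (hybrid_iou_loss(bp, gt, lambda_mix) -
             hybrid_iou_loss(bm, gt, lambda_mix)) / (2 * h)
  }
  g
}

adam_update <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the miniature detector on annotated scenes
#'
#' Full-batch Adam over the trainable parts of the head: the visual
#' embedding and box-regression layers, the per-class biases, the output
#' layer of the EDC modulation MLP (analytic gradients through the
#' normalization and GELU) and the two fusion weights (exact central
#' finite differences on the epoch loss).  Positive samples come from
#' [assign_targets()] recomputed every epoch from the current scores and
#' boxes; the classification term is binary cross-entropy over all
#' anchors and categories, the regression term is the hybrid CIoU/GIoU
#' loss over positive anchors.
#'
#' @param scenes List of `list(image = rgb_image, boxes = data.frame)`
#'   training scenes (boxes in corner format with a `category` column).
#' @param bank A `text_bank`.
#' @param epochs Number of epochs (default 60).
#' @param lr Adam learning rate (default 0.02).
#' @param dim,stride,hidden,seed Passed to [tiny_detector_init()].
#' @param assigner An [assigner_params()] object.
#' @param lambda_mix Hybrid-loss mixing weight (default 0.5).
#' @param box_weight Weight of the regression term (default 2).
#' @param pos_weight Up-weighting of positive classification targets
#'   (default 8).
#' @param verbose Print the loss every 10 epochs.
#' @return A trained `tiny_detector` with a `history` element (per-epoch
#'   loss).
#' @export
train_tiny_detector <- function(scenes, bank, epochs = 60L, lr = 0.02,
                                dim = 64L, stride = 4L, hidden = 16L,
                                seed = 0L, assigner = assigner_params(),
                                lambda_mix = 0.5, box_weight = 2.0,
                                pos_weight = 8.0, verbose = FALSE) {
  w <- tiny_detector_init(bank, dim, stride, hidden, seed)
  K <- length(w$categories)
  C <- w$channels
  cache <- lapply(scenes, function(sc) {
    feats <- detector_features(sc$image, stride)
    cats <- match(sc$boxes$category, w$categories)
    ok <- !is.na(cats)
    list(feats = feats,
         gt = as.matrix(sc$boxes[ok, c("x1", "y1", "x2", "y2")]),
         gt_cat = cats[ok],
         anchors = cbind(feats$cx, feats$cy))
  })
  h_txt <- edc_hidden(w$edc, w$pooled_bank)

  params <- list(w_v = w$w_v, b_v = w$b_v, b_cls = w$b_cls,
                 w_b = w$w_b, b_b = w$b_b,
                 w2 = w$edc$w2, b2 = w$edc$b2, fus = w$fusion_raw)
  states <- lapply(params, function(p) list(m = p * 0, v = p * 0))

  history <- numeric(epochs)
  avg_params <- NULL
  avg_n <- 0L
  for (ep in seq_len(epochs)) {
    mod <- edc_modulation(list(dim = w$dim, channels = C, hidden = hidden,
                               w1 = w$edc$w1, b1 = w$edc$b1,
                               w2 = params$w2, b2 = params$b2),
                          w$pooled_bank)
    g <- lapply(params, function(p) p * 0)
    gm <- numeric(2L + 2L * C)   # modulation-parameter gradient
    assigns <- vector("list", length(cache))
    total <- 0
    wcur <- w
    wcur$w_v <- params$w_v; wcur$b_v <- params$b_v
    wcur$b_cls <- params$b_cls
    wcur$w_b <- params$w_b; wcur$b_b <- params$b_b
    wcur$fusion_raw <- params$fus
    for (si in seq_along(cache)) {
      cc <- cache[[si]]
      fwd <- detector_forward_raw(wcur, cc$feats, mod)
      n <- ncol(fwd$S)
      m <- nrow(cc$gt)
      Yt <- matrix(0, K, n)
      pos <- integer(0); pos_gt <- integer(0)
      if (m > 0) {
        cls_sc <- t(fwd$S)[, cc$gt_cat, drop = FALSE]
        asg <- assign_targets(cc$anchors, cc$gt, cls_sc, fwd$boxes, assigner)
        pos <- which(!is.na(asg$assigned_gt))
        pos_gt <- asg$assigned_gt[pos]
        if (length(pos) > 0)
          Yt[cbind(cc$gt_cat[pos_gt], pos)] <- 1
      }
      assigns[[si]] <- list(Yt = Yt, pos = pos, pos_gt = pos_gt)
      # ---- classification backward
      z <- wcur$logit_scale * crossprod(wcur$text_emb, fwd$E) + wcur$b_cls
      wt <- matrix(1, K, n); wt[Yt > 0] <- pos_weight
      cls_loss <- sum(wt * bce_from_logits(z, Yt)) / n
      Gz <- wt * (fwd$S - Yt) / n
      dE <- wcur$logit_scale * (wcur$text_emb %*% Gz)
      g$b_cls <- g$b_cls + rowSums(Gz)
      g$w_v <- g$w_v + dE %*% t(fwd$Ycls)
      g$b_v <- g$b_v + rowSums(dE)
      dY <- crossprod(wcur$w_v, dE)
      # ---- box backward (vectorized numeric grad of the hybrid loss,
      # chained through the exponential distance decoding)
      box_loss <- 0
      if (length(pos) > 0) {
        P <- fwd$boxes[pos, , drop = FALSE]
        G <- cc$gt[pos_gt, , drop = FALSE]
        # macro-balanced regression: every category contributes equally,
        # so the shared regressor is not dominated by the categories with
        # the most positive anchors (legs, hind quarters)
        pcat <- cc$gt_cat[pos_gt]
        cnt <- table(pcat)
        vq <- 1 / (length(cnt) * as.numeric(cnt[as.character(pcat)]))
        box_loss <- sum(vq * pair_hybrid_loss(P, G, lambda_mix))
        hstep <- 1e-3
        gB <- matrix(0, length(pos), 4)
        for (d in 1:4) {
          Pp <- P; Pp[, d] <- Pp[, d] + hstep
          Pm <- P; Pm[, d] <- Pm[, d] - hstep
          gB[, d] <- (pair_hybrid_loss(Pp, G, lambda_mix) -
                        pair_hybrid_loss(Pm, G, lambda_mix)) / (2 * hstep)
        }
        # d(box)/d(distances): x1 = cx - d1, ..., x2 = cx + d3; the
        # exponential decoding is clamped, so its derivative vanishes
        # outside the clamp
        dU <- matrix(0, 4, n)
        gB[, 1] <- -gB[, 1]; gB[, 2] <- -gB[, 2]
        dU[, pos] <- t(gB * vq) * fwd$D[, pos, drop = FALSE] *
          (abs(fwd$U[, pos, drop = FALSE]) < 6)
        g$w_b <- g$w_b + box_weight * dU %*% t(fwd$X)
        g$b_b <- g$b_b + box_weight * rowSums(dU)
      }
      total <- total + cls_loss + box_weight * box_loss
      # ---- EDC backward: dY -> modulation parameters
      dZpre <- dY * gelu_grad(fwd$Z)
      mg <- colMeans(dZpre)
      mgz <- colMeans(dZpre * fwd$Z)
      dXh <- sweep(dZpre, 2, mg, "-") - sweep(fwd$Z, 2, mgz, "*")
      dXh <- sweep(dXh, 2, fwd$sdv, "/")
      gm[1] <- gm[1] + sum(dXh * fwd$Xp * mod$cs)
      gm[2] <- gm[2] + sum(dXh)
      gm[3:(2 + C)] <- gm[3:(2 + C)] + mod$gs * rowSums(dXh * fwd$Xp)
      gm[(3 + C):(2 + 2 * C)] <- gm[(3 + C):(2 + 2 * C)] + rowSums(dXh)
      # ---- fusion backward: exact gradient of the loss in the two raw
      # fusion weights, through the residual, the attention factors, the
      # modulated branch and the box head
      dXp <- dXh * (mod$gs * mod$cs)
      watt <- outer(fwd$a_c, fwd$a_s)
      dX <- dY + dXp * watt
      dla_s <- colSums(dXp * fwd$X * fwd$a_c)
      sp_s <- fwd$a_s * (1 - fwd$a_s) / C
      dX <- dX + matrix(dla_s * sp_s, C, n, byrow = TRUE)
      dla_c <- rowSums(sweep(dXp * fwd$X, 2, fwd$a_s, "*"))
      sp_c <- fwd$a_c * (1 - fwd$a_c) / n
      dX <- dX + matrix(dla_c * sp_c, C, n)
      if (length(pos) > 0)
        dX <- dX + box_weight * crossprod(wcur$w_b, dU)
      g$fus[1] <- g$fus[1] + sum(dX * (fwd$fine - fwd$X)) / fwd$denom
      g$fus[2] <- g$fus[2] + sum(dX * (fwd$coarse - fwd$X)) / fwd$denom
    }
    ns <- length(cache)
    total <- total / ns
    for (nm in c("w_v", "b_v", "b_cls", "w_b", "b_b", "fus"))
      g[[nm]] <- g[[nm]] / ns
    gm <- gm / ns
    g$w2 <- gm %*% t(h_txt)
    g$b2 <- gm
    lr_ep <- if (ep > 0.7 * epochs) lr / 10 else lr   # step decay
    for (nm in names(params)) {
      upd <- adam_update(params[[nm]], g[[nm]], states[[nm]], lr_ep, ep)
      params[[nm]] <- upd$p
      states[[nm]] <- upd$st
    }
    params$fus <- pmax(params$fus, 0)
    # tail averaging over the decayed phase stabilizes the returned weights
    if (ep > 0.8 * epochs) {
      if (is.null(avg_params)) {
        avg_params <- params; avg_n <- 1L
      } else {
        avg_n <- avg_n + 1L
        for (nm in names(params))
          avg_params[[nm]] <- avg_params[[nm]] +
            (params[[nm]] - avg_params[[nm]]) / avg_n
      }
    }
    history[ep] <- total
    if (verbose && (ep %% 10 == 0 || ep == 1)) {
      npos <- integer(K)   # positives per category, a quick health check
      for (si in seq_along(cache)) {
        aa <- assigns[[si]]
        if (length(aa$pos) == 0) next
        cats <- cache[[si]]$gt_cat[aa$pos_gt]
        for (k in cats) npos[k] <- npos[k] + 1L
      }
      message(sprintf("epoch %3d  loss %.5f  positives [%s]", ep, total,
                      paste(npos, collapse = ",")))
    }
  }
  if (!is.null(avg_params)) params <- avg_params
  w$w_v <- params$w_v; w$b_v <- params$b_v; w$b_cls <- params$b_cls
  w$w_b <- params$w_b; w$b_b <- params$b_b
  w$edc$w2 <- params$w2; w$edc$b2 <- params$b2
  w$fusion_raw <- params$fus
  w$history <- history
  w
}

#' Save / load detector weights
#'
#' Weights are stored as a single named-array archive (RDS).
#'
#' @param weights A `tiny_detector`.
#' @param path Checkpoint path.
#' @return `path` (save) or the `tiny_detector` (load).
#' @export
save_detector <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  w <- readRDS(path)
  if (!inherits(w, "tiny_detector")) stop("not a detector checkpoint",
                                          call. = FALSE)
  w
}
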