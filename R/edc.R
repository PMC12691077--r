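#' Text-guided dynamic feature modulation (EDC block)
#'
#' The EDC block refines a feature map with joint spatial/channel
#' attention, rescales and shifts it with four text-derived modulation
#' parameters (a global scale/shift pair and a channel-wise scale/shift
#' pair), then normalizes, applies a GELU activation and adds a residual
#' connection back to the input.  With the modulation MLP's output layer
#' zero-initialized the whole block is exactly the identity, which anchors
#' its tests and gives stable training from scratch.
#'
#' @name edc
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# GELU, tanh approximation (fast and smooth; exact at 0)
gelu <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) +
    0.5 * x * (1 - t^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
}

check_feature_map <- function(X) {
  if (!is.array(X) || length(dim(X)) != 4L)
    stop("feature map must be a B x C x H x W array", call. = FALSE)
  if (any(dim(X) < 1L)) stop("all feature-map dims must be >= 1", call. = FALSE)
  if (!all(is.finite(X))) stop("feature map must be finite", call. = FALSE)
  invisible(X)
}

# ---- core math on a C x N matrix (one batch element, positions flattened)

sca_core <- function(Xm) {
  a_s <- sigmoid(colMeans(Xm))   # spatial attention, one weight per position
  a_c <- sigmoid(rowMeans(Xm))   # channel attention, one weight per channel
  Xm * outer(a_c, a_s)
}

edc_modulate_core <- function(Xp, mod) {
  Xp * (mod$gs * mod$cs) + (mod$gb + mod$cb)
}

layer_norm_core <- function(Xh, eps = 1e-5) {
  mu <- colMeans(Xh)
  v <- colMeans(Xh^2) - mu^2
  sweep(sweep(Xh, 2, mu, "-"), 2, sqrt(pmax(v, 0) + eps), "/")
}

edc_forward_core <- function(Xm, mod) {
  Xp <- sca_core(Xm)
  Xh <- edc_modulate_core(Xp, mod)
  Xm + gelu(layer_norm_core(Xh))
}

map_over_batch <- function(X, f) {
  d <- dim(X)
  out <- X
  for (b in seq_len(d[1])) {
    Xm <- matrix(X[b, , , ], nrow = d[2])    # C x (H*W), row-major over c
    out[b, , , ] <- array(f(Xm), dim = d[2:4])
  }
  out
}

#' Joint spatial and channel attention
#'
#' The spatial attention map is the sigmoid of the channel-wise mean (one
#' weight per position) and the channel attention is the sigmoid of the
#' spatial mean (one weight per channel); the input is multiplied by both,
#' element-wise with broadcasting.
#'
#' @param X B x C x H x W numeric array.
#' @return Array of the same shape.
#' @export
spatial_channel_attention <- function(X) {
  check_feature_map(X)
  map_over_batch(X, sca_core)
}

#' Apply text-derived modulation parameters
#'
#' Computes `X' * gs * cs + gb + cb` with `gs`, `gb` scalars and `cs`,
#' `cb` per-channel vectors broadcast over positions.
#'
#' @param Xp B x C x H x W attention-refined feature map.
#' @param mod A list with `gs`, `gb` (scalars) and `cs`, `cb` (C-vectors),
#'   e.g. from [edc_modulation()].
#' @return Modulated array of the same shape.
#' @export
edc_modulate <- function(Xp, mod) {
  check_feature_map(Xp)
  C <- dim(Xp)[2]
  if (length(mod$cs) != C || length(mod$cb) != C)
    stop("channel count of `mod` does not match the feature map",
         call. = FALSE)
  map_over_batch(Xp, function(Xm) edc_modulate_core(Xm, mod))
}

#' Initialize EDC modulation-MLP parameters
#'
#' One hidden layer of width `hidden` with GELU activation; the output
#' layer (producing the 2 + 2C modulation parameters) is zero-initialized
#' so the block starts as the identity.
#'
#' @param dim Text embedding dimension D.
#' @param channels Feature channel count C.
#' @param hidden Hidden width (default 16).
#' @param seed Seed for the (fixed) hidden-layer initialization.
#' @return A list of class `edc_params`.
#' @export
edc_params_init <- function(dim, channels, hidden = 16L, seed = 0L) {
  w1 <- matrix(hash_normal(string_hash("edc_w1", seed), hidden * dim),
               nrow = hidden) / sqrt(dim)
  structure(list(dim = as.integer(dim), channels = as.integer(channels),
                 hidden = as.integer(hidden),
                 w1 = w1, b1 = numeric(hidden),
                 w2 = matrix(0, nrow = 2L + 2L * channels, ncol = hidden),
                 b2 = numeric(2L + 2L * channels)),
            class = "edc_params")
}

edc_hidden <- function(params, pooled_text) {
  gelu(as.vector(params$w1 %*% pooled_text) + params$b1)
}

#' Compute the four modulation parameters from a pooled text vector
#'
#' @param params An `edc_params` object.
#' @param pooled_text D-vector (pooled text embedding).
#' @return List with scalars `gs`, `gb` and C-vectors `cs`, `cb`.
#' @export
edc_modulation <- function(params, pooled_text) {
  if (length(pooled_text) != params$dim)
    stop("pooled text dimension does not match `params$dim`", call. = FALSE)
  h <- edc_hidden(params, pooled_text)
  m <- as.vector(params$w2 %*% h) + params$b2
  C <- params$channels
  list(gs = m[1], gb = m[2], cs = m[3:(2 + C)], cb = m[(3 + C):(2 + 2 * C)])
}

#' Full EDC forward pass
#'
#' `Y = X + GELU(layer_norm(edc_modulate(attention(X))))`, with the layer
#' normalization taken over the channel axis at every position (mean 0,
#' variance 1, no learned affine).
#'
#' @param X B x C x H x W feature map.
#' @param pooled_text D-vector conditioning the modulation.
#' @param params An `edc_params` object.
#' @return Array of the same shape as `X`.
#' @export
edc_forward <- function(X, pooled_text, params) {
  check_feature_map(X)
  if (dim(X)[2] != params$channels)
    stop("channel count mismatch between `X` and `params`", call. = FALSE)
  mod <- edc_modulation(params, pooled_text)
  map_over_batch(X, function(Xm) edc_forward_core(Xm, mod))
}

#' Learnable-weight fusion node
#'
#' @param raw_weights Non-negative reals, one per fused branch.
#' @param epsilon Stabilizer of the fast normalization (default 1e-4).
#' @return A list of class `fusion_node`.
#' @export
fusion_node <- function(raw_weights, epsilon = 1e-4) {
  if (length(raw_weights) < 2L)
    stop("a fusion node needs at least two branches", call. = FALSE)
  structure(list(raw_weights = as.numeric(raw_weights),
                 epsilon = epsilon),
            class = "fusion_node")
}

#' Fast-normalized bidirectional feature fusion
#'
#' `O = sum_i w_i / (eps + sum_j w_j) * I_i` with `w_i = max(raw_i, 0)`:
#' the learnable-weight fusion used at every node of a bidirectional
#' feature pyramid.  Up to the epsilon slack the output is a convex
#' combination of the inputs.
#'
#' @param inputs List of equal-shaped numeric arrays.
#' @param node A [fusion_node()] whose weight count matches
#'   `length(inputs)`.
#' @return Array of the common input shape.
#' @export
db_fuse <- function(inputs, node) {
  if (length(inputs) < 2L) stop("need at least two inputs", call. = FALSE)
  if (length(node$raw_weights) != length(inputs))
    stop("fusion node has wrong number of weights", call. = FALSE)
  d <- dim(inputs[[1]])
  for (x in inputs[-1])
    if (!identical(dim(x), d))
      stop("all fused inputs must share a shape", call. = FALSE)
  w <- pmax(node$raw_weights, 0)
  denom <- node$epsilon + sum(w)
  out <- inputs[[1]] * (w[1] / denom)
  for (i in seq_along(inputs)[-1]) out <- out + inputs[[i]] * (w[i] / denom)
  out
}
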