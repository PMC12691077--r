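#' Parameters of the Retinex low-light enhancer
#'
#' The low-light path models a frame as reflectance times illumination,
#' I = R * L, estimates an initial decomposition in closed form and then
#' refines it by alternating minimization of the penalized energy
#'
#'   E(P, Q, R, L) = ||I - P.R||_F^2 + alpha phi(R) + beta psi(L)
#'                   + gamma ||P - Q||_F^2 + lambda ||Q - L||_F^2
#'
#' where P and Q are auxiliary illumination variables and phi, psi are
#' quadratic total-variation-style smoothness penalties on the reflectance
#' and illumination maps.  The refined illumination is brightened by a
#' gamma-style coefficient `omega` before recombination.
#'
#' @param mu_init Weight of the structure term in the initializer.
#' @param alpha_reg,beta_reg Smoothness weights for reflectance and
#'   illumination.
#' @param gamma_pen,lambda_pen Penalty weights coupling P, Q and L.
#' @param stages Number of alternating-optimization stages T (>= 1 for
#'   refinement; 0 leaves the initialization untouched).
#' @param omega Brightness coefficient in (0, 1]; smaller values brighten
#'   more.  Default 0.5.
#' @return A list of class `retinex_params`.
#' @export
retinex_params <- function(mu_init = 0.05, alpha_reg = 0.001, beta_reg = 0.01,
                           gamma_pen = 0.1, lambda_pen = 0.1,
                           stages = 3L, omega = 0.5) {
  weights <- c(mu_init, alpha_reg, beta_reg, gamma_pen, lambda_pen)
  if (any(weights < 0)) stop("all Retinex weights must be >= 0", call. = FALSE)
  if (stages < 0) stop("`stages` must be >= 0", call. = FALSE)
  if (omega <= 0 || omega > 1) stop("`omega` must lie in (0, 1]", call. = FALSE)
  structure(list(mu_init = mu_init, alpha_reg = alpha_reg,
                 beta_reg = beta_reg, gamma_pen = gamma_pen,
                 lambda_pen = lambda_pen, stages = as.integer(stages),
                 omega = omega),
            class = "retinex_params")
}

RETINEX_EPS <- 1e-4

# quadratic TV energy sum((forward dx)^2 + (forward dy)^2) of a matrix
tv_energy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  e <- 0
  if (h > 1) e <- e + sum((m[-1, , drop = FALSE] - m[-h, , drop = FALSE])^2)
  if (w > 1) e <- e + sum((m[, -1, drop = FALSE] - m[, -w, drop = FALSE])^2)
  e
}

# gradient of tv_energy: 2 * graph-Laplacian(m) on the 4-neighbour grid
tv_grad <- function(m) {
  h <- nrow(m); w <- ncol(m)
  g <- matrix(0, h, w)
  if (h > 1) {
    d <- m[-1, , drop = FALSE] - m[-h, , drop = FALSE]
    g[-h, ] <- g[-h, , drop = FALSE] - 2 * d
    g[-1, ] <- g[-1, , drop = FALSE] + 2 * d
  }
  if (w > 1) {
    d <- m[, -1, drop = FALSE] - m[, -w, drop = FALSE]
    g[, -w] <- g[, -w, drop = FALSE] - 2 * d
    g[, -1] <- g[, -1, drop = FALSE] + 2 * d
  }
  g
}

#' Evaluate the Retinex refinement energy
#'
#' @param img_norm H x W x 3 array in \[0, 1\].
#' @param P,Q,L H x W illumination-block matrices.
#' @param R H x W x 3 reflectance array.
#' @param params A [retinex_params()] object.
#' @return Scalar energy value.
#' @export
retinex_energy <- function(img_norm, P, Q, R, L, params) {
  fid <- sum((img_norm - R * as.vector(P))^2)  # P broadcast over channels
  smooth_r <- sum(vapply(1:3, function(c) tv_energy(R[, , c]), numeric(1)))
  fid + params$alpha_reg * smooth_r + params$beta_reg * tv_energy(L) +
    params$gamma_pen * sum((P - Q)^2) + params$lambda_pen * sum((Q - L)^2)
}

#' Closed-form Retinex initialization
#'
#' The initial illumination is the per-pixel maximum over the RGB channels
#' (the structure prior of the initializer objective), floored at a small
#' epsilon; the initial reflectance is the input divided by it, clipped to
#' \[0, 1\].  Because the max channel bounds every channel, the product
#' R0 * L0 reconstructs the input exactly wherever L0 exceeds the floor.
#'
#' @param img_norm H x W x 3 array in \[0, 1\].
#' @param params A [retinex_params()] object.
#' @return A list of class `retinex_decomposition` with `reflectance`
#'   (H x W x 3 in \[0, 1\]) and `illumination` (H x W in (0, 1\]).
#' @export
retinex_init <- function(img_norm, params = retinex_params()) {
  if (!is.array(img_norm) || length(dim(img_norm)) != 3L)
    stop("`img_norm` must be an H x W x 3 array", call. = FALSE)
  if (min(img_norm) < 0 || max(img_norm) > 1)
    stop("`img_norm` must be normalized to [0, 1]", call. = FALSE)
  L0 <- pmax(pmax(img_norm[, , 1], img_norm[, , 2]), img_norm[, , 3])
  L0 <- pmax(L0, RETINEX_EPS)
  R0 <- img_norm / as.vector(L0)
  R0 <- array(pmin(1, pmax(0, R0)), dim = dim(img_norm))
  structure(list(reflectance = R0, illumination = L0),
            class = "retinex_decomposition")
}

#' Alternating refinement of a Retinex decomposition
#'
#' Runs `params$stages` stages; each stage updates the four blocks P, Q, R,
#' L in turn.  P and Q have exact per-pixel minimizers; R and L are updated
#' by a few gradient steps with a step size below the inverse Lipschitz
#' constant of their (convex quadratic) sub-objectives, so the total energy
#' is non-increasing stage to stage.  The energy trace (initial value plus
#' one value per stage) is attached as attribute `"energy"`.
#'
#' @param init A `retinex_decomposition` from [retinex_init()].
#' @param img_norm The normalized input image, H x W x 3 in \[0, 1\].
#' @param params A [retinex_params()] object.
#' @param inner_steps Gradient steps per R/L block update (default 5).
#' @return A refined `retinex_decomposition` with an `"energy"` attribute.
#' @export
retinex_unfold <- function(init, img_norm, params = retinex_params(),
                           inner_steps = 5L) {
  R <- init$reflectance
  L <- init$illumination
  P <- L
  Q <- L
  a <- params$alpha_reg; b <- params$beta_reg
  g <- params$gamma_pen; l <- params$lambda_pen
  trace <- retinex_energy(img_norm, P, Q, R, L, params)
  if (params$stages == 0L) {
    attr(init, "energy") <- trace
    return(init)
  }
  for (stage in seq_len(params$stages)) {
    # P: per-pixel least squares against all three channels plus the Q tie
    num <- img_norm[, , 1] * R[, , 1] + img_norm[, , 2] * R[, , 2] +
      img_norm[, , 3] * R[, , 3] + g * Q
    den <- R[, , 1]^2 + R[, , 2]^2 + R[, , 3]^2 + g
    P <- num / pmax(den, 1e-12)
    # Q: exact average of its two ties
    if (g + l > 0) Q <- (g * P + l * L) / (g + l)
    # R: gradient steps on sum_c ||I_c - P R_c||^2 + alpha * TV(R_c)
    step_r <- 1 / (2 * max(P^2) + 16 * a + 1e-12)
    for (k in seq_len(inner_steps)) {
      for (c in 1:3) {
        gr <- -2 * P * (img_norm[, , c] - P * R[, , c]) + a * tv_grad(R[, , c])
        R[, , c] <- R[, , c] - step_r * gr
      }
    }
    # L: gradient steps on beta * TV(L) + lambda ||Q - L||^2
    if (l + b > 0) {
      step_l <- 1 / (16 * b + 2 * l + 1e-12)
      for (k in seq_len(inner_steps)) {
        gl <- b * tv_grad(L) - 2 * l * (Q - L)
        L <- L - step_l * gl
      }
    }
    e <- retinex_energy(img_norm, P, Q, R, L, params)
    if (!is.finite(e))
      stop(sprintf("Retinex energy became non-finite at stage %d", stage),
           call. = FALSE)
    trace <- c(trace, e)
  }
  out <- structure(
    list(reflectance = array(pmin(1, pmax(0, R)), dim = dim(R)),
         illumination = pmax(pmin(L, 1), RETINEX_EPS)),
    class = "retinex_decomposition")
  attr(out, "energy") <- trace
  out
}

#' Brighten an illumination map
#'
#' Gamma-style adjustment L^omega for omega in (0, 1].  Monotone in L and
#' maps 1 to 1; values below 1 are raised toward 1.
#'
#' @param L Illumination matrix with values in (0, 1].
#' @param omega Brightness coefficient in (0, 1].
#' @return Adjusted illumination matrix.
#' @export
adjust_illumination <- function(L, omega) {
  if (omega <= 0 || omega > 1) stop("`omega` must lie in (0, 1]", call. = FALSE)
  L^omega
}

#' Enhance a low-light image
#'
#' Full low-light path: normalize, decompose (init + unfolding), brighten
#' the illumination map with `params$omega`, recombine with the reflectance
#' and rescale to 8-bit.  Because L^omega >= L on (0, 1], the result is at
#' least as bright as the reconstruction R * L.
#'
#' @param img An `rgb_image` (assumed already gated as low light).
#' @param params A [retinex_params()] object.
#' @return Enhanced `rgb_image`.
#' @export
enhance_lowlight <- function(img, params = retinex_params()) {
  px <- as_pixel_array(img) / 255
  dec <- retinex_unfold(retinex_init(px, params), px, params)
  Lt <- adjust_illumination(dec$illumination, params$omega)
  finalize_rgb(dec$reflectance * as.vector(Lt) * 255)
}
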