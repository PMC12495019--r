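# Focal correction: collapse a curved 3D stack onto its in-focus manifold.
#
# The DAPI channel is the sharpness reference. Per slice, a Sobel gradient
# magnitude is computed; its per-pixel maximum over z locates the slice where
# the nuclear borders are sharpest. Low-gradient pixels (noise rather than
# structure) are zero-weighted, a bivariate polynomial z_f(x, y) is fitted to
# the argmax map by weighted least squares, and every channel is linearly
# interpolated along z onto the fitted surface.

#' Sobel gradient magnitude
#'
#' Magnitude of the two unnormalized 3x3 Sobel responses, computed with
#' replicate border padding (no spurious frame-edge gradients).
#'
#' @param img numeric matrix (`[y, x]`), at least 3x3.
#' @return non-negative numeric matrix of the same dimension.
#' @export
sobel_gradient <- function(img) {
  check_matrix(img, min_dim = 3L)
  gx <- cpp_conv_sep(img, c(1, 0, -1), c(1, 2, 1))
  gy <- cpp_conv_sep(img, c(1, 2, 1), c(1, 0, -1))
  sqrt(gx^2 + gy^2)
}

#' Maximum gradient projection of a stack
#'
#' Applies [sobel_gradient()] to every slice and takes, per pixel, the maximum
#' gradient magnitude over z and the slice index attaining it (lowest index on
#' ties, for determinism).
#'
#' @param stack3d numeric 3D array `[y, x, z]` with at least 2 slices
#'   (typically the DAPI channel).
#' @return list with `M` (max gradient magnitude, matrix) and `z_m`
#'   (argmax slice index, integer matrix, 1-based).
#' @export
max_gradient_projection <- function(stack3d) {
  if (length(dim(stack3d)) != 3L || dim(stack3d)[3] < 2L)
    stop("`stack3d` must be a 3D array with >= 2 slices", call. = FALSE)
  nz <- dim(stack3d)[3]
  M <- sobel_gradient(stack3d[, , 1])
  z_m <- array(1L, dim = dim(M))
  for (k in seq_len(nz)[-1]) {
    g <- sobel_gradient(stack3d[, , k])
    upd <- g > M            # strict: ties keep the lowest slice index
    M[upd] <- g[upd]
    z_m[upd] <- k
  }
  list(M = M, z_m = z_m)
}

#' Threshold the gradient weights
#'
#' Sets to zero every value below `factor` times the 99th percentile of the
#' input (linear-interpolation percentile convention); other values are kept
#' unchanged. The surviving values weight the manifold fit.
#'
#' @param M non-negative numeric matrix (max gradient magnitude).
#' @param factor threshold factor (default 0.1).
#' @param percentile reference percentile (default 99).
#' @return numeric matrix of weights.
#' @export
threshold_weights <- function(M, factor = 0.1, percentile = 99) {
  check_matrix(M)
  th <- factor * prc(M, percentile)
  M[M < th] <- 0
  M
}

# ---- bivariate polynomial machinery ----------------------------------------

# Exponent pairs (a, b) with a + b <= degree, in a fixed deterministic order.
poly_exponents <- function(degree) {
  g <- expand.grid(a = 0:degree, b = 0:degree)
  g <- g[g$a + g$b <= degree, , drop = FALSE]
  g[order(g$a + g$b, g$a), , drop = FALSE]
}

# Coordinates normalized to [-1, 1] over the frame (singleton axes map to 0).
norm_coord <- function(n) if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0

coeffs_degree <- function(coeffs) {
  nz <- which(coeffs != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(0L)
  max(nz[, 1] + nz[, 2] - 2L)
}

# Evaluate a coefficient matrix (coeffs[a+1, b+1] multiplies xhat^a yhat^b)
# over an H x W frame on normalized coordinates.
eval_poly_surface <- function(coeffs, shape) {
  H <- shape[1]; W <- shape[2]
  xs <- norm_coord(W); ys <- norm_coord(H)
  surf <- matrix(0, H, W)
  nz <- which(coeffs != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(surf)
  for (i in seq_len(nrow(nz))) {
    a <- nz[i, 1] - 1L; b <- nz[i, 2] - 1L
    surf <- surf + coeffs[nz[i, 1], nz[i, 2]] * outer(ys^b, xs^a)
  }
  surf
}

#' Fit the in-focus manifold
#'
#' Weighted least-squares fit of a bivariate polynomial of total degree
#' `degree` (21 coefficients at the default degree 5) to the argmax slice map,
#' on coordinates normalized to \eqn{[-1, 1]}. Pixels with zero weight do not
#' influence the fit. The fitted surface is evaluated over the whole frame and
#' is not clamped here; clamping to the valid slice range happens at
#' interpolation time.
#'
#' @param z_m numeric matrix of per-pixel argmax slice indices.
#' @param weights non-negative numeric matrix of the same dimension
#'   (typically [threshold_weights()] output).
#' @param degree total polynomial degree (default 5).
#' @return an object of class `focus_manifold`: list with `coeffs`
#'   (coefficient matrix), `z_f` (fitted surface), `z_m`, `weights`, `degree`,
#'   and `rmse_w` (weighted residual RMSE, slice units).
#' @export
fit_focus_manifold <- function(z_m, weights, degree = 5L) {
  fit <- wls_poly_surface(z_m, weights, degree,
                          what = "manifold fit")
  sel <- which(weights > 0)
  res <- fit$surface[sel] - z_m[sel]
  structure(
    list(coeffs = fit$coeffs, z_f = fit$surface, z_m = z_m, weights = weights,
         degree = degree,
         rmse_w = sqrt(sum(weights[sel] * res^2) / sum(weights[sel]))),
    class = "focus_manifold")
}

# Weighted least-squares fit of a total-degree bivariate polynomial surface on
# [-1, 1]-normalized frame coordinates. Shared by the manifold fit (degree 5
# on the argmax map) and the local contrast adjustment (self-weighted degree 2
# on the nuclear signal).
wls_poly_surface <- function(values, weights, degree, what = "surface fit") {
  check_matrix(values); check_matrix(weights)
  if (!all(dim(values) == dim(weights)))
    stop("`values` and `weights` must have identical dimensions", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  ex <- poly_exponents(degree)
  sel <- which(weights > 0)
  if (length(sel) < nrow(ex))
    stop(sprintf("%s needs >= %d pixels with positive weight, got %d",
                 what, nrow(ex), length(sel)), call. = FALSE)
  H <- nrow(values); W <- ncol(values)
  xs <- norm_coord(W); ys <- norm_coord(H)
  xi <- xs[((sel - 1) %/% H) + 1]
  yi <- ys[((sel - 1) %% H) + 1]
  X <- mapply(function(a, b) xi^a * yi^b, ex$a, ex$b)
  sw <- sqrt(weights[sel])
  Xw <- X * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw))
    stop(sprintf("%s failed: rank-deficient design (weighted pixels do not constrain all polynomial terms)",
                 what), call. = FALSE)
  beta <- qr.coef(qrX, values[sel] * sw)
  coeffs <- matrix(0, degree + 1L, degree + 1L)
  coeffs[cbind(ex$a + 1L, ex$b + 1L)] <- beta
  list(coeffs = coeffs, surface = eval_poly_surface(coeffs, c(H, W)))
}

#' @export
print.focus_manifold <- function(x, ...) {
  cat(sprintf("<focus_manifold> degree %d, z_f range [%.2f, %.2f], weighted RMSE %.3f slices\n",
              x$degree, min(x$z_f), max(x$z_f), x$rmse_w))
  invisible(x)
}

#' Interpolate a stack on the focus manifold
#'
#' Per pixel, linear interpolation along z between the two slices bracketing
#' `z_f`, applied to every channel of the stack. `z_f` is clamped to the valid
#' slice range `[1, n_slices]`; values within 1e-9 of an integer are snapped
#' to it, so an integer-valued flat manifold reproduces the corresponding
#' slice bit-exactly.
#'
#' @param stack an [image_stack].
#' @param manifold a [fit_focus_manifold()] result (or any list with a `z_f` matrix of
#'   matching dimension).
#' @return an [in_focus_image] with the same channels as `stack`.
#' @export
interpolate_on_manifold <- function(stack, manifold) {
  stopifnot(inherits(stack, "image_stack"))
  z_f <- manifold$z_f
  d <- dim(stack)
  if (!all(dim(z_f) == d[1:2]))
    stop("manifold and stack frames differ in size", call. = FALSE)
  nz <- d[3]
  z <- pmin(pmax(z_f, 1), nz)
  zr <- round(z)
  snap <- abs(z - zr) < 1e-9
  z[snap] <- zr[snap]
  k0 <- pmin(floor(z), nz - 1L)
  f <- z - k0
  npx <- d[1] * d[2]
  i0 <- seq_len(npx) + (as.vector(k0) - 1) * npx
  channels <- lapply(stack$channels, function(a) {
    v <- as.vector(a)
    out <- v[i0] * (1 - as.vector(f)) + v[i0 + npx] * as.vector(f)
    matrix(out, d[1], d[2])
  })
  in_focus_image(channels, stack$pixel_size_um, manifold = manifold)
}

#' Focal correction of a stack
#'
#' The full focal-correction stage: Sobel gradient of every DAPI slice,
#' per-pixel maximum over z, thresholding of the gradient weights, weighted
#' polynomial fit of the in-focus manifold, and linear interpolation of all
#' channels onto it.
#'
#' The DAPI slices are lightly Gaussian-smoothed (`presmooth_sigma`) before
#' the gradient is taken: the Sobel operator amplifies pixel-independent
#' noise about 3.5-fold and the per-pixel maximum over z then selects its
#' extremes, so on noisy stacks unsmoothed gradients let structureless pixels
#' through the weight threshold and contaminate the manifold fit. Smoothing
#' at roughly the optical-blur scale restores the edge-to-background gradient
#' contrast the threshold assumes; set `presmooth_sigma = 0` to disable.
#'
#' @param stack an [image_stack] with a `"dapi"` channel.
#' @param degree total polynomial degree of the manifold (default 5).
#' @param threshold_factor weight threshold factor (default 0.1 of the 99th
#'   percentile).
#' @param presmooth_sigma Gaussian sd (px) applied to each DAPI slice before
#'   the gradient (default 2; 0 disables).
#' @return list with `image` (the [in_focus_image]) and `manifold`.
#' @export
focal_correct <- function(stack, degree = 5L, threshold_factor = 0.1,
                          presmooth_sigma = 2) {
  stopifnot(inherits(stack, "image_stack"))
  dapi <- stack_channel(stack, "dapi")
  if (presmooth_sigma > 0)
    for (k in seq_len(dim(dapi)[3]))
      dapi[, , k] <- gauss_smooth(dapi[, , k], presmooth_sigma)
  proj <- max_gradient_projection(dapi)
  w <- threshold_weights(proj$M, factor = threshold_factor)
  manifold <- fit_focus_manifold(proj$z_m, w, degree = degree)
  list(image = interpolate_on_manifold(stack, manifold), manifold = manifold)
}
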