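# Shared internal helpers: percentile convention, kernels, input checks.

# Single percentile convention for the whole package: linear interpolation
# between order statistics (R type 7). Both the gradient-weight threshold and
# the h-maxima height depend on it, so it is fixed here and nowhere else.
prc <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

check_matrix <- function(x, name = deparse(substitute(x)), min_dim = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(sprintf("`%s` must be at least %dx%d", name, min_dim, min_dim),
         call. = FALSE)
  invisible(x)
}

# Disc structuring element of radius r (pixels), as (dy, dx) offsets with
# dy^2 + dx^2 <= r^2. r = 0 gives the identity element.
disc_offsets <- function(r) {
  if (r < 0) stop("structuring-element radius must be >= 0", call. = FALSE)
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Normalized 1D Gaussian kernel, radius 3*sd (odd length >= 1).
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) stop("gaussian sd must be > 0", call. = FALSE)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with replicate border padding
#'
#' Separable Gaussian convolution; the kernel is truncated at three standard
#' deviations and renormalized, borders are edge-clamped.
#'
#' @param img numeric matrix (`[y, x]`).
#' @param sigma standard deviation in pixels; must be positive. `sigma = 0`
#'   returns the input unchanged.
#' @return numeric matrix of the same dimension.
#' @export
gauss_smooth <- function(img, sigma) {
  check_matrix(img)
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  cpp_conv_sep(img, k, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
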