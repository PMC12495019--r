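# Synthetic phantoms with known ground truth. Every downstream stage of the
# pipeline (focal correction, segmentation, profiling, colocalization) is
# tested against stacks and image pairs generated here.
#
# The phantom emulates a contact-inhibited epithelial monolayer: disk-shaped
# nuclei on a jittered hexagonal (contact-inhibited) lattice, cytoplasm as the
# Voronoi region of each nucleus clipped to the sheet mask, per-cell protein
# means drawn from a
# bivariate normal with controllable inter-channel correlation, a smooth
# polynomial in-focus surface through the stack, distance-dependent defocus
# blur, and Poisson-Gaussian noise.

# Run `expr` under a private RNG stream; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evaluate a polynomial focus surface
#'
#' Evaluates a bivariate polynomial of total degree at most 5 on coordinates
#' normalized to \eqn{[-1, 1]} over the frame: `surface[y, x] =
#' sum(c[a, b] * xhat^a * yhat^b)`.
#'
#' @param coeffs numeric coefficient matrix; `coeffs[a + 1, b + 1]` multiplies
#'   `xhat^a * yhat^b`. Any non-zero entry with total degree above 5 is
#'   rejected.
#' @param shape frame size `c(H, W)`.
#' @return an `H x W` numeric matrix.
#' @export
make_focus_surface <- function(coeffs, shape) {
  if (!is.matrix(coeffs) || !is.numeric(coeffs))
    stop("`coeffs` must be a numeric matrix", call. = FALSE)
  if (coeffs_degree(coeffs) > 5L)
    stop("focus-surface polynomial degree must be <= 5 (non-zero coefficient of higher total degree found)",
         call. = FALSE)
  if (length(shape) != 2L || any(shape < 2))
    stop("`shape` must be c(H, W) with H, W >= 2", call. = FALSE)
  eval_poly_surface(coeffs, shape)
}

#' Random focus-surface coefficients confined to the slice range
#'
#' Draws random degree-5 coefficients with magnitude decaying in total degree,
#' then rescales affinely so that the surface over the frame spans
#' `[lo, hi]` slice units exactly.
#'
#' @param shape frame size `c(H, W)`.
#' @param n_slices number of slices; the surface spans a sub-range of
#'   `[1, n_slices]`.
#' @param margin slices kept clear at both ends (default 2).
#' @param seed RNG seed.
#' @return a coefficient matrix for [make_focus_surface()].
#' @export
random_focus_coeffs <- function(shape, n_slices, margin = 2, seed = NULL) {
  with_seed(seed, {
    ex <- poly_exponents(5L)
    coeffs <- matrix(0, 6L, 6L)
    coeffs[cbind(ex$a + 1L, ex$b + 1L)] <- rnorm(nrow(ex)) / (1 + ex$a + ex$b)^2
    surf <- eval_poly_surface(coeffs, shape)
    lo <- 1 + margin; hi <- n_slices - margin
    if (hi <= lo) stop("n_slices too small for the requested margin", call. = FALSE)
    rng <- max(surf) - min(surf)
    scale <- if (rng > 0) (hi - lo) / rng else 0
    coeffs <- coeffs * scale
    coeffs[1, 1] <- coeffs[1, 1] + lo - min(surf) * scale
    coeffs
  })
}

#' Place non-overlapping nuclei
#'
#' Rejection sampling of `n` nucleus centers with pairwise separation at least
#' `2 * radius + 2` px and a margin of `radius` px from the frame edge (and
#' from the sheet border, if a `mask` is given).
#'
#' @param n number of nuclei.
#' @param shape frame size `c(H, W)`.
#' @param radius nucleus radius in px.
#' @param seed RNG seed.
#' @param mask optional logical matrix restricting placement.
#' @param max_tries rejection-sampling budget (default `500 * n`).
#' @return an `n x 2` matrix of centers, columns `x`, `y` (1-based px).
#' @export
place_nuclei <- function(n, shape, radius, seed = NULL, mask = NULL,
                         max_tries = 500L * n) {
  H <- shape[1]; W <- shape[2]
  if (n * pi * (2 * radius)^2 >= H * W)
    stop(sprintf("infeasible packing: %d nuclei of radius %g do not fit a %dx%d frame",
                 n, radius, H, W), call. = FALSE)
  min_sep2 <- (2 * radius + 2)^2
  with_seed(seed, {
    centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
    placed <- 0L
    for (try in seq_len(max_tries)) {
      cx <- runif(1, radius + 1, W - radius)
      cy <- runif(1, radius + 1, H - radius)
      if (!is.null(mask) && !mask[round(cy), round(cx)]) next
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cx)^2 +
              (centers[seq_len(placed), 2] - cy)^2
        if (min(d2) < min_sep2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
      if (placed == n) break
    }
    if (placed < n)
      stop(sprintf("nucleus packing failed: placed %d of %d after %d attempts",
                   placed, n, max_tries), call. = FALSE)
    centers
  })
}

#' Place nuclei on a jittered hexagonal lattice
#'
#' Emulates a contact-inhibited monolayer: nucleus centers sit on a hexagonal
#' lattice whose pitch is chosen so that `n` cells tile the frame, each
#' jittered by a uniform offset of up to `jitter_frac * pitch`. Compared with
#' random sequential packing this gives the near-uniform internuclear spacing
#' of a confluent epithelium (no unbiological cell-free gaps).
#'
#' @param n number of nuclei.
#' @param shape frame size `c(H, W)`.
#' @param radius nucleus radius in px (margin from the frame edge).
#' @param jitter_frac jitter amplitude as a fraction of the pitch
#'   (default 0.12).
#' @param seed RNG seed.
#' @param mask optional logical matrix restricting placement.
#' @return an `n x 2` matrix of centers, columns `x`, `y`.
#' @export
place_nuclei_lattice <- function(n, shape, radius, jitter_frac = 0.12,
                                 seed = NULL, mask = NULL) {
  H <- shape[1]; W <- shape[2]
  area <- if (is.null(mask)) H * W else sum(mask)
  pitch <- sqrt(2 * area / (sqrt(3) * n))
  if (pitch * (1 - 2 * sqrt(2) * jitter_frac) < 2 * radius + 2)
    stop("too many nuclei for lattice placement at this radius", call. = FALSE)
  with_seed(seed, {
    for (shrink in c(1, 0.95, 0.9, 0.85, 0.8)) {
      p <- pitch * shrink
      dy <- p * sqrt(3) / 2
      ys <- seq(radius + 1, H - radius, by = dy)
      pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
        off <- if (i %% 2 == 0) p / 2 else 0
        xs <- seq(radius + 1 + off, W - radius, by = p)
        cbind(x = xs, y = rep(ys[i], length(xs)))
      }))
      jit <- matrix(runif(2 * nrow(pts), -jitter_frac * p, jitter_frac * p),
                    ncol = 2)
      pts <- pts + jit
      pts[, 1] <- pmin(pmax(pts[, 1], radius + 1), W - radius)
      pts[, 2] <- pmin(pmax(pts[, 2], radius + 1), H - radius)
      if (!is.null(mask))
        pts <- pts[mask[cbind(round(pts[, 2]), round(pts[, 1]))], , drop = FALSE]
      if (nrow(pts) >= n) {
        ctr <- c((W + 1) / 2, (H + 1) / 2)
        d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
        sel <- order(d2)[seq_len(n)]
        out <- pts[sort(sel), , drop = FALSE]
        colnames(out) <- c("x", "y")
        return(out)
      }
    }
    stop(sprintf("lattice placement failed: could not fit %d nuclei", n),
         call. = FALSE)
  })
}

# Per-pixel nearest-nucleus labels (Voronoi partition; ties to the lowest
# cell id) and the nucleus disk labels.
voronoi_labels <- function(centers, shape, radius) {
  H <- shape[1]; W <- shape[2]
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  best <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- i
  }
  nuc <- matrix(0L, H, W)
  nuc[best <= radius^2] <- lab[best <= radius^2]
  list(cell = lab, nucleus = nuc)
}

#' Construct a phantom ground truth
#'
#' Defines the complete scene: focus surface, nucleus lattice, per-cell
#' compartment means with a target inter-channel Pearson correlation, and an
#' optional proximal enrichment of channel A near a vertical sheet border.
#' [render_stack()] turns it into a noisy defocused stack.
#'
#' Per-cell cytoplasm means are drawn from a bivariate normal with constant
#' coefficient of variation (A: mean 150, sd 30; B: mean 120, sd 24), floored
#' at 5; at `channel_corr = 1` the B means are exactly proportional to the A
#' means. Nucleoplasm means are the cytoplasm means scaled by independent
#' per-cell, per-channel factors in `[0.4, 1]`.
#'
#' @param shape frame size `c(H, W)` (default `c(128, 128)`).
#' @param n_cells number of cells (default 30).
#' @param nucleus_radius nucleus radius in px (default 6).
#' @param n_slices stack depth (default 21).
#' @param channel_corr target Pearson correlation between the per-cell
#'   cytoplasm means of the two protein channels, in `[-1, 1]` (default 0.5).
#' @param edge_enrichment multiplicative proximal factor for channel A near
#'   the border (default 1 = none); requires `border_x`.
#' @param border_x optional x-column of the sheet border; columns left of it
#'   are acellular (cut away).
#' @param coeffs focus-surface coefficient matrix (default: random via
#'   [random_focus_coeffs()], derived from `seed`).
#' @param pixel_size_um pixel size (default 1).
#' @param dapi_intensity nuclear DAPI level (default 200).
#' @param placement `"lattice"` (jittered hexagonal, the contact-inhibited
#'   default, via [place_nuclei_lattice()]) or `"random"` (rejection-sampled
#'   packing via [place_nuclei()]).
#' @param seed RNG seed.
#' @return an object of class `phantom_truth` with fields `centers`,
#'   `coeffs`, `surface`, `labels` (`cell`, `nucleus` ground-truth label
#'   matrices), `compartment_means` (per-cell data frame), `sheet` mask, and
#'   the scalar parameters.
#' @export
phantom_truth <- function(shape = c(128L, 128L), n_cells = 30L,
                          nucleus_radius = 6, n_slices = 21L,
                          channel_corr = 0.5, edge_enrichment = 1,
                          border_x = NULL, coeffs = NULL,
                          pixel_size_um = 1, dapi_intensity = 200,
                          placement = c("lattice", "random"), seed = NULL) {
  placement <- match.arg(placement)
  if (abs(channel_corr) > 1) stop("`channel_corr` must be in [-1, 1]", call. = FALSE)
  if (edge_enrichment < 0) stop("`edge_enrichment` must be >= 0", call. = FALSE)
  if (edge_enrichment != 1 && is.null(border_x))
    stop("edge enrichment requires `border_x`", call. = FALSE)
  if (is.null(coeffs))
    coeffs <- random_focus_coeffs(shape, n_slices,
                                  seed = if (is.null(seed)) NULL else seed + 1L)
  surface <- make_focus_surface(coeffs, shape)
  if (min(surface) < 1 || max(surface) > n_slices)
    stop("focus surface leaves the slice range [1, n_slices]", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  sheet <- matrix(TRUE, H, W)
  if (!is.null(border_x)) sheet[, seq_len(W) < border_x] <- FALSE
  pmask <- if (is.null(border_x)) NULL else sheet
  pseed <- if (is.null(seed)) NULL else seed + 2L
  centers <- if (placement == "lattice")
    place_nuclei_lattice(n_cells, shape, nucleus_radius, seed = pseed, mask = pmask)
  else
    place_nuclei(n_cells, shape, nucleus_radius, seed = pseed, mask = pmask)
  labs <- voronoi_labels(centers, shape, nucleus_radius)
  labs$cell[!sheet] <- 0L
  labs$nucleus[!sheet] <- 0L
  means <- with_seed(if (is.null(seed)) NULL else seed + 3L, {
    z1 <- rnorm(n_cells)
    z2 <- rnorm(n_cells)
    zb <- channel_corr * z1 + sqrt(1 - channel_corr^2) * z2
    cyt_A <- pmax(150 + 30 * z1, 5)
    cyt_B <- pmax(120 + 24 * zb, 5)
    data.frame(cell_id = seq_len(n_cells),
               A_nuc = cyt_A * runif(n_cells, 0.4, 1),
               A_cyt = cyt_A,
               B_nuc = cyt_B * runif(n_cells, 0.4, 1),
               B_cyt = cyt_B)
  })
  structure(
    list(shape = as.integer(shape), n_cells = as.integer(n_cells),
         nucleus_radius = nucleus_radius, n_slices = as.integer(n_slices),
         channel_corr = channel_corr, edge_enrichment = edge_enrichment,
         border_x = border_x, coeffs = coeffs, surface = surface,
         centers = centers, labels = labs, sheet = sheet,
         compartment_means = means, pixel_size_um = pixel_size_um,
         dapi_intensity = dapi_intensity, seed = seed),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %dx%d px, %d slices, %d cells (r = %g px), channel corr %.2f\n",
              x$shape[1], x$shape[2], x$n_slices, x$n_cells, x$nucleus_radius,
              x$channel_corr))
  invisible(x)
}

# Noise-free sharp 2D scenes (one matrix per channel), piecewise constant on
# the ground-truth compartments.
phantom_scene <- function(truth) {
  m <- truth$compartment_means
  lab_c <- truth$labels$cell
  lab_n <- truth$labels$nucleus
  lut <- function(nuc, cyt) {
    img <- matrix(0, truth$shape[1], truth$shape[2])
    inc <- lab_c > 0L
    img[inc] <- cyt[lab_c[inc]]
    inn <- lab_n > 0L
    img[inn] <- nuc[lab_n[inn]]
    img
  }
  A <- lut(m$A_nuc, m$A_cyt)
  B <- lut(m$B_nuc, m$B_cyt)
  dapi <- matrix(0, truth$shape[1], truth$shape[2])
  dapi[lab_n > 0L] <- truth$dapi_intensity
  if (!is.null(truth$border_x) && truth$edge_enrichment != 1) {
    d_um <- (matrix(rep(seq_len(truth$shape[2]), each = truth$shape[1]),
                    truth$shape[1], truth$shape[2]) - truth$border_x) *
            truth$pixel_size_um
    A <- A * edge_ramp(d_um, truth$edge_enrichment)
  }
  list(dapi = dapi, proteinA = A, proteinB = B)
}

# Proximal enrichment profile: factor for d <= 30 um, linear ramp down to 1
# between 30 and 40 um, 1 beyond.
edge_ramp <- function(d_um, factor) {
  g <- matrix(1, nrow(d_um), ncol(d_um))
  g[d_um <= 30] <- factor
  mid <- d_um > 30 & d_um < 40
  g[mid] <- factor + (1 - factor) * (d_um[mid] - 30) / 10
  g
}

#' Render a phantom stack
#'
#' Turns a [phantom_truth()] into a defocused, noisy multichannel stack. Each
#' slice k is the sharp scene blurred with a per-pixel Gaussian sd
#' proportional to the defocus distance `|k - z_f(x, y)|` (approximated by
#' blending a bank of uniformly blurred scenes at integer sd levels), after
#' which Poisson scaling and additive Gaussian noise are applied. With zero
#' noise and a flat integer surface at slice k, slice k equals the sharp scene
#' exactly.
#'
#' @param truth a [phantom_truth()].
#' @param noise `c(gauss_sd, poisson_scale)`: additive Gaussian sd in
#'   intensity units and Poisson photon scale (0 disables either term).
#' @param defocus_scale blur sd per slice of defocus, in px (default 1.2).
#' @param seed RNG seed for the noise (defaults to the truth's seed).
#' @return list with `stack` (an [image_stack]) and `truth` (unchanged).
#' @export
render_stack <- function(truth, noise = c(gauss_sd = 15, poisson_scale = 0),
                         defocus_scale = 1.2, seed = truth$seed) {
  stopifnot(inherits(truth, "phantom_truth"))
  scene <- phantom_scene(truth)
  nz <- truth$n_slices
  zf <- truth$surface
  sd_max <- defocus_scale * max(pmax(abs(1 - zf), abs(nz - zf)))
  n_lev <- ceiling(sd_max) + 1L
  channels <- lapply(scene, function(img) {
    bank <- vector("list", n_lev + 1L)
    bank[[1]] <- img
    for (l in seq_len(n_lev)) bank[[l + 1]] <- gauss_smooth(img, l)
    arr <- array(0, dim = c(truth$shape, nz))
    for (k in seq_len(nz)) {
      sdm <- defocus_scale * abs(k - zf)
      fl <- floor(sdm)
      fr <- sdm - fl
      sl <- matrix(0, truth$shape[1], truth$shape[2])
      for (l in sort(unique(as.vector(fl)))) {
        sel <- fl == l
        sl[sel] <- bank[[l + 1]][sel] * (1 - fr[sel]) + bank[[l + 2]][sel] * fr[sel]
      }
      arr[, , k] <- sl
    }
    arr
  })
  channels <- with_seed(seed, {
    lapply(channels, function(arr) {
      if (noise[2] > 0)
        arr[] <- rpois(length(arr), pmax(arr, 0) * noise[2]) / noise[2]
      if (noise[1] > 0)
        arr[] <- arr + rnorm(length(arr), sd = noise[1])
      pmax(arr, 0)
    })
  })
  list(stack = image_stack(channels, truth$pixel_size_um), truth = truth)
}

#' Correlated image pair
#'
#' Two Gaussian white-noise images whose generating variables have exactly the
#' target correlation `rho`; the sample pixelwise Pearson correlation
#' converges to `rho` as the pixel count grows. At `rho = 1` the second image
#' is an exact affine copy of the first.
#'
#' @param rho target correlation in `[-1, 1]`.
#' @param shape frame size `c(H, W)`.
#' @param seed RNG seed.
#' @param mean,sd marginal intensity mean and sd (defaults 100 and 20).
#' @return list of two numeric matrices `A`, `B`.
#' @export
make_correlated_pair <- function(rho, shape, seed = NULL, mean = 100, sd = 20) {
  if (abs(rho) > 1) stop("`rho` must be in [-1, 1]", call. = FALSE)
  with_seed(seed, {
    n <- shape[1] * shape[2]
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    zb <- rho * z1 + sqrt(1 - rho^2) * z2
    list(A = matrix(mean + sd * z1, shape[1], shape[2]),
         B = matrix(mean + sd * zb, shape[1], shape[2]))
  })
}

#' Wound-edge intensity phantom
#'
#' A 2D fixture for the edge-profile analysis: zero left of the border
#' column, `base * factor` in the proximal band (0-30 um), a linear ramp from
#' `base * factor` to `base` between 30 and 40 um, and `base` beyond. By
#' construction the interval fraction over the standard proximal (5-30 um)
#' and distal (50-80 um) bands is `factor / (factor + 1)`.
#'
#' @param factor proximal enrichment factor (>= 0).
#' @param border_x border column (px).
#' @param shape frame size `c(H, W)`.
#' @param pixel_size_um pixel size (default 1).
#' @param base distal intensity level (default 100).
#' @return numeric matrix.
#' @export
make_edge_phantom <- function(factor, border_x, shape, pixel_size_um = 1,
                              base = 100) {
  if (factor < 0) stop("`factor` must be >= 0", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  d_um <- (matrix(rep(seq_len(W), each = H), H, W) - border_x) * pixel_size_um
  img <- base * edge_ramp(d_um, factor)
  img[d_um < 0] <- 0
  img
}
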