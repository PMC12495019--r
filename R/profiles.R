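# Wound-edge spatial analysis: profiles of vertically averaged intensity as a
# function of distance from the border, interval fractions, normalized
# profiles, cross-sample aggregation, and destruction areas.

#' Rotate an image to align the cut vertically
#'
#' Bilinear rotation about the frame center. The rotation angle may be given
#' directly or derived from a border polyline (the principal direction of the
#' points is brought to vertical). Pixels mapped from outside the frame are
#' set to zero; a zero angle is an exact identity.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees (features rotate by this angle).
#' @param border_polyline optional `n x 2` matrix of `(x, y)` points (n >= 2);
#'   used to derive the angle and the border column.
#' @return list with `image`, `angle_deg`, and `border_x` (mean rotated
#'   polyline x, or `NA` when no polyline was given).
#' @export
align_cut_vertical <- function(img, angle_deg = NULL, border_polyline = NULL) {
  check_matrix(img)
  if (is.null(angle_deg) && is.null(border_polyline))
    stop("give either `angle_deg` or `border_polyline`", call. = FALSE)
  if (!is.null(border_polyline)) {
    pts <- as.matrix(border_polyline)
    if (nrow(pts) < 2L)
      stop("`border_polyline` needs at least 2 points", call. = FALSE)
    if (all(apply(pts, 2, function(v) diff(range(v)) == 0)))
      stop("degenerate polyline: all points coincide", call. = FALSE)
    if (is.null(angle_deg)) {
      v <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
      angle_deg <- atan2(v[1], v[2]) * 180 / pi
    }
  }
  rot <- rotate_bilinear(img, angle_deg)
  border_x <- NA_real_
  if (!is.null(border_polyline)) {
    ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
    th <- angle_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rp <- sweep(as.matrix(border_polyline), 2, ctr) %*% t(R)
    border_x <- mean(rp[, 1] + ctr[1])
    attr(border_x, "rotated_polyline") <- sweep(rp, 2, ctr, `+`)
  }
  list(image = rot, angle_deg = angle_deg, border_x = border_x)
}

# Bilinear rotation of image content by `angle_deg` about the frame center
# (inverse mapping); out-of-frame samples are zero.
rotate_bilinear <- function(img, angle_deg) {
  if (angle_deg %% 360 == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  th <- -angle_deg * pi / 180   # inverse rotation
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), W), H, W) - cy
  sx <- cos(th) * xs - sin(th) * ys + cx
  sy <- sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  sample_at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- matrix(0, H, W)
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- sample_at(y0, x0);     v01 <- sample_at(y0, x0 + 1)
  v10 <- sample_at(y0 + 1, x0); v11 <- sample_at(y0 + 1, x0 + 1)
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

#' Distance-binned vertical-average intensity profile
#'
#' Averages each image column over the rows, converts column position to
#' distance from the border (`(x - border_x) * pixel_size_um`), and resamples
#' the non-negative-distance part into half-open `[k b, (k+1) b)` bins of
#' width `bin_um` by averaging member columns.
#'
#' @param img numeric matrix (one channel, cut aligned vertically, tissue to
#'   the right of the border).
#' @param border_x border column in px (may be fractional).
#' @param pixel_size_um pixel size in micrometres.
#' @param bin_um bin width in micrometres (default 5).
#' @return an `edge_profile` data frame with columns `bin_lo`, `bin_hi`,
#'   `distance` (bin center, um) and `value`.
#' @export
vertical_profile <- function(img, border_x, pixel_size_um, bin_um = 5) {
  check_matrix(img)
  if (border_x < 1 || border_x >= ncol(img))
    stop("border outside the frame: no positive-distance domain", call. = FALSE)
  d <- (seq_len(ncol(img)) - border_x) * pixel_size_um
  keep <- d >= 0
  if (!any(keep))
    stop("no columns at non-negative distance from the border", call. = FALSE)
  cm <- colMeans(img)[keep]
  bin <- floor(d[keep] / bin_um)
  val <- tapply(cm, bin, mean)
  lo <- as.numeric(names(val)) * bin_um
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_um,
                    distance = lo + bin_um / 2,
                    value = as.numeric(val), row.names = NULL)
  structure(out, class = c("edge_profile", "data.frame"),
            bin_um = bin_um, pixel_size_um = pixel_size_um, border_x = border_x)
}

profile_band_mean <- function(profile, band) {
  sel <- profile$bin_lo >= band[1] - 1e-9 & profile$bin_hi <= band[2] + 1e-9
  if (!any(sel))
    stop(sprintf("profile does not cover the [%g, %g] um band", band[1], band[2]),
         call. = FALSE)
  mean(profile$value[sel])
}

#' Interval fraction of an edge profile
#'
#' `IF = <P>_proximal / (<P>_proximal + <P>_distal)` over the proximal
#' (5-30 um) and distal (50-80 um) bands, each mean taken over the 5-um bin
#' averages. The 0-5 um ramp and the 30-50 um transitional band are excluded.
#' 0.5 means equidistribution; values above 0.5 indicate proximal
#' accumulation. Invariant to global intensity scaling.
#'
#' @param profile an [vertical_profile()] result.
#' @param proximal,distal band limits in um.
#' @return list with `mean_prox`, `mean_dist`, `IF` (`NA` with a warning when
#'   both band means are zero).
#' @export
interval_fraction <- function(profile, proximal = c(5, 30), distal = c(50, 80)) {
  p <- profile_band_mean(profile, proximal)
  d <- profile_band_mean(profile, distal)
  if (p + d == 0) {
    warning("both interval means are zero; IF undefined")
    return(list(mean_prox = p, mean_dist = d, IF = NA_real_))
  }
  list(mean_prox = p, mean_dist = d, IF = p / (p + d))
}

#' Normalize a profile by its domain average
#'
#' Divides the profile by its mean over the `[0, 80]` um domain (bin
#' averages), so the normalized profile has domain mean exactly 1. Removes
#' inter-sample intensity variability before cross-sample comparison.
#'
#' @param profile an [vertical_profile()] result.
#' @param domain normalization domain in um (default `c(0, 80)`).
#' @return the profile with `value` rescaled.
#' @export
normalize_profile <- function(profile, domain = c(0, 80)) {
  m <- profile_band_mean(profile, domain)
  if (m == 0) stop("profile mean over the domain is zero; cannot normalize",
                   call. = FALSE)
  profile$value <- profile$value / m
  profile
}

#' Aggregate profiles across samples
#'
#' Per 5-um bin: number of contributing samples, mean, sample SD (`n - 1`
#' denominator) and SEM (`SD / sqrt(n)`). Bins present in fewer than two
#' samples get `NA` SD and SEM.
#'
#' @param profiles list of [vertical_profile()] results.
#' @return data frame with `bin_lo`, `distance`, `n`, `mean`, `sd`, `sem`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  all_lo <- sort(unique(unlist(lapply(profiles, `[[`, "bin_lo"))))
  rows <- lapply(all_lo, function(lo) {
    v <- unlist(lapply(profiles, function(p) p$value[p$bin_lo == lo]))
    n <- length(v)
    s <- if (n >= 2) sd(v) else NA_real_
    data.frame(bin_lo = lo, distance = lo + attr(profiles[[1]], "bin_um") / 2,
               n = n, mean = mean(v), sd = s, sem = s / sqrt(n))
  })
  do.call(rbind, rows)
}

#' Cell destruction area between two polylines
#'
#' Area of the polygon formed by the cut polyline, the reversed border
#' polyline and the two closing segments, by the shoelace formula (px^2).
#' Both polylines must be ordered along the same axis; a self-intersecting
#' closure is rejected.
#'
#' @param cut_polyline,border_polyline `n x 2` matrices of `(x, y)` points.
#' @return area in px^2.
#' @export
destruction_area <- function(cut_polyline, border_polyline) {
  cutp <- as.matrix(cut_polyline)
  bord <- as.matrix(border_polyline)
  if (ncol(cutp) != 2L || ncol(bord) != 2L)
    stop("polylines must be n x 2 matrices of (x, y) points", call. = FALSE)
  poly <- rbind(cutp, bord[rev(seq_len(nrow(bord))), , drop = FALSE])
  if (polygon_self_intersects(poly))
    stop("cut and border polylines produce a self-intersecting closure; check their ordering",
         call. = FALSE)
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

# Strict (proper) crossing test between non-adjacent polygon edges.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next   # adjacent through closure
      o1 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      o2 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      o3 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      o4 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' @export
plot.edge_profile <- function(x, ..., xlab = "distance from border (um)",
                              ylab = "mean intensity") {
  graphics::plot(x$distance, x$value, type = "b", pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = c(5, 30, 50, 80), lty = 3, col = "grey50")
  invisible(x)
}
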