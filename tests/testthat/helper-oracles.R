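# Naive reference implementations, independent of the compiled kernels.
# Deliberately simple (shift-and-reduce or per-pixel loops) so they can serve
# as oracles for the morphology, gradient and interpolation operators.

shift_pad <- function(img, dy, dx, fill) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
  okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
  out[okY, okX] <- img[ys[okY], xs[okX]]
  out
}

oracle_minmax <- function(img, r, take_max) {
  ri <- ceiling(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, ]
  fill <- if (take_max) -Inf else Inf
  acc <- matrix(fill, nrow(img), ncol(img))
  for (i in seq_len(nrow(off))) {
    s <- shift_pad(img, off$dy[i], off$dx[i], fill)
    acc <- if (take_max) pmax(acc, s) else pmin(acc, s)
  }
  acc
}

oracle_edt <- function(mask) {
  tr <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (y in seq_len(nrow(mask))) {
    for (x in seq_len(ncol(mask))) {
      out[y, x] <- sqrt(min((tr[, 1] - y)^2 + (tr[, 2] - x)^2))
    }
  }
  out
}

oracle_dilate8 <- function(img) {
  acc <- img
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- pmax(acc, shift_pad(img, dy, dx, -Inf))
  }
  acc
}

# Grayscale reconstruction by iterative geodesic dilation until stability.
oracle_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    J2 <- pmin(oracle_dilate8(J), mask)
    if (identical(J2, J)) return(J)
    J <- J2
  }
}

oracle_hmax <- function(img, h) oracle_reconstruct(img - h, img)

oracle_sobel <- function(img) {
  H <- nrow(img); W <- ncol(img)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- t(kx)
  pad <- function(y, x) img[min(max(y, 1), H), min(max(x, 1), W)]
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      gx <- 0; gy <- 0
      for (j in -1:1) for (i in -1:1) {
        v <- pad(y + j, x + i)
        gx <- gx + kx[j + 2, i + 2] * v
        gy <- gy + ky[j + 2, i + 2] * v
      }
      out[y, x] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

oracle_poly_eval <- function(coeffs, shape) {
  H <- shape[1]; W <- shape[2]
  xs <- if (W > 1) 2 * (seq_len(W) - 1) / (W - 1) - 1 else 0
  ys <- if (H > 1) 2 * (seq_len(H) - 1) / (H - 1) - 1 else 0
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    s <- 0
    for (a in 0:(nrow(coeffs) - 1)) for (b in 0:(ncol(coeffs) - 1)) {
      s <- s + coeffs[a + 1, b + 1] * xs[x]^a * ys[y]^b
    }
    out[y, x] <- s
  }
  out
}

# Mean intersection-over-union of recovered vs true cell masks, matching each
# true cell to the recovered label with the largest overlap.
mean_cell_iou <- function(cell_id, truth) {
  mean(sapply(seq_len(truth$n_cells), function(i) {
    tmask <- truth$labels$cell == i
    ids <- cell_id[tmask]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(0)
    j <- as.integer(names(which.max(table(ids))))
    smask <- cell_id == j
    sum(smask & tmask) / sum(smask | tmask)
  }))
}
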