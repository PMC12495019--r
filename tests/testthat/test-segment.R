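test_that("background removal keeps sub-radius objects and clips at zero", {
  expect_equal(remove_background(matrix(5, 32, 32))$nuc, matrix(0, 32, 32))
  img <- matrix(0, 48, 48)
  d <- oracle_minmax(`[<-`(matrix(0, 48, 48), 24, 24, 1), 4, TRUE)  # disk r=4
  img <- 100 * d
  bg <- remove_background(img)
  expect_gt(max(bg$nuc), 0.25 * max(img))   # small disk survives subtraction
  expect_true(all(bg$nuc >= 0))
  expect_error(remove_background(img, sigma_n = 0), "positive")
})

test_that("local contrast adjustment flattens a representable surface", {
  s <- make_focus_surface(`[<-`(matrix(0, 6, 6), 1, 1, 4) +
                          `[<-`(matrix(0, 6, 6), 2, 1, 1), c(32, 32))  # 4 + xhat
  lca <- local_contrast_adjust(s)
  expect_equal(lca$F_nuc, s, tolerance = 1e-6)
  expect_equal(lca$lca[s > 1], rep(1, sum(s > 1)), tolerance = 1e-6)
  expect_error(local_contrast_adjust(matrix(0, 16, 16)), "all-zero")
})

test_that("self-weighted degree-2 fit matches a direct normal-equations solve", {
  set.seed(17)
  img <- matrix(runif(30 * 26), 30, 26)
  fit <- epifocus:::wls_poly_surface(img, img, 2L)
  # independent dense solve
  xs <- 2 * (seq_len(26) - 1) / 25 - 1
  ys <- 2 * (seq_len(30) - 1) / 29 - 1
  X <- NULL
  for (a in 0:2) for (b in 0:(2 - a))
    X <- cbind(X, as.vector(outer(ys^b, xs^a)))
  w <- as.vector(img)
  beta <- solve(t(X) %*% (X * w), t(X) %*% (w * as.vector(img)))
  expect_equal(as.vector(fit$surface), as.vector(X %*% beta), tolerance = 1e-8)
})

test_that("two identical nuclei under an illumination ramp equalize after LCA", {
  xs <- seq_len(96)
  bump <- function(cx) exp(-(outer(xs, xs, function(y, x)
    (x - cx)^2 + (y - 48)^2)) / 30)
  ramp <- outer(rep(1, 96), 1 + (xs - 1) / 95)        # 1x to 2x left to right
  img <- (bump(24) + bump(72)) * ramp
  lca <- local_contrast_adjust(img)$lca
  # compare at the nucleus centers: the ratio is only meaningful where
  # nuclear signal exists (the fitted surface crosses zero in the background)
  p1 <- lca[48, 24]; p2 <- lca[48, 72]
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.10)
})

test_that("nuclear markers isolate distinct bumps and drop shallow ones", {
  xs <- seq_len(64)
  bump <- function(c, h = 1) h * exp(-(outer(xs, xs, function(y, x)
    (x - c[1])^2 + (y - c[2])^2)) / 16)
  img <- pmax(bump(c(20, 32)), bump(c(44, 32)))
  nm <- nuclear_markers(img)
  expect_equal(max(label_components(nm$B_nuc, 8)), 2L)
  nm1 <- nuclear_markers(bump(c(32, 32)))
  expect_equal(max(label_components(nm1$B_nuc, 8)), 1L)
})

test_that("extranuclear marker is the eroded below-median mask", {
  img <- cbind(matrix(0, 20, 10), matrix(10, 20, 10))
  ex <- extranuclear_marker(img)
  expect_true(all(!ex[, 11:20]))
  expect_true(any(ex[, 1:8]))
  set.seed(19)
  r <- matrix(runif(24 * 24), 24, 24)
  low <- r <= quantile(r, 0.5, type = 7)
  expect_equal(extranuclear_marker(r),
               oracle_minmax(low + 0, 2, FALSE) > 0.5)
})

test_that("first watershed finds one region per nucleus around its center", {
  tr <- small_truth(2)
  r <- render_stack(tr, noise = c(0, 0))
  fc <- focal_correct(r$stack)
  seg <- segment_cells(fc$image)
  expect_equal(max(seg$intermediates$L1) - 1L, tr$n_cells)
  L1 <- seg$intermediates$L1
  for (i in seq_len(tr$n_cells)) {
    cx <- round(tr$centers[i, 1]); cy <- round(tr$centers[i, 2])
    expect_gt(L1[cy, cx], 1L)     # generating disk center inside a nucleus label
  }
  expect_warning(
    L1e <- watershed_nuclei(matrix(0, 16, 16), matrix(FALSE, 16, 16),
                            matrix(TRUE, 16, 16)),
    "no nuclear markers")
  expect_true(all(L1e == 1L))
})

test_that("internuclear distance tracks the lattice half-pitch", {
  p <- 20
  mask <- matrix(FALSE, 100, 100)
  mask[cbind(rep(seq(10, 90, p), each = 5), rep(seq(10, 90, p), 5))] <- TRUE
  d_avg <- suppressWarnings(estimate_internuclear_distance(mask))
  # independent raw-histogram mode
  dmap <- oracle_edt(mask)
  v <- dmap[dmap > 0]
  raw_mode <- which.max(tabulate(floor(v) + 1L)) - 1L + 0.5
  d_raw <- estimate_internuclear_distance(mask, smooth_sd = 0)
  expect_equal(d_raw, raw_mode)
  expect_lt(abs(d_avg - p / 2), 2.5)
  expect_error(estimate_internuclear_distance(matrix(TRUE, 8, 8)), "whole frame")
})

test_that("void marker flags wide cell-free bands but not confluent sheets", {
  tr <- small_truth(5)
  B_cell <- tr$labels$nucleus > 0
  d_avg <- estimate_internuclear_distance(B_cell)
  expect_equal(sum(void_marker(B_cell, d_avg) & B_cell), 0L)
  # a frame whose right 60% is cell-free
  mask2 <- matrix(FALSE, 100, 160)
  mask2[cbind(rep(seq(10, 90, 20), each = 3), rep(c(10, 30, 50), 5))] <- TRUE
  mask2 <- oracle_minmax(mask2 + 0, 4, TRUE) > 0.5
  v <- void_marker(mask2, 10)
  expect_gt(sum(v[, 100:160]), 500)     # band interior detected
  expect_equal(sum(v & mask2), 0L)
})

test_that("second watershed pairs every cell with exactly one nucleus", {
  tr <- small_truth(7)
  r <- render_stack(tr, noise = c(0, 0))
  fc <- focal_correct(r$stack)
  seg <- segment_cells(fc$image)
  L1 <- seg$intermediates$L1; L2 <- seg$intermediates$L2
  expect_equal(max(L2) - 1L, max(L1) - 1L)        # count conservation
  for (id in 2:max(L2)) {
    nuc_ids <- unique(L1[L2 == id & L1 > 1])
    expect_equal(nuc_ids, id)
  }
  # no void marker: every pixel belongs to a cell
  L2b <- watershed_cells(fc$image$channels$proteinA, fc$image$channels$proteinB,
                         L1, B_void = NULL)
  expect_true(all(L2b > 1L))
})

test_that("compartments partition the frame and measurements are consistent", {
  tr <- small_truth(10)
  r <- render_stack(tr, noise = c(0, 0))
  fc <- focal_correct(r$stack)
  seg <- segment_cells(fc$image)
  lab <- seg$labels
  expect_equal(lab$cell_count, tr$n_cells)
  # partition: compartment none <=> acellular; nucleus/cyt inside cells only
  expect_true(all((lab$compartment == 0) == (lab$cell_id == 0)))
  # each cell has exactly one 4-connected nucleus region
  for (i in unique(lab$cell_id[lab$cell_id > 0])) {
    nuc_i <- lab$cell_id == i & lab$compartment == 1L
    expect_equal(max(label_components(nuc_i, 4)), 1L)
  }
  # uniform channel: all cytoplasm means equal
  u <- matrix(3, 96, 96)
  tab_u <- measure_compartments(tr$labels$nucleus, tr$labels$cell, u, u)
  expect_equal(tab_u$A_cyt, rep(3, tr$n_cells))
})

test_that("noise-free segmentation recovers compartment means within 5%", {
  tr <- small_truth(11)
  r <- render_stack(tr, noise = c(0, 0))
  fc <- focal_correct(r$stack)
  seg <- segment_cells(fc$image)
  truthm <- tr$compartment_means
  # match by centroid proximity to true centers
  match_id <- sapply(seq_len(nrow(seg$table)), function(j) {
    which.min((tr$centers[, 1] - seg$table$centroid_x[j])^2 +
              (tr$centers[, 2] - seg$table$centroid_y[j])^2)
  })
  expect_equal(sort(match_id), seq_len(tr$n_cells))
  # cytoplasm regions are large (>= 200 px): per-cell means within 5%
  relerr <- abs(seg$table$A_cyt - truthm$A_cyt[match_id]) / truthm$A_cyt[match_id]
  expect_lt(max(relerr), 0.05)
  # nucleoplasm regions are small (~80 px) and carry the optical-sectioning
  # bias of residual defocus at the border; bounded rather than tight
  relerr_n <- abs(seg$table$A_nuc - truthm$A_nuc[match_id]) / truthm$A_nuc[match_id]
  expect_lt(max(relerr_n), 0.15)
  expect_lt(mean(relerr_n), 0.05)
})
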