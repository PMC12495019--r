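test_that("Sobel gradient: constant images, step edges, and the conv oracle", {
  expect_equal(sobel_gradient(matrix(4, 8, 8)), matrix(0, 8, 8))
  h <- 3.5
  step <- cbind(matrix(0, 10, 5), matrix(h, 10, 5))
  g <- sobel_gradient(step)
  expect_equal(g[, 5], rep(4 * h, 10))   # unnormalized Sobel on a step edge
  expect_equal(g[, 6], rep(4 * h, 10))
  expect_equal(g[, 2], rep(0, 10))
  set.seed(13)
  img <- matrix(rnorm(15 * 11), 15, 11)
  expect_equal(sobel_gradient(img), oracle_sobel(img), tolerance = 1e-12)
})

test_that("max gradient projection takes the per-pixel max with low-z ties", {
  arr <- array(0, dim = c(8, 8, 6))
  arr[, , 3][4, 4] <- 5                       # structure only in slice 3
  proj <- max_gradient_projection(arr)
  expect_true(all(proj$z_m[proj$M > 0] == 3))
  # equal gradients in slices 2 and 5: argmax stays at 2
  arr2 <- array(0, dim = c(8, 8, 6))
  arr2[, , 2][4, 4] <- 5
  arr2[, , 5][4, 4] <- 5
  zm2 <- max_gradient_projection(arr2)$z_m
  expect_true(all(zm2[cbind(c(4, 4, 3, 5), c(3, 5, 4, 4))] == 2))
  # random stack vs per-pixel loop oracle
  set.seed(9)
  arr3 <- array(runif(10 * 9 * 4), dim = c(10, 9, 4))
  proj3 <- max_gradient_projection(arr3)
  g <- sapply(1:4, function(k) sobel_gradient(arr3[, , k]), simplify = "array")
  for (y in 1:10) for (x in 1:9) {
    expect_equal(proj3$M[y, x], max(g[y, x, ]))
    expect_equal(proj3$z_m[y, x], which.max(g[y, x, ]))
  }
})

test_that("weight thresholding zeroes exactly the sub-threshold pixels", {
  eq <- matrix(7, 5, 5)
  expect_equal(threshold_weights(eq), eq)     # threshold = 0.1 * value
  m <- matrix(1:100, 10, 10)
  w <- threshold_weights(m)
  th <- 0.1 * quantile(1:100, 0.99, type = 7)
  expect_equal(sum(w > 0), sum(1:100 >= th))
  expect_true(all(w[w > 0] == m[m >= th]))
  z <- matrix(0, 6, 6)
  expect_equal(threshold_weights(z), z)
})

test_that("manifold fit recovers representable surfaces and ignores zero weights", {
  set.seed(21)
  coeffs <- matrix(0, 6, 6)
  for (a in 0:5) for (b in 0:(5 - a)) coeffs[a + 1, b + 1] <- rnorm(1) / (1 + a + b)
  z <- make_focus_surface(coeffs, c(24, 24))
  fit <- fit_focus_manifold(z, matrix(1, 24, 24))
  expect_lt(sqrt(mean((fit$z_f - z)^2)), 1e-8)
  # plane plus zero-weighted outliers: plane recovered exactly
  plane <- make_focus_surface(rbind(c(2, 0.5, 0, 0, 0, 0), matrix(0, 5, 6)) +
                              cbind(c(0, 1, 0, 0, 0, 0), matrix(0, 6, 5)),
                              c(20, 20))
  zo <- plane
  w <- matrix(1, 20, 20)
  out_idx <- cbind(c(3, 7, 15), c(4, 12, 18))
  zo[out_idx] <- 99
  w[out_idx] <- 0
  fit2 <- fit_focus_manifold(zo, w, degree = 1)
  expect_equal(fit2$z_f, plane, tolerance = 1e-8)
})

test_that("degenerate weight layouts give an explicit fit failure", {
  z <- matrix(5, 16, 16)
  w <- matrix(0, 16, 16)
  w[, 4] <- 1    # all weight on one column: x terms unconstrained
  expect_error(fit_focus_manifold(z, w, degree = 2), "rank-deficient")
  expect_error(fit_focus_manifold(z, matrix(0, 16, 16)), "positive weight")
})

test_that("interpolation on the manifold is exact for flat and bracketing cases", {
  arr <- array(0, dim = c(6, 6, 4))
  for (k in 1:4) arr[, , k] <- k * 10
  stk <- image_stack(list(dapi = arr), 1)
  flat2 <- list(z_f = matrix(2, 6, 6))
  out <- interpolate_on_manifold(stk, flat2)
  expect_identical(out$channels$dapi, arr[, , 2])
  mid <- list(z_f = matrix(1.5, 6, 6))
  expect_equal(interpolate_on_manifold(stk, mid)$channels$dapi, matrix(15, 6, 6))
  # random in-range surface vs scalar two-point interpolation oracle
  set.seed(5)
  arr2 <- array(runif(6 * 5 * 4), dim = c(6, 5, 4))
  stk2 <- image_stack(list(dapi = arr2), 1)
  zf <- matrix(runif(30, 1, 4), 6, 5)
  got <- interpolate_on_manifold(stk2, list(z_f = zf))$channels$dapi
  for (y in 1:6) for (x in 1:5) {
    k0 <- floor(zf[y, x]); f <- zf[y, x] - k0
    expect_equal(got[y, x], arr2[y, x, k0] * (1 - f) + arr2[y, x, min(k0 + 1, 4)] * f)
  }
})

test_that("focal correction of an already-flat stack returns the slice bit-exactly", {
  cf <- matrix(0, 6, 6); cf[1, 1] <- 4
  trf <- phantom_truth(shape = c(96, 96), n_cells = 12, nucleus_radius = 5,
                       n_slices = 9, coeffs = cf, seed = 3)
  scene <- epifocus:::phantom_scene(trf)
  rep_slices <- function(m, nz = 5) array(rep(m, nz), dim = c(dim(m), nz))
  stk <- image_stack(lapply(scene, rep_slices), 1)
  fc <- focal_correct(stk)
  expect_identical(fc$image$channels$dapi, scene$dapi)
  expect_identical(fc$image$channels$proteinA, scene$proteinA)
  # rendered flat-manifold stack, zero noise: the designated slice is the
  # sharp scene and interpolation on the true manifold returns it bit-exactly
  r <- render_stack(trf, noise = c(0, 0))
  out <- interpolate_on_manifold(r$stack, list(z_f = trf$surface))
  expect_identical(out$channels$proteinA, scene$proteinA)
})

test_that("in-focus DAPI is at least as sharp as every raw slice", {
  r <- small_stack(8, noise = c(0, 0))
  fc <- focal_correct(r$stack)
  sharp <- mean(sobel_gradient(fc$image$channels$dapi))
  per_slice <- sapply(seq_len(dim(r$stack)[3]),
                      function(k) mean(sobel_gradient(r$stack$channels$dapi[, , k])))
  expect_true(all(sharp >= per_slice))
})

test_that("raising the weight threshold factor never adds influential pixels", {
  r <- small_stack(4)
  proj <- max_gradient_projection(r$stack$channels$dapi)
  sets <- lapply(c(0.05, 0.1, 0.2, 0.4),
                 function(f) which(threshold_weights(proj$M, factor = f) > 0))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("manifold recovery on rendered phantoms stays within half a slice", {
  tr <- small_truth(12)
  r <- render_stack(tr, noise = c(10, 0))
  fc <- focal_correct(r$stack)
  sel <- fc$manifold$weights > 0
  expect_lt(sqrt(mean((fc$manifold$z_f[sel] - tr$surface[sel])^2)), 0.5)
})
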