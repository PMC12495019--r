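test_that("rotation: identity at zero, quarter turns, polyline-derived angle", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  expect_identical(align_cut_vertical(img, angle_deg = 0)$image, img)
  stripes <- matrix(rep(c(0, 1), each = 20), 40, 40)        # horizontal bands
  rot <- align_cut_vertical(stripes, angle_deg = 90)$image
  inner <- rot[10:30, 10:30]
  expect_lt(max(abs(inner - matrix(rep(inner[1, ], each = 21), 21))), 1e-9)
  # synthetic border at 30 degrees from vertical
  ys <- seq(5, 95, by = 5)
  pts <- cbind(x = 50 + tan(30 * pi / 180) * (ys - 50), y = ys)
  al <- align_cut_vertical(matrix(0, 100, 100), border_polyline = pts)
  rp <- attr(al$border_x, "rotated_polyline")
  slope <- abs(coef(lm(rp[, 1] ~ rp[, 2]))[2])
  expect_lt(slope, 0.05)
  expect_error(align_cut_vertical(img, border_polyline = rbind(c(3, 3))),
               "at least 2 points")
})

test_that("vertical profile bins column means at 5-um resolution", {
  u <- matrix(7, 20, 100)
  p <- vertical_profile(u, border_x = 10, pixel_size_um = 1)
  expect_true(all(p$value == 7))
  expect_equal(diff(p$bin_lo)[1], 5)
  # column ramp: bin means equal analytic averages of member columns
  ramp <- matrix(rep(seq_len(100), each = 20), 20, 100)
  pr <- vertical_profile(ramp, border_x = 10, pixel_size_um = 1)
  first_bin_cols <- 10:14   # distances 0..4
  expect_equal(pr$value[1], mean(first_bin_cols))
  expect_error(vertical_profile(u, border_x = 100, pixel_size_um = 1), "border")
})

test_that("interval fraction: equidistribution, 2:1 enrichment, phantom pipeline", {
  u <- matrix(7, 20, 100)
  p <- vertical_profile(u, border_x = 5, pixel_size_um = 1)
  expect_identical(interval_fraction(p)$IF, 0.5)
  e <- make_edge_phantom(2, 20, c(64, 150))
  pe <- vertical_profile(e, border_x = 20, pixel_size_um = 1)
  expect_equal(interval_fraction(pe)$IF, 2 / 3, tolerance = 1e-12)
  # end-to-end with noise
  set.seed(8)
  en <- pmax(e + matrix(rnorm(length(e), sd = 10), nrow(e)), 0)
  pen <- vertical_profile(en, border_x = 20, pixel_size_um = 1)
  expect_lt(abs(interval_fraction(pen)$IF - 0.667), 0.02)
})

test_that("interval fraction is invariant to global intensity scaling", {
  set.seed(4)
  img <- matrix(runif(30 * 150, 10, 50), 30, 150)
  p1 <- vertical_profile(img, 10, 1)
  p2 <- vertical_profile(img * 37.5, 10, 1)
  expect_equal(interval_fraction(p1)$IF, interval_fraction(p2)$IF,
               tolerance = 1e-12)
})

test_that("profile normalization has unit domain mean and is idempotent", {
  u <- matrix(7, 10, 120)
  p <- vertical_profile(u, 5, 1)
  np <- normalize_profile(p)
  expect_true(all(np$value == 1))
  set.seed(6)
  img <- matrix(runif(20 * 150, 1, 9), 20, 150)
  pr <- normalize_profile(vertical_profile(img, 8, 1))
  sel <- pr$bin_hi <= 80
  expect_equal(mean(pr$value[sel]), 1, tolerance = 1e-12)
  expect_equal(normalize_profile(pr)$value, pr$value, tolerance = 1e-12)
  # IF unchanged by normalization
  p0 <- vertical_profile(img, 8, 1)
  expect_equal(interval_fraction(p0)$IF, interval_fraction(normalize_profile(p0))$IF,
               tolerance = 1e-12)
})

test_that("profile aggregation uses sample SD and flags singleton bins", {
  u1 <- vertical_profile(matrix(1, 10, 60), 5, 1)
  u2 <- vertical_profile(matrix(3, 10, 60), 5, 1)
  agg <- aggregate_profiles(list(u1, u2))
  expect_true(all(agg$mean == 2))
  expect_equal(agg$sd, rep(sd(c(1, 3)), nrow(agg)))           # n-1 denominator
  expect_equal(agg$sem, rep(sd(c(1, 3)) / sqrt(2), nrow(agg)))
  agg1 <- aggregate_profiles(list(u1))
  expect_true(all(is.na(agg1$sd)))
  same <- aggregate_profiles(list(u1, u1))
  expect_true(all(same$sd == 0) && all(same$sem == 0))
})

test_that("destruction area: rectangle, degenerate, and raster-fill oracle", {
  cutl <- cbind(x = rep(10, 5), y = seq(0, 100, 25))
  bord <- cbind(x = rep(34, 5), y = seq(0, 100, 25))
  expect_equal(destruction_area(cutl, bord), 100 * 24)
  expect_equal(destruction_area(cutl, cutl), 0)
  # random monotone polylines vs pixel-fill count
  set.seed(15)
  ys <- seq(1, 199, length.out = 12)
  c1 <- cbind(x = 40 + cumsum(rnorm(12, 0, 2)), y = ys)
  c2 <- cbind(x = 120 + cumsum(rnorm(12, 0, 2)), y = ys)
  area <- destruction_area(c1, c2)
  xs_at <- function(pl, y) approx(pl[, 2], pl[, 1], y)$y
  yy <- seq(1.5, 198.5, by = 0.25)
  fill <- sum(pmax(xs_at(c2, yy) - xs_at(c1, yy), 0)) * 0.25
  expect_lt(abs(area - fill) / fill, 0.01)
  # crossing polylines are rejected
  c3 <- cbind(x = c(10, 50), y = c(0, 100))
  c4 <- cbind(x = c(50, 10), y = c(0, 100))
  expect_error(destruction_area(c3, c4), "self-intersecting")
})
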