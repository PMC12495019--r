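test_that("correlation coefficients: linear, monotone, hand formula, guards", {
  x <- 1:10
  expect_equal(img_correlation(x, 2 * x + 1, "pearson"), 1)
  expect_equal(img_correlation(x, 2 * x + 1, "spearman"), 1)
  g <- seq(-2, 2, length.out = 9)
  expect_equal(img_correlation(g, g^3, "spearman"), 1)
  expect_lt(img_correlation(g, g^3, "pearson"), 1)
  a <- c(2, 4, 4, 7, 9, 1, 5, 8, 3, 6)
  b <- c(1, 3, 6, 8, 10, 2, 4, 9, 5, 7)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(img_correlation(a, b, "pearson"), hand, tolerance = 1e-12)
  expect_error(img_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(img_correlation(1:2, 1:2), "at least 3")
})

test_that("tile-shuffle test: identity case, degenerate tiles, permutation guard", {
  set.seed(2)
  img <- matrix(rnorm(64 * 64), 64, 64)
  r <- tile_shuffle_test(img, img, tile = 8, n_perm = 99, seed = 1)
  expect_equal(r$p, 1 / 100)                      # nothing beats identity
  expect_equal(r$r_obs, 1)
  expect_error(tile_shuffle_test(img, img, tile = 64, n_perm = 99), "2 tiles")
  expect_error(tile_shuffle_test(img, img, n_perm = 10), "at least 19")
})

test_that("percentile pairing lies on the channel relation", {
  set.seed(12)
  a <- matrix(rlnorm(40 * 40), 40, 40)
  curve_same <- percentile_pairing(a, a)
  expect_equal(curve_same$Th_A, curve_same$Th_B)
  curve_2x <- percentile_pairing(a, 2 * a)
  expect_equal(curve_2x$Th_B, 2 * curve_2x$Th_A, tolerance = 1e-12)
  b <- matrix(runif(40 * 40), 40, 40)
  curve <- percentile_pairing(a, b, grid = c(10, 50, 90))
  expect_equal(curve$Th_A, unname(quantile(a, c(.1, .5, .9), type = 7)))
  expect_equal(curve$Th_B, unname(quantile(b, c(.1, .5, .9), type = 7)))
  expect_true(all(diff(percentile_pairing(a, b)$Th_A) >= 0))
})

two_population_pair <- function(seed) {
  # uncorrelated dim background plus a bright correlated foreground block
  set.seed(seed)
  H <- 96; W <- 96
  A <- matrix(rnorm(H * W, 50, 10), H, W)
  B <- matrix(rnorm(H * W, 50, 10), H, W)
  fg <- matrix(FALSE, H, W); fg[1:48, 1:48] <- TRUE
  t <- rnorm(sum(fg), 0, 30)
  A[fg] <- 180 + t + rnorm(sum(fg), 0, 5)
  B[fg] <- 170 + 0.8 * t + rnorm(sum(fg), 0, 5)
  list(A = pmax(A, 0), B = pmax(B, 0), fg = fg)
}

test_that("Costes thresholds separate background from correlated foreground", {
  tp <- two_population_pair(21)
  cst <- costes_thresholds(tp$A, tp$B)
  expect_true(cst$converged)
  expect_lte(cst$PCC_outside, 0.02)               # stopping contract
  expect_gte(mean(cst$M_co[tp$fg]), 0.95)         # foreground inside the mask
  expect_lt(mean(cst$M_co[!tp$fg]), 0.2)
})

test_that("independent images degrade to the curve minimum with a warning", {
  set.seed(33)
  a <- matrix(abs(rnorm(32 * 32)) + 1, 32, 32)
  b <- matrix(a[sample(length(a))] * 2, 32, 32)   # same marginal, independent
  # force a pair whose outside PCC stays positive: B an affine copy of A
  expect_warning(cst <- costes_thresholds(a, a * 2 + 1), "never reached zero")
  expect_false(cst$converged)
})

test_that("Manders coefficients are exact fractions of total intensity", {
  A <- matrix(1:16, 4, 4); B <- matrix(16:1, 4, 4)
  full <- matrix(TRUE, 4, 4); empty <- matrix(FALSE, 4, 4)
  expect_equal(manders(A, B, full), list(M1 = 1, M2 = 1))
  expect_equal(manders(A, B, empty), list(M1 = 0, M2 = 0))
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  m <- manders(A, B, mask)
  expect_equal(m$M1, sum(A[1:2, 1:2]) / sum(A))       # hand-summed
  expect_equal(m$M2, sum(B[1:2, 1:2]) / sum(B))
  expect_error(manders(matrix(0, 3, 3), B[1:3, 1:3], full[1:3, 1:3]), "zero total")
})

test_that("M1 never increases when Th_A rises", {
  set.seed(41)
  A <- matrix(rlnorm(50 * 50), 50, 50)
  B <- matrix(rlnorm(50 * 50), 50, 50)
  ths <- quantile(A, seq(0.1, 0.9, 0.1), type = 7)
  m1 <- sapply(ths, function(t) manders(A, B, A > t & B > median(B))$M1)
  expect_true(all(diff(m1) <= 1e-12))
  expect_true(all(m1 >= 0 & m1 <= 1))
})

test_that("masked correlation recovers a correlated subregion", {
  set.seed(51)
  n <- 60
  A <- matrix(rnorm(n * n), n, n)
  B <- matrix(rnorm(n * n), n, n)
  mask <- matrix(FALSE, n, n); mask[1:20, 1:20] <- TRUE
  B[mask] <- A[mask]                         # perfect correlation inside mask
  mc <- masked_correlation(A, B, mask)
  expect_equal(mc$PCC, 1)
  full <- masked_correlation(A, B, matrix(TRUE, n, n))
  expect_equal(full$PCC, cor(as.vector(A), as.vector(B)))
  expect_error(masked_correlation(A, B, matrix(FALSE, n, n)), "fewer than 3")
})

test_that("correlation invariances: affine for PCC, monotone for SRCC", {
  set.seed(61)
  a <- runif(200); b <- runif(200)
  expect_equal(img_correlation(a, b), img_correlation(3 * a + 2, b),
               tolerance = 1e-12)
  expect_equal(img_correlation(a, b, "spearman"),
               img_correlation(exp(a), b, "spearman"), tolerance = 1e-12)
})

test_that("nuclear fractions handle boundary cases and phantom truth", {
  tab <- data.frame(A_nuc = c(2, 0, 3), A_cyt = c(2, 5, 0),
                    B_nuc = c(1, 1, 1), B_cyt = c(1, 1, 1))
  nf <- nuclear_fractions(tab)
  expect_equal(nf$nucfr_A, c(0.5, 0, 1))
  tr <- small_truth(13)
  scene <- epifocus:::phantom_scene(tr)
  t2 <- nuclear_fractions(measure_compartments(tr$labels$nucleus, tr$labels$cell,
                                               scene$proteinA, scene$proteinB))
  m <- tr$compartment_means
  expect_equal(t2$nucfr_A, m$A_nuc / (m$A_nuc + m$A_cyt), tolerance = 1e-12)
})

test_that("compartment correlations match column-wise computation", {
  set.seed(11)
  tab <- data.frame(A_nuc = runif(40), A_cyt = runif(40),
                    B_nuc = runif(40), B_cyt = runif(40))
  cc <- compartment_correlations(tab)
  expect_equal(cc$PCC[cc$pair == "nuc_nuc"],
               img_correlation(tab$A_nuc, tab$B_nuc))
  expect_equal(cc$SRCC[cc$pair == "cyt_cyt"],
               img_correlation(tab$A_cyt, tab$B_cyt, "spearman"))
  # proportional channels: all six pairings perfectly correlated
  tab2 <- data.frame(A_nuc = 1:20, A_cyt = (1:20) * 1.5,
                     B_nuc = (1:20) * 2, B_cyt = (1:20) * 3)
  cc2 <- compartment_correlations(tab2)
  expect_true(all(abs(cc2$PCC[cc2$pair != "Acyt_nucfrB"] - 1) < 1e-12))
})

test_that("orthogonal regression recovers exact lines", {
  x <- runif(50)
  orr <- orthogonal_regression(x, 3 * x)
  expect_equal(orr$slope, 3, tolerance = 1e-10)
  expect_equal(orr$intercept, 0, tolerance = 1e-10)
  orr2 <- orthogonal_regression(x, -2 * x + 5)
  expect_equal(orr2$slope, -2, tolerance = 1e-10)
  expect_equal(orr2$intercept, 5, tolerance = 1e-10)
})

test_that("HNF analysis skips small groups and reports percent differences", {
  tab <- data.frame(A_nuc = 1, A_cyt = rep(10, 20), B_nuc = 1, B_cyt = 9)
  tabnf <- nuclear_fractions(tab)                 # all nucfr_B = 0.1
  out <- hnf_analysis(tabnf)
  expect_true(out$skipped)
  expect_equal(out$n_hnf, 0L)
  set.seed(71)
  tab2 <- data.frame(A_nuc = 1,
                     A_cyt = c(rep(20, 8), rep(10, 12)) + rnorm(20, 0, 0.01),
                     B_nuc = c(rep(3, 8), rep(1, 12)),
                     B_cyt = c(rep(1, 8), rep(9, 12)))
  out2 <- hnf_analysis(nuclear_fractions(tab2))
  expect_false(out2$skipped)
  expect_equal(out2$n_hnf, 8L)
  expect_equal(out2$percent_diff, 100, tolerance = 0.5)
  expect_error(hnf_analysis(tabnf, nucfr_threshold = 1.2), "in \\(0, 1\\)")
})

test_that("pixel_coloc assembles a coherent report with compartment masks", {
  tr <- small_truth(14)
  scene <- epifocus:::phantom_scene(tr)
  lab <- compartment_labels(tr$labels$cell, tr$labels$nucleus)
  px <- pixel_coloc(scene$proteinA, scene$proteinB, labels = lab,
                    n_perm = 49, seed = 3)
  expect_true(px$PCC >= -1 && px$PCC <= 1)
  expect_true(px$M1 >= 0 && px$M1 <= 1 && px$M2 >= 0 && px$M2 <= 1)
  expect_true(!is.null(px$PCC_cyt) && !is.null(px$PCC_nuc))
  expect_equal(sum(px$histogram$counts), length(scene$proteinA))
})
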