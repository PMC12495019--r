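# Pixelwise and compartmental colocalization: correlation coefficients with
# tile-shuffle randomization significance, Costes thresholds found along a
# percentile-pairing curve, Manders coefficients, per-cell nuclear fractions,
# compartment correlations with orthogonal regression, and the
# high-nuclear-fraction (HNF) subgroup comparison.

#' Pearson or Spearman correlation of two images
#'
#' Spearman is Pearson on average-ranked data (ties get mean ranks). Inputs
#' with fewer than 3 finite pixels or zero variance are rejected rather than
#' returning a silent `NA`.
#'
#' @param x,y numeric vectors or matrices of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
img_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("correlation needs at least 3 pixels", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("correlation inputs must be finite", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  cor(x, y)
}

#' Tile-shuffle randomization test for image correlation
#'
#' Null distribution of the correlation coefficient obtained by cutting the
#' first image into `tile x tile` blocks and shuffling them while the second
#' image stays fixed; images are cropped to tile multiples. Two-sided p-value
#' with the add-one convention: `p = (1 + #{|r_null| >= |r_obs|}) /
#' (n_perm + 1)`, never exactly zero.
#'
#' @param imgA,imgB numeric matrices of the same dimension.
#' @param tile tile side in px (default 8).
#' @param n_perm number of permutations (default 200; at least 19).
#' @param method correlation method.
#' @param seed RNG seed.
#' @return list with `p`, `r_obs`, `r_null`, `n_tiles`.
#' @export
tile_shuffle_test <- function(imgA, imgB, tile = 8L, n_perm = 200L,
                              method = c("pearson", "spearman"), seed = NULL) {
  method <- match.arg(method)
  check_matrix(imgA); check_matrix(imgB)
  if (!all(dim(imgA) == dim(imgB)))
    stop("images must have identical dimensions", call. = FALSE)
  if (n_perm < 19L)
    stop("`n_perm` must be at least 19 for a usable p-value resolution", call. = FALSE)
  H <- (nrow(imgA) %/% tile) * tile
  W <- (ncol(imgA) %/% tile) * tile
  if (H < tile || W < tile)
    stop("images smaller than one tile", call. = FALSE)
  nty <- H %/% tile; ntx <- W %/% tile
  n_tiles <- nty * ntx
  if (n_tiles < 2L)
    stop("degenerate randomization: need at least 2 tiles", call. = FALSE)
  a <- imgA[seq_len(H), seq_len(W)]
  b <- imgB[seq_len(H), seq_len(W)]
  if (method == "spearman") { a[] <- rank(a); b[] <- rank(b) }
  # columns of `ta` are tiles, in a fixed raster order
  tile_cols <- function(m) {
    arr <- array(m, dim = c(tile, nty, tile, ntx))
    matrix(aperm(arr, c(1, 3, 2, 4)), nrow = tile * tile, ncol = n_tiles)
  }
  ta <- tile_cols(a)
  vb <- as.vector(tile_cols(b))
  r_obs <- cor(as.vector(ta), vb)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) cor(as.vector(ta[, sample.int(n_tiles)]), vb), 0)
  })
  list(p = (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1),
       r_obs = r_obs, r_null = r_null, n_tiles = n_tiles)
}

#' Percentile-pairing threshold curve
#'
#' Pairs the two channels' intensities at equal quantiles: for every quantile
#' `q` on the grid, the candidate threshold pair is
#' `(prc_q(A), prc_q(B))`. The curve is monotone non-decreasing in both
#' coordinates by construction and replaces the orthogonal-regression line of
#' the classic Costes procedure, accommodating nonlinear channel relations.
#'
#' @param imgA,imgB numeric matrices.
#' @param grid quantile grid in percent (default 0 to 99.9 by 0.1).
#' @return data frame with `q`, `Th_A`, `Th_B`.
#' @export
percentile_pairing <- function(imgA, imgB, grid = seq(0, 99.9, by = 0.1)) {
  data.frame(q = grid,
             Th_A = quantile(imgA, grid / 100, type = 7, names = FALSE),
             Th_B = quantile(imgB, grid / 100, type = 7, names = FALSE))
}

#' Costes thresholds along the percentile-pairing curve
#'
#' Walks the percentile curve from the highest quantile downward; at each
#' candidate pair it computes the Pearson correlation on the *outside* region
#' (`A <= Th_A | B <= Th_B`) and stops at the first step where that
#' correlation reaches zero (<= 0) from decreasing values. The cooccurrence
#' mask is `M_co = A > Th_A & B > Th_B`. If the outside correlation never
#' reaches zero the thresholds degenerate to the curve minimum, with a
#' warning.
#'
#' @param imgA,imgB numeric matrices (non-constant).
#' @param step quantile step in percent (default 0.1).
#' @param q_max top of the quantile grid (default 99.9).
#' @return list with `Th_A`, `Th_B`, `q`, `M_co`, `PCC_costes` (inside the
#'   mask; `NA` when degenerate), `PCC_outside`, `converged`.
#' @export
costes_thresholds <- function(imgA, imgB, step = 0.1, q_max = 99.9) {
  check_matrix(imgA); check_matrix(imgB)
  if (var(as.numeric(imgA)) == 0 || var(as.numeric(imgB)) == 0)
    stop("Costes thresholds need non-constant images", call. = FALSE)
  grid <- seq(q_max, 0, by = -step)
  curve <- percentile_pairing(imgA, imgB, grid)
  a <- as.numeric(imgA); b <- as.numeric(imgB)
  pcc_out <- NA_real_
  hit <- NA_integer_
  for (i in seq_len(nrow(curve))) {
    out <- a <= curve$Th_A[i] | b <= curve$Th_B[i]
    if (sum(out) < 3L) next
    ao <- a[out]; bo <- b[out]
    if (var(ao) == 0 || var(bo) == 0) next
    pcc_out <- cor(ao, bo)
    if (pcc_out <= 0) { hit <- i; break }
  }
  converged <- !is.na(hit)
  if (!converged) {
    warning("outside-region PCC never reached zero; thresholds set to the curve minimum")
    hit <- nrow(curve)
  }
  Th_A <- curve$Th_A[hit]; Th_B <- curve$Th_B[hit]
  M_co <- imgA > Th_A & imgB > Th_B
  pcc_in <- NA_real_
  if (sum(M_co) >= 3L && var(a[M_co]) > 0 && var(b[M_co]) > 0)
    pcc_in <- cor(a[M_co], b[M_co])
  list(Th_A = Th_A, Th_B = Th_B, q = curve$q[hit], M_co = M_co,
       PCC_costes = pcc_in, PCC_outside = pcc_out, converged = converged)
}

#' Manders cooccurrence coefficients
#'
#' `M1` is the fraction of channel A's total intensity inside the
#' cooccurrence mask, `M2` the same for channel B. Both lie in `[0, 1]`.
#'
#' @param imgA,imgB numeric matrices (non-negative, non-zero total).
#' @param M_co logical cooccurrence mask.
#' @return list with `M1`, `M2`.
#' @export
manders <- function(imgA, imgB, M_co) {
  sA <- sum(imgA); sB <- sum(imgB)
  if (sA == 0 || sB == 0)
    stop("Manders coefficients undefined: zero total intensity", call. = FALSE)
  list(M1 = sum(imgA[M_co]) / sA, M2 = sum(imgB[M_co]) / sB)
}

#' Correlation restricted to a mask
#'
#' @param imgA,imgB numeric matrices.
#' @param mask logical matrix with at least 3 `TRUE` pixels.
#' @return list with `PCC` and `SRCC`.
#' @export
masked_correlation <- function(imgA, imgB, mask) {
  mask <- as_logical_matrix(mask)
  if (sum(mask) < 3L) stop("mask selects fewer than 3 pixels", call. = FALSE)
  list(PCC = img_correlation(imgA[mask], imgB[mask], "pearson"),
       SRCC = img_correlation(imgA[mask], imgB[mask], "spearman"))
}

#' Bivariate intensity histogram
#'
#' Counts over an `nbins x nbins` grid of equal-width intensity bins;
#' intended to be displayed on a log10 color scale.
#'
#' @param imgA,imgB numeric matrices.
#' @param nbins bins per axis (default 64).
#' @return list with `counts` (matrix, A along rows), `breaks_A`, `breaks_B`.
#' @export
bivariate_histogram <- function(imgA, imgB, nbins = 64L) {
  brA <- seq(min(imgA), max(imgA), length.out = nbins + 1L)
  brB <- seq(min(imgB), max(imgB), length.out = nbins + 1L)
  ia <- pmin(pmax(findInterval(imgA, brA, all.inside = TRUE), 1L), nbins)
  ib <- pmin(pmax(findInterval(imgB, brB, all.inside = TRUE), 1L), nbins)
  counts <- matrix(0L, nbins, nbins)
  t <- table(factor(ia, levels = seq_len(nbins)), factor(ib, levels = seq_len(nbins)))
  counts[] <- as.integer(t)
  list(counts = counts, breaks_A = brA, breaks_B = brB)
}

#' Full pixelwise colocalization analysis
#'
#' PCC and SRCC with tile-shuffle randomization p-values, the bivariate
#' histogram, Costes thresholds with Manders coefficients, and (when
#' compartment labels are given) the correlations restricted to the pooled
#' nucleoplasm and cytoplasm masks.
#'
#' @param imgA,imgB numeric matrices (the two protein channels).
#' @param labels optional [compartment_labels()].
#' @param tile,n_perm,seed randomization-test settings.
#' @param costes_step quantile step of the Costes walk.
#' @param nbins histogram bins.
#' @return an object of class `pixel_coloc`.
#' @export
pixel_coloc <- function(imgA, imgB, labels = NULL, tile = 8L, n_perm = 200L,
                        seed = NULL, costes_step = 0.1, nbins = 64L) {
  pcc <- img_correlation(imgA, imgB, "pearson")
  srcc <- img_correlation(imgA, imgB, "spearman")
  tp <- tile_shuffle_test(imgA, imgB, tile = tile, n_perm = n_perm,
                          method = "pearson", seed = seed)
  ts <- tile_shuffle_test(imgA, imgB, tile = tile, n_perm = n_perm,
                          method = "spearman",
                          seed = if (is.null(seed)) NULL else seed + 1L)
  cst <- costes_thresholds(imgA, imgB, step = costes_step)
  man <- manders(imgA, imgB, cst$M_co)
  out <- list(PCC = pcc, SRCC = srcc, p_PCC = tp$p, p_SRCC = ts$p,
              histogram = bivariate_histogram(imgA, imgB, nbins),
              Th_A = cst$Th_A, Th_B = cst$Th_B, M_co_frac = mean(cst$M_co),
              PCC_costes = cst$PCC_costes, costes_converged = cst$converged,
              M1 = man$M1, M2 = man$M2)
  if (!is.null(labels)) {
    nucm <- labels$compartment == 1L
    cytm <- labels$compartment == 2L
    if (sum(nucm) >= 3L) {
      mc <- masked_correlation(imgA, imgB, nucm)
      out$PCC_nuc <- mc$PCC; out$SRCC_nuc <- mc$SRCC
    }
    if (sum(cytm) >= 3L) {
      mc <- masked_correlation(imgA, imgB, cytm)
      out$PCC_cyt <- mc$PCC; out$SRCC_cyt <- mc$SRCC
    }
  }
  structure(out, class = "pixel_coloc")
}

#' @export
print.pixel_coloc <- function(x, ...) {
  cat(sprintf("<pixel_coloc> PCC %.3f (p = %.4g), SRCC %.3f (p = %.4g)\n",
              x$PCC, x$p_PCC, x$SRCC, x$p_SRCC))
  cat(sprintf("  Costes: Th_A %.3g, Th_B %.3g (%sconverged); M1 %.3f, M2 %.3f\n",
              x$Th_A, x$Th_B, if (x$costes_converged) "" else "NOT ", x$M1, x$M2))
  invisible(x)
}

#' Per-cell nuclear fractions
#'
#' Appends `nucfr_A = A_nuc / (A_nuc + A_cyt)` and the analogous `nucfr_B`
#' to a compartment table. A zero nucleoplasm mean gives 0, a zero cytoplasm
#' mean with positive nucleoplasm gives 1; cells with both compartments zero
#' get `NA` with a warning.
#'
#' @param table a [measure_compartments()] data frame.
#' @return the table with `nucfr_A`, `nucfr_B` columns appended.
#' @export
nuclear_fractions <- function(table) {
  frac <- function(nuc, cyt) {
    tot <- nuc + cyt
    out <- nuc / tot
    bad <- tot == 0
    if (any(bad, na.rm = TRUE)) {
      warning("cells with zero signal in both compartments: nuclear fraction NA")
      out[bad] <- NA_real_
    }
    out
  }
  table$nucfr_A <- frac(table$A_nuc, table$A_cyt)
  table$nucfr_B <- frac(table$B_nuc, table$B_cyt)
  table
}

#' Scale-invariant orthogonal regression
#'
#' First principal axis of the standardized pair, mapped back to the original
#' units: `slope = sign(cov(x, y)) * sd(y) / sd(x)` and the line passes
#' through the centroid. An exact linear relation is recovered exactly.
#'
#' @param x,y numeric vectors.
#' @return list with `slope`, `intercept`.
#' @export
orthogonal_regression <- function(x, y) {
  if (sd(x) == 0) stop("orthogonal regression undefined: zero variance in x", call. = FALSE)
  s <- stats::cov(x, y)
  slope <- (if (s < 0) -1 else 1) * sd(y) / sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Compartment-mean correlation structure
#'
#' All six per-cell pairings of the compartment means (same compartment
#' across channels, crossed compartments, and same channel across
#' compartments), plus the cytoplasmic-A versus nuclear-fraction-B scatter.
#' Each pairing reports PCC and SRCC with two-sided null-hypothesis p-values
#' and the orthogonal regression line.
#'
#' @param table a [measure_compartments()] data frame (nuclear fractions are
#'   added if missing).
#' @return data frame with one row per pairing.
#' @export
compartment_correlations <- function(table) {
  if (is.null(table$nucfr_B)) table <- nuclear_fractions(table)
  pairs <- list(
    nuc_nuc   = c("A_nuc", "B_nuc"),
    cyt_cyt   = c("A_cyt", "B_cyt"),
    Anuc_Bcyt = c("A_nuc", "B_cyt"),
    Acyt_Bnuc = c("A_cyt", "B_nuc"),
    A_nuc_cyt = c("A_nuc", "A_cyt"),
    B_nuc_cyt = c("B_nuc", "B_cyt"),
    Acyt_nucfrB = c("A_cyt", "nucfr_B"))
  rows <- lapply(names(pairs), function(nm) {
    x <- table[[pairs[[nm]][1]]]; y <- table[[pairs[[nm]][2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
      return(data.frame(pair = nm, x = pairs[[nm]][1], y = pairs[[nm]][2],
                        n = length(x), PCC = NA_real_, p_PCC = NA_real_,
                        SRCC = NA_real_, p_SRCC = NA_real_,
                        slope = NA_real_, intercept = NA_real_))
    ct_p <- cor.test(x, y, method = "pearson")
    ct_s <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    orr <- orthogonal_regression(x, y)
    data.frame(pair = nm, x = pairs[[nm]][1], y = pairs[[nm]][2], n = length(x),
               PCC = unname(ct_p$estimate), p_PCC = ct_p$p.value,
               SRCC = unname(ct_s$estimate), p_SRCC = ct_s$p.value,
               slope = orr$slope, intercept = orr$intercept)
  })
  do.call(rbind, rows)
}

#' High-nuclear-fraction subgroup comparison
#'
#' Flags cells whose channel-B nuclear fraction exceeds `nucfr_threshold`
#' (HNF) and, when at least `min_cells` qualify, compares the cytoplasmic
#' channel-A mean between the HNF and LNF groups with an unpaired
#' normality-gated test, reporting the percent difference.
#'
#' @param table a compartment table with nuclear fractions.
#' @param nucfr_threshold HNF cutoff in `(0, 1)` (default 0.5,
#'   nuclear-dominant).
#' @param min_cells minimum HNF group size (default 5).
#' @return list with `n_hnf`, `n_lnf`, `skipped` (+ `reason`), and when
#'   performed `percent_diff` and `comparison` (a [compare_samples()] result).
#' @export
hnf_analysis <- function(table, nucfr_threshold = 0.5, min_cells = 5L) {
  if (nucfr_threshold <= 0 || nucfr_threshold >= 1)
    stop("`nucfr_threshold` must be in (0, 1)", call. = FALSE)
  if (is.null(table$nucfr_B)) table <- nuclear_fractions(table)
  hnf <- !is.na(table$nucfr_B) & table$nucfr_B > nucfr_threshold
  out <- list(n_hnf = sum(hnf), n_lnf = sum(!hnf),
              nucfr_threshold = nucfr_threshold)
  if (sum(hnf) < min_cells || sum(!hnf) < min_cells) {
    out$skipped <- TRUE
    out$reason <- sprintf("HNF group has %d cells (minimum %d) or LNF group too small",
                          sum(hnf), min_cells)
    return(out)
  }
  a_hnf <- table$A_cyt[hnf]; a_lnf <- table$A_cyt[!hnf]
  out$skipped <- FALSE
  out$percent_diff <- 100 * (mean(a_hnf) - mean(a_lnf)) / mean(a_lnf)
  out$comparison <- compare_samples(a_hnf, a_lnf, design = "unpaired")
  out
}
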