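# Compartmental segmentation: two marker-controlled watershed transforms turn
# the in-focus image into per-cell nucleoplasm and cytoplasm labels.
#
# Stage 1 (nuclei): the DAPI channel is background-subtracted and
# contrast-adjusted; nuclear seeds come from the regional maxima of an
# automatically tuned h-maxima transform, the extranuclear seed from an eroded
# below-median mask; the DAPI gradient is flooded from both.
# Stage 2 (cells): nuclear regions become per-cell seeds, a void seed marks
# acellular space found via the distance transform, and the summed protein
# gradients (with a 2 px guard band around nuclei zeroed) are flooded.

#' Remove the DAPI background
#'
#' Gaussian-smooths the in-focus DAPI image, estimates a soft background by a
#' grayscale opening-style sequence (erosion by a disc of radius `r_n`,
#' dilation by `2 r_n`, Gaussian smoothing with sd `r_n`) that removes all
#' objects under radius `r_n`, and subtracts it, clipping at zero.
#'
#' @param dapi_f in-focus DAPI image (numeric matrix).
#' @param sigma_n smoothing sd in px (default 3).
#' @param r_n background structuring radius in px (default 9).
#' @return list with `smooth`, `back`, `nuc` matrices.
#' @export
remove_background <- function(dapi_f, sigma_n = 3, r_n = 9) {
  check_matrix(dapi_f)
  if (sigma_n <= 0 || r_n <= 0)
    stop("`sigma_n` and `r_n` must be positive", call. = FALSE)
  smooth <- gauss_smooth(dapi_f, sigma_n)
  back <- gauss_smooth(gray_dilate(gray_erode(smooth, r_n), 2 * r_n), r_n)
  list(smooth = smooth, back = back, nuc = pmax(smooth - back, 0))
}

#' Local contrast adjustment of the nuclear signal
#'
#' Fits a smooth local nuclear-intensity surface `F_nuc` as a self-weighted
#' least-squares degree-2 polynomial (the signal is its own weight, so only
#' nuclear pixels shape the surface) and divides by it, flooring `F_nuc` at
#' `1e-6 * max(F_nuc)` to keep the ratio finite where no nuclei are present.
#'
#' @param dapi_nuc background-subtracted DAPI (non-negative matrix, not all
#'   zero).
#' @return list with `F_nuc` (fitted surface) and `lca` (adjusted image).
#' @export
local_contrast_adjust <- function(dapi_nuc) {
  check_matrix(dapi_nuc)
  if (any(dapi_nuc < 0)) stop("`dapi_nuc` must be non-negative", call. = FALSE)
  if (all(dapi_nuc == 0))
    stop("local contrast adjustment failed: no nuclear signal (all-zero input)",
         call. = FALSE)
  fit <- wls_poly_surface(dapi_nuc, dapi_nuc, 2L,
                          what = "local contrast adjustment")
  F_nuc <- fit$surface
  eps <- 1e-6 * max(F_nuc)
  if (eps <= 0) eps <- 1e-12
  list(F_nuc = F_nuc, lca = dapi_nuc / pmax(F_nuc, eps))
}

#' Nuclear seed markers
#'
#' Shifts the contrast-adjusted DAPI to its upper half (subtracting the median
#' and clipping at zero), suppresses maxima shallower than
#' `h = 0.1 * prc99.9` with the h-maxima transform, and takes the regional
#' maxima of the result as binary nucleus markers (the zero background plateau
#' is excluded).
#'
#' @param dapi_lca contrast-adjusted DAPI (non-negative matrix).
#' @param h_factor fraction of the 99.9th percentile used as suppression
#'   height (default 0.1).
#' @return list with `B_nuc` (logical marker mask) and `h`.
#' @export
nuclear_markers <- function(dapi_lca, h_factor = 0.1) {
  check_matrix(dapi_lca)
  shifted <- pmax(dapi_lca - prc(dapi_lca, 50), 0)
  h <- h_factor * prc(dapi_lca, 99.9)
  hm <- if (h > 0) h_maxima(shifted, h) else shifted
  B_nuc <- regional_maxima(hm) & hm > 0
  list(B_nuc = B_nuc, h = h)
}

#' Extranuclear seed marker
#'
#' The below-median part of the contrast-adjusted DAPI, eroded by a disc of
#' radius 2 so it retreats from nuclear borders.
#'
#' @param dapi_lca contrast-adjusted DAPI.
#' @param erosion_r erosion radius in px (default 2).
#' @return logical marker mask.
#' @export
extranuclear_marker <- function(dapi_lca, erosion_r = 2) {
  check_matrix(dapi_lca)
  low <- dapi_lca <= prc(dapi_lca, 50)
  gray_erode(low, erosion_r) > 0.5
}

#' First watershed: nuclei
#'
#' Floods the DAPI gradient magnitude from the nuclear markers (labels
#' 2..N+1, one per 8-connected marker component) and the extranuclear marker
#' (label 1). With no nuclear markers the whole frame becomes extranuclear,
#' with a warning.
#'
#' @param g_dapi gradient magnitude of the in-focus DAPI image.
#' @param B_nuc,B_exnuc logical marker masks (overlapping pixels are treated
#'   as nuclear).
#' @return integer label image `L1`.
#' @export
watershed_nuclei <- function(g_dapi, B_nuc, B_exnuc) {
  check_matrix(g_dapi)
  nl <- label_components(B_nuc, connectivity = 8L)
  markers <- matrix(0L, nrow(g_dapi), ncol(g_dapi))
  markers[B_exnuc & nl == 0L] <- 1L
  markers[nl > 0L] <- nl[nl > 0L] + 1L
  if (max(nl) == 0L) {
    warning("no nuclear markers found; returning a single extranuclear label")
    return(matrix(1L, nrow(g_dapi), ncol(g_dapi)))
  }
  if (!any(markers == 1L))
    warning("empty extranuclear marker; all pixels will be assigned to nuclei")
  marker_watershed(g_dapi, markers)
}

#' Average internuclear distance
#'
#' The mode of the Gaussian-regularized histogram of the non-zero values of
#' the Euclidean distance transform of the nuclear space: most of the
#' monolayer's cytoplasm sits about half an internuclear spacing away from the
#' nearest nucleus, so the histogram peaks there.
#'
#' @param B_cell logical mask of nuclear space (non-empty, not full-frame).
#' @param bin_width histogram bin width in px (default 1).
#' @param smooth_sd Gaussian regularization sd in bins (default 2; 0 gives
#'   the raw-histogram argmax).
#' @return `d_avg` in px (bin center of the mode).
#' @export
estimate_internuclear_distance <- function(B_cell, bin_width = 1, smooth_sd = 2) {
  B_cell <- as_logical_matrix(B_cell)
  if (!any(B_cell)) stop("`B_cell` is empty", call. = FALSE)
  if (all(B_cell)) stop("`B_cell` covers the whole frame; no distances to histogram",
                        call. = FALSE)
  if (max(cpp_label(B_cell, 8L)) == 1L)
    warning("single nuclear component; d_avg reflects frame geometry rather than cell spacing")
  d <- distance_transform(B_cell)
  v <- d[d > 0]
  breaks <- seq(0, ceiling(max(v) / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(v, breaks, left.open = FALSE),
                     nbins = length(breaks) - 1L)
  if (smooth_sd > 0) {
    k <- gaussian_kernel(smooth_sd)
    r <- (length(k) - 1L) / 2L
    padded <- c(rep(0, r), counts, rep(0, r))
    sm <- vapply(seq_along(counts),
                 function(i) sum(padded[i:(i + 2L * r)] * k), 0)
    norm <- vapply(seq_along(counts),
                   function(i) sum(k[pmax(1, r + 2 - i):min(length(k), length(counts) + r + 1 - i)]), 0)
    counts <- sm / norm
  }
  i <- which.max(counts)
  (breaks[i] + breaks[i + 1L]) / 2
}

#' Acellular (void) seed marker
#'
#' Opening of the thresholded distance transform of the nuclear space:
#' pixels farther than `2 * d_avg` from any nucleus, eroded and re-dilated by
#' a disc of radius `d_avg`. Empty on a confluent sheet.
#'
#' @param B_cell logical mask of nuclear space.
#' @param d_avg average internuclear distance in px.
#' @return logical marker mask, disjoint from `B_cell`.
#' @export
void_marker <- function(B_cell, d_avg) {
  B_cell <- as_logical_matrix(B_cell)
  far <- distance_transform(B_cell) > 2 * d_avg
  gray_dilate(gray_erode(far, d_avg), d_avg) > 0.5
}

#' Second watershed: cells
#'
#' Sums the Sobel gradient magnitudes of the two protein channels, zeroes a
#' 2 px guard band around the nuclear space (so nuclear borders do not
#' interfere with the cell borders), and floods from the nuclear regions of
#' `L1` (each nucleus keeps its label, so cell count equals nucleus count)
#' plus the void marker (label 1).
#'
#' @param A_f,B_f in-focus protein channel images.
#' @param L1 nuclear label image from [watershed_nuclei()].
#' @param B_void logical acellular marker (possibly empty).
#' @param guard_r guard-band radius around nuclei in px (default 2).
#' @return integer label image `L2` (1 = acellular, 2..N+1 = cells).
#' @export
watershed_cells <- function(A_f, B_f, L1, B_void = NULL, guard_r = 2) {
  check_matrix(A_f); check_matrix(B_f)
  B_cell <- L1 > 1L
  A2 <- sobel_gradient(A_f) + sobel_gradient(B_f)
  A2[gray_dilate(B_cell, guard_r) > 0.5] <- 0
  markers <- matrix(0L, nrow(A_f), ncol(A_f))
  if (!is.null(B_void)) markers[B_void & !B_cell] <- 1L
  markers[B_cell] <- L1[B_cell]
  if (!any(markers > 0L)) {
    warning("no cell or void markers; returning a single acellular label")
    return(matrix(1L, nrow(A_f), ncol(A_f)))
  }
  marker_watershed(A2, markers)
}

#' Combine the two watersheds and measure compartments
#'
#' Nucleus i is the `L1` region with the same label as cell i in `L2`
#' (clipped to the cell); the cytoplasm is the rest of the cell. Cells whose
#' nucleus ends up empty are dropped with a warning and their pixels returned
#' to the acellular label. Mean intensities of both protein channels are
#' measured per compartment.
#'
#' @param L1,L2 label images from the two watersheds.
#' @param A_f,B_f in-focus protein channel images.
#' @return list with `labels` (a `compartment_labels` object) and `table`
#'   (the per-cell [measure_compartments()] data frame).
#' @export
combine_and_measure <- function(L1, L2, A_f, B_f) {
  stopifnot(all(dim(L1) == dim(L2)))
  nuc <- matrix(0L, nrow(L1), ncol(L1))
  sel <- L1 > 1L & L1 == L2
  nuc[sel] <- L1[sel] - 1L
  cell <- matrix(0L, nrow(L2), ncol(L2))
  cell[L2 > 1L] <- L2[L2 > 1L] - 1L
  ids <- sort(unique(cell[cell > 0L]))
  no_nuc <- setdiff(ids, unique(nuc[nuc > 0L]))
  if (length(no_nuc) > 0L) {
    warning(sprintf("dropping %d cell(s) without nucleus pixels", length(no_nuc)))
    cell[cell %in% no_nuc] <- 0L
  }
  tab <- measure_compartments(nuc, cell, A_f, B_f)
  labels <- compartment_labels(cell, nuc)
  list(labels = labels, table = tab)
}

#' Per-cell compartment label image
#'
#' @param cell integer matrix of cell ids (0 = acellular).
#' @param nucleus integer matrix of nucleus ids (0 = none; ids match `cell`).
#' @return an object of class `compartment_labels` with fields `cell_id`,
#'   `compartment` (0 none, 1 nucleus, 2 cytoplasm) and `cell_count`.
#' @export
compartment_labels <- function(cell, nucleus) {
  comp <- matrix(0L, nrow(cell), ncol(cell))
  comp[cell > 0L] <- 2L
  comp[nucleus > 0L & nucleus == cell] <- 1L
  structure(list(cell_id = cell, compartment = comp,
                 cell_count = length(unique(cell[cell > 0L]))),
            class = "compartment_labels")
}

#' @export
print.compartment_labels <- function(x, ...) {
  cat(sprintf("<compartment_labels> %dx%d px, %d cells\n",
              nrow(x$cell_id), ncol(x$cell_id), x$cell_count))
  invisible(x)
}

#' Measure per-cell compartment intensities
#'
#' Mean intensity of each channel in the nucleoplasm and cytoplasm of every
#' cell, with pixel counts and centroids. Works on any pair of matching label
#' images (pipeline output or phantom ground truth).
#'
#' @param nucleus,cell integer label matrices with matching ids (0 =
#'   background/acellular).
#' @param A_f,B_f channel images.
#' @return data frame with one row per cell: `cell_id`, `area_px`, `nuc_px`,
#'   `cyt_px`, `centroid_x`, `centroid_y`, `A_nuc`, `A_cyt`, `B_nuc`,
#'   `B_cyt`.
#' @export
measure_compartments <- function(nucleus, cell, A_f, B_f) {
  ids <- sort(unique(cell[cell > 0L]))
  in_nuc <- nucleus > 0L & nucleus == cell
  in_cyt <- cell > 0L & !in_nuc
  xs <- matrix(rep(seq_len(ncol(cell)), each = nrow(cell)), nrow(cell))
  ys <- matrix(rep(seq_len(nrow(cell)), ncol(cell)), nrow(cell))
  mean_by <- function(v, mask) {
    m <- tapply(v[mask], cell[mask], mean)
    out <- setNames(rep(NA_real_, length(ids)), ids)
    out[names(m)] <- m
    out
  }
  count_by <- function(mask) {
    m <- table(factor(cell[mask], levels = ids))
    as.integer(m)
  }
  data.frame(
    cell_id = ids,
    area_px = count_by(cell > 0L),
    nuc_px = count_by(in_nuc),
    cyt_px = count_by(in_cyt),
    centroid_x = as.numeric(mean_by(xs, cell > 0L)),
    centroid_y = as.numeric(mean_by(ys, cell > 0L)),
    A_nuc = as.numeric(mean_by(A_f, in_nuc)),
    A_cyt = as.numeric(mean_by(A_f, in_cyt)),
    B_nuc = as.numeric(mean_by(B_f, in_nuc)),
    B_cyt = as.numeric(mean_by(B_f, in_cyt)),
    row.names = NULL)
}

#' Full compartmental segmentation of an in-focus image
#'
#' Runs the whole two-stage watershed segmentation on an [in_focus_image]
#' with channels `dapi`, `proteinA`, `proteinB`.
#'
#' @param img an [in_focus_image].
#' @param sigma_n,r_n background-removal parameters (px).
#' @param h_factor h-maxima tuning factor.
#' @return list with `labels`, `table`, and `intermediates` (all
#'   intermediate images and scalars).
#' @export
segment_cells <- function(img, sigma_n = 3, r_n = 9, h_factor = 0.1) {
  stopifnot(inherits(img, "in_focus_image"))
  dapi <- img$channels$dapi
  A_f <- img$channels$proteinA
  B_f <- img$channels$proteinB
  if (is.null(dapi) || is.null(A_f) || is.null(B_f))
    stop("segmentation needs channels 'dapi', 'proteinA' and 'proteinB'", call. = FALSE)
  bg <- remove_background(dapi, sigma_n = sigma_n, r_n = r_n)
  lca <- local_contrast_adjust(bg$nuc)
  nm <- nuclear_markers(lca$lca, h_factor = h_factor)
  B_exnuc <- extranuclear_marker(lca$lca)
  g_dapi <- sobel_gradient(dapi)
  L1 <- watershed_nuclei(g_dapi, nm$B_nuc, B_exnuc)
  B_cell <- L1 > 1L
  if (!any(B_cell)) {
    warning("segmentation found no nuclei")
    empty <- compartment_labels(matrix(0L, nrow(dapi), ncol(dapi)),
                                matrix(0L, nrow(dapi), ncol(dapi)))
    return(list(labels = empty,
                table = measure_compartments(empty$cell_id, empty$cell_id, A_f, B_f),
                intermediates = list(L1 = L1)))
  }
  d_avg <- estimate_internuclear_distance(B_cell)
  B_void <- void_marker(B_cell, d_avg)
  L2 <- watershed_cells(A_f, B_f, L1, B_void)
  res <- combine_and_measure(L1, L2, A_f, B_f)
  res$intermediates <- list(
    DAPI_smooth = bg$smooth, DAPI_back = bg$back, DAPI_nuc = bg$nuc,
    F_nuc = lca$F_nuc, DAPI_LCA = lca$lca, B_nuc = nm$B_nuc, h = nm$h,
    B_exnuc = B_exnuc, L1 = L1, B_cell = B_cell, d_avg = d_avg,
    B_void = B_void, L2 = L2)
  res
}
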