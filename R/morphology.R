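# Morphological primitives used by the segmentation stage. Thin wrappers over
# the compiled kernels; the conventions (padding, connectivity, tie-breaks)
# are part of the method contract and are pinned by oracle-equivalence tests.

#' Grayscale erosion and dilation with a disc structuring element
#'
#' Erosion takes the minimum and dilation the maximum over a disc of radius
#' `r` pixels (offsets with \eqn{dy^2 + dx^2 \le r^2}). Samples falling
#' outside the frame are ignored, i.e. the image is implicitly padded with
#' \eqn{+\infty} for erosion and \eqn{-\infty} for dilation. Binary masks
#' (logical or 0/1 matrices) are handled as grayscale images.
#'
#' @param img numeric or logical matrix (`[y, x]`).
#' @param r disc radius in pixels (non-negative; may be fractional).
#' @return numeric matrix of the same dimension.
#' @export
gray_erode <- function(img, r) {
  img <- as_num_matrix(img)
  cpp_minmax_filter(img, disc_offsets(r), FALSE)
}

#' @rdname gray_erode
#' @export
gray_dilate <- function(img, r) {
  img <- as_num_matrix(img)
  cpp_minmax_filter(img, disc_offsets(r), TRUE)
}

#' @rdname gray_erode
#' @export
gray_open <- function(img, r) {
  gray_dilate(gray_erode(img, r), r)
}

as_num_matrix <- function(img) {
  if (is.logical(img)) img <- array(as.numeric(img), dim = dim(img))
  check_matrix(img)
  img
}

#' Exact Euclidean distance transform
#'
#' For every pixel, the Euclidean distance (in pixels) to the nearest `TRUE`
#' pixel of `mask`; zero on the mask itself.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  mask <- as_logical_matrix(mask)
  if (!any(mask)) stop("distance transform of an empty mask is undefined", call. = FALSE)
  cpp_edt(mask)
}

as_logical_matrix <- function(mask) {
  if (is.numeric(mask)) mask <- array(mask != 0, dim = dim(mask))
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  mask
}

#' Grayscale reconstruction by dilation
#'
#' Iteratively dilates `marker` (8-connected) while clamping to `mask`, until
#' stability. Requires `marker <= mask` pointwise (enforced by clamping).
#'
#' @param marker,mask numeric matrices of identical dimension.
#' @return the reconstructed image.
#' @export
reconstruct_dilate <- function(marker, mask) {
  check_matrix(marker); check_matrix(mask)
  cpp_reconstruct(marker, mask)
}

#' h-maxima transform
#'
#' Suppresses regional maxima shallower than `h`:
#' `HMAX_h(I) = reconstruct(I - h, I)` by dilation.
#'
#' @param img numeric matrix.
#' @param h suppression height (non-negative).
#' @return numeric matrix.
#' @export
h_maxima <- function(img, h) {
  check_matrix(img)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  cpp_reconstruct(img - h, img)
}

#' Regional maxima
#'
#' 8-connected plateaus with no strictly higher neighbour.
#'
#' @param img numeric matrix.
#' @return logical matrix marking maximal plateaus.
#' @export
regional_maxima <- function(img) {
  check_matrix(img)
  cpp_regional_maxima(img)
}

#' Connected-component labelling
#'
#' Components numbered 1..n in raster order of first encounter.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 4L) {
  cpp_label(as_logical_matrix(mask), as.integer(connectivity))
}

#' Marker-controlled watershed transform
#'
#' Priority-flood watershed: the relief `surface` is flooded from the labelled
#' `markers`, lowest surface value first, 4-connected, with FIFO tie-breaking.
#' Every pixel receives the label of the seed region that reaches it first, so
#' the result is a total partition of the frame (no unlabelled ridge pixels)
#' and marker pixels always keep their label.
#'
#' @param surface numeric matrix (typically a gradient magnitude).
#' @param markers integer matrix; 0 = unlabelled, positive values = seed
#'   labels (need not be contiguous).
#' @return integer matrix of region labels.
#' @export
marker_watershed <- function(surface, markers) {
  check_matrix(surface)
  if (!all(dim(surface) == dim(markers)))
    stop("surface and markers must have identical dimensions", call. = FALSE)
  storage.mode(markers) <- "integer"
  cpp_watershed(surface, markers)
}
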