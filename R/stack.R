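# Containers for raw stacks and in-focus images.

#' Multichannel 3D image stack
#'
#' The raw input of the pipeline: one 3D array per channel, `[y, x, z]`,
#' non-negative intensities, at least 3 slices, plus the planar pixel size.
#' Channel names are free, but the focal-correction and segmentation stages
#' expect the roles `"dapi"`, `"proteinA"` and `"proteinB"`.
#'
#' @param channels named list of numeric 3D arrays of identical dimension.
#' @param pixel_size_um planar pixel size in micrometres (> 0).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of 3D arrays", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array [y, x, z]", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions", call. = FALSE)
  if (dims[[1]][3] < 3L)
    stop("a stack needs at least 3 slices", call. = FALSE)
  if (any(vapply(channels, function(a) any(a < 0), TRUE)))
    stop("stack intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %dx%d px, %d slices, %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size: %g um/px\n", x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

n_slices <- function(stack) dim(stack$channels[[1]])[3]

stack_channel <- function(stack, name) {
  if (!name %in% names(stack$channels))
    stop(sprintf("stack has no channel '%s'", name), call. = FALSE)
  stack$channels[[name]]
}

#' In-focus multichannel image
#'
#' The result of collapsing a stack onto its focus manifold: one 2D matrix per
#' channel plus the manifold used (provenance).
#'
#' @param channels named list of numeric matrices of identical dimension.
#' @param pixel_size_um planar pixel size in micrometres.
#' @param manifold the [fit_focus_manifold()] result used, or `NULL`.
#' @return an object of class `in_focus_image`.
#' @export
in_focus_image <- function(channels, pixel_size_um, manifold = NULL) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  lapply(channels, check_matrix, name = "channel")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, manifold = manifold),
    class = "in_focus_image")
}

#' @export
print.in_focus_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<in_focus_image> %dx%d px, channels: %s\n",
              d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
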