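# File formats: multi-page TIFF for images (channel-major page order for
# stacks), stored as 32-bit samples after scaling into [0, 1] by a per-file
# intensity scale recorded in the JSON sidecar (`<path>.json`) together with
# channel names, slice count and pixel size; quantization is 2^-32 of the
# scale and fully deterministic. Label images are 16-bit (ids round-trip
# exactly); compartment tables are CSV with a config provenance comment line.

tiff_write_pages <- function(pages, path, bits = 32L) {
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all slices of channel 1, then channel 2,
#' ...), 32-bit float. The sidecar records channel names, slice count and
#' pixel size so the file round-trips through [read_stack()].
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  scale <- max(1, vapply(stack$channels, max, 0))
  pages <- list()
  for (ch in names(stack$channels))
    for (k in seq_len(nz))
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][, , k] / scale
  tiff_write_pages(pages, path)
  jsonlite::write_json(
    list(channels = names(stack$channels), n_slices = nz,
         pixel_size_um = stack$pixel_size_um, scale = scale,
         page_order = "channel-major"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel stack from multi-page TIFF
#'
#' Channel assignment and geometry come from the JSON sidecar when present;
#' otherwise `channel_map` (channel name -> channel index in channel-major
#' page order) and `pixel_size_um` must be supplied. A stack without a
#' `"dapi"` channel or without a pixel size is rejected, as are pages of
#' mismatched shape.
#'
#' @param path TIFF path.
#' @param channel_map named integer vector, e.g. `c(dapi = 1, proteinA = 2,
#'   proteinB = 3)`; overrides the sidecar channel names when given.
#' @param pixel_size_um pixel-size override in micrometres.
#' @return an [image_stack].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("TIFF pages have mismatched shapes", call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop("pixel size missing: no sidecar metadata and no `pixel_size_um` override",
         call. = FALSE)
  ch_names <- if (!is.null(channel_map)) names(channel_map) else meta$channels
  if (is.null(ch_names))
    stop("channel assignment missing: no sidecar metadata and no `channel_map`",
         call. = FALSE)
  n_ch <- length(ch_names)
  if (length(pages) %% n_ch != 0L)
    stop(sprintf("%d pages do not divide into %d channels", length(pages), n_ch),
         call. = FALSE)
  nz <- meta$n_slices %||% (length(pages) %/% n_ch)
  if (nz * n_ch != length(pages))
    stop("sidecar slice count inconsistent with page count", call. = FALSE)
  ch_index <- if (!is.null(channel_map)) as.integer(channel_map) else seq_len(n_ch)
  scale <- meta$scale %||% 1
  H <- dims[[1]][1]; W <- dims[[1]][2]
  channels <- lapply(seq_len(n_ch), function(i) {
    block <- (ch_index[i] - 1L) * nz
    arr <- array(0, dim = c(H, W, nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[block + k]] * scale
    arr
  })
  names(channels) <- ch_names
  if (!"dapi" %in% ch_names)
    stop("stack has no 'dapi' channel; focal correction and segmentation need one",
         call. = FALSE)
  image_stack(channels, pixel_size_um)
}

#' Write an in-focus image (one page per channel)
#'
#' @param img an [in_focus_image].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_infocus <- function(img, path) {
  stopifnot(inherits(img, "in_focus_image"))
  scale <- max(1, vapply(img$channels, max, 0))
  tiff_write_pages(lapply(unname(img$channels), function(m) m / scale), path)
  jsonlite::write_json(
    list(channels = names(img$channels), pixel_size_um = img$pixel_size_um,
         scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an in-focus image written by [write_infocus()]
#'
#' @param path TIFF path.
#' @return an [in_focus_image].
#' @export
read_infocus <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- lapply(pages, function(m) m * (meta$scale %||% 1))
  names(pages) <- meta$channels
  in_focus_image(pages, meta$pixel_size_um)
}

#' Write compartment labels as a two-page 16-bit TIFF
#'
#' Page 1 holds the cell ids, page 2 the compartment code (0 none,
#' 1 nucleus, 2 cytoplasm); ids up to 65535 round-trip exactly.
#'
#' @param labels a [compartment_labels()] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "compartment_labels"))
  tiff_write_pages(list(labels$cell_id / 65535, labels$compartment / 65535),
                   path, bits = 16L)
  invisible(path)
}

#' Read compartment labels written by [write_labels()]
#'
#' @param path TIFF path.
#' @return a [compartment_labels()] object.
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) round(m * 65535))
  cell <- array(as.integer(pages[[1]]), dim = dim(pages[[1]]))
  nuc <- array(0L, dim = dim(cell))
  comp <- array(as.integer(pages[[2]]), dim = dim(cell))
  nuc[comp == 1L] <- cell[comp == 1L]
  compartment_labels(cell, nuc)
}

# CSV with a provenance comment line; read back with comment.char = "#".
write_csv_prov <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config: %s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
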