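#' Multi-channel fluorescence image container
#'
#' Named 2D intensity rasters of equal shape with a physical pixel size
#' (square pixels, um per pixel). Coordinates are pixel-centred, row-major,
#' origin top-left; areas downstream are reported in um^2 via
#' `pixel_size_um^2`.
#'
#' @param channels Named list of numeric matrices, all the same dimension,
#'   nonnegative.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @return An object of class `arc_image`.
#' @export
channel_image <- function(channels, pixel_size_um) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("channels must be a non-empty named list of matrices")
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share the same shape")
  neg <- names(channels)[vapply(channels, function(m) any(m < 0), logical(1))]
  if (length(neg)) {
    abort(paste0("negative intensities in channel(s): ",
                 paste(neg, collapse = ", ")))
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be a single positive number")
  }
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "arc_image")
}

#' @export
print.arc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<arc_image> %d x %d px, %g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# channel accessor with a helpful error
get_channel <- function(img, channel) {
  if (!channel %in% names(img$channels)) {
    abort(paste0("no channel '", channel, "'; available: ",
                 paste(names(img$channels), collapse = ", ")))
  }
  img$channels[[channel]]
}

#' Read / write a multi-channel TIFF with side-car metadata
#'
#' Channels are stored as one TIFF directory (page) each. Physical pixel
#' size and channel names live in a YAML side-car (default `<path>.yaml`)
#' with keys `pixel_size_um`, `channels`, `scale` and `integer`. The pixel
#' size is required: the segmentation size filter operates in physical
#' units. Integer-valued images round-trip exactly.
#'
#' @param path TIFF path.
#' @param sidecar Side-car YAML path; defaults to `<path>.yaml`.
#' @return `read_channel_image()` returns an `arc_image`;
#'   `write_channel_image()` returns `path` invisibly.
#' @export
read_channel_image <- function(path, sidecar = NULL) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  sidecar <- sidecar %||% paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    abort(paste0("missing side-car metadata (pixel size is required): ",
                 sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$pixel_size_um)) {
    abort(paste0("side-car has no pixel_size_um entry: ", sidecar))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  ch_names <- meta$channels %||% paste0("ch", seq_along(pages))
  if (length(ch_names) != length(pages)) {
    abort(sprintf("side-car names %d channel(s) but TIFF has %d page(s)",
                  length(ch_names), length(pages)))
  }
  scale <- meta$scale %||% 1
  pages <- lapply(pages, function(p) {
    v <- p * scale
    if (isTRUE(meta$integer)) v <- round(v)
    v
  })
  channel_image(setNames(pages, ch_names), as.numeric(meta$pixel_size_um))
}

#' @rdname read_channel_image
#' @param img An `arc_image`.
#' @export
write_channel_image <- function(img, path, sidecar = NULL) {
  stopifnot(inherits(img, "arc_image"))
  sidecar <- sidecar %||% paste0(path, ".yaml")
  mx <- max(1, vapply(img$channels, max, numeric(1)))
  is_int <- all(vapply(img$channels,
                       function(m) all(m == round(m)), logical(1)))
  pages <- lapply(img$channels, function(m) m / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(
    list(pixel_size_um = img$pixel_size_um, channels = names(img$channels),
         scale = mx, integer = is_int),
    sidecar, precision = 15
  )
  invisible(path)
}

#' Write a labelled ROI mask as 16-bit TIFF
#'
#' @param labels Integer label matrix (0 = background).
#' @param path Output TIFF path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 ROIs; cannot write 16-bit")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
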