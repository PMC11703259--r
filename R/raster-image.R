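#' Multi-channel raster image with physical pixel size
#'
#' The basic image container of the pipeline: a list of equally sized
#' 2-D intensity matrices (one per fluorescence channel), the physical
#' pixel size in nanometres, and the biological role of each channel.
#' The default channel assignment follows the imaging convention
#' CH1 = Bassoon (presynaptic active-zone scaffold), CH2 = PSD95
#' (postsynaptic density scaffold), CH3 = Dyn1xA (endocytic-zone dynamin
#' isoform), at 20 nm per pixel.
#'
#' @param channels List of numeric matrices, all the same dimension.
#' @param pixel_size_nm Physical pixel size in nm (> 0).
#' @param channel_roles Character vector naming each channel's role.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(channels, pixel_size_nm = 20,
                         channel_roles = c("Bassoon", "PSD95", "Dyn1xA")[seq_along(channels)]) {
  stopifnot(is.list(channels), length(channels) >= 1)
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    stop("all channels must be matrices")
  }
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must share one shape")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("pixel_size_nm must be > 0")
  }
  stopifnot(length(channel_roles) == length(channels))
  names(channels) <- channel_roles
  structure(list(channels = channels,
                 pixel_size_nm = pixel_size_nm,
                 channel_roles = channel_roles),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<raster_image> %d x %d px, %g nm/px, channels: %s\n",
              d[1], d[2], x$pixel_size_nm,
              paste(x$channel_roles, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a raster image by role or index
#'
#' @param image A `raster_image`.
#' @param which Channel role (e.g. `"Dyn1xA"`) or integer index.
#' @return The channel matrix.
#' @export
get_channel <- function(image, which) {
  stopifnot(inherits(image, "raster_image"))
  if (is.character(which)) {
    i <- match(which, image$channel_roles)
    if (is.na(i)) stop("no channel with role '", which, "'")
  } else {
    i <- which
  }
  image$channels[[i]]
}

#' Replace the channels of a raster image
#' @keywords internal
set_channels <- function(image, channels) {
  image$channels <- channels
  names(image$channels) <- image$channel_roles
  image
}

#' Write a raster image as a 16-bit multi-channel TIFF
#'
#' Channels are stored in CH1, CH2, CH3 order as samples per pixel.
#' Intensities are scaled linearly to the 16-bit range by a single
#' per-file factor; the factor, pixel size (nm) and channel roles are
#' recorded in a JSON sidecar (`<path>.meta.json`) so that
#' [read_sted_tiff()] restores the original values.
#'
#' @param image A `raster_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sted_tiff <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  d <- dim(image$channels[[1]])
  arr <- array(0, c(d[1], d[2], length(image$channels)))
  for (i in seq_along(image$channels)) arr[, , i] <- image$channels[[i]]
  mx <- max(arr)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(arr / scale, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = image$pixel_size_nm,
                            channel_roles = image$channel_roles,
                            intensity_scale = scale),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_sted_tiff()]
#'
#' @param path File path.
#' @return A `raster_image`; intensities are restored to their original
#'   scale (up to 16-bit quantization).
#' @export
read_sted_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- list(pixel_size_nm = 20, channel_roles = NULL, intensity_scale = 1)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    parsed <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (is.list(parsed)) meta[names(parsed)] <- parsed
  }
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  nch <- dim(img)[3]
  roles <- meta$channel_roles
  if (is.null(roles) || length(roles) != nch) {
    roles <- c("Bassoon", "PSD95", "Dyn1xA")[seq_len(nch)]
  }
  channels <- lapply(seq_len(nch), function(i) {
    img[, , i] * meta$intensity_scale
  })
  raster_image(channels, pixel_size_nm = meta$pixel_size_nm,
               channel_roles = roles)
}

#' Write the ground truth of a synthetic rendering as a JSON sidecar
#'
#' @param truth A truth object (a list).
#' @param image_path Path of the image the truth belongs to; the sidecar
#'   is written next to it with extension `.truth.json`.
#' @return The sidecar path, invisibly.
#' @export
write_truth_json <- function(truth, image_path) {
  out <- sub("\\.tiff?$", "", image_path)
  out <- paste0(out, ".truth.json")
  jsonlite::write_json(unclass(truth), out, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out)
}

#' Display range for quality-control rendering
#'
#' Returns the 1st-99th percentile intensity range of a channel, the
#' scaling used for QC figures only; analysis always uses min-max
#' normalized values.
#'
#' @param m Numeric matrix.
#' @return Length-2 numeric vector (low, high).
#' @export
display_range <- function(m) {
  unname(stats::quantile(m, c(0.01, 0.99)))
}
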