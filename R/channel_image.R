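#' Laurdan emission bands
#'
#' The two emission windows recorded for the ratiometric Laurdan readout:
#' a blue band (400--460 nm, sensitive to gel-phase packing) and a green
#' band (470--530 nm, sensitive to the liquid-crystalline phase).
#'
#' @format Character vector of the two band tags.
#' @export
LAURDAN_BANDS <- c("blue_400_460", "green_470_530")

#' Single-band fluorescence intensity image
#'
#' Container for one emission channel of a two-channel Laurdan acquisition:
#' a non-negative intensity raster (photon-count scale) tagged with its
#' emission band and pixel pitch.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = image
#'   rows, origin top-left, 0-based pixel coordinates in all reported
#'   positions).
#' @param band One of `LAURDAN_BANDS`.
#' @param pixel_size_nm Positive pixel pitch in nanometres (default 200).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, band, pixel_size_nm = 200) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  band <- match.arg(band, LAURDAN_BANDS)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar", call. = FALSE)
  structure(
    list(pixels = pixels, band = band, pixel_size_nm = pixel_size_nm),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px @ %g nm/px, range [%g, %g]\n",
              x$band, nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# shared precondition for every two-channel operation
check_pair <- function(blue, green) {
  stopifnot(inherits(blue, "channel_image"), inherits(green, "channel_image"))
  if (!identical(dim(blue$pixels), dim(green$pixels)))
    stop("channel images have mismatched shapes", call. = FALSE)
  if (!isTRUE(all.equal(blue$pixel_size_nm, green$pixel_size_nm)))
    stop("channel images have mismatched pixel sizes", call. = FALSE)
  invisible(TRUE)
}

#' Read a channel image from a 16-bit grayscale TIFF
#'
#' Intensities are restored to the photon-count scale (the writer stores
#' `counts / 65535`), so a write/read round trip is lossless for integer
#' counts up to 65535.
#'
#' @param path TIFF file path.
#' @param band Emission band tag for the loaded image.
#' @param pixel_size_nm Pixel pitch in nanometres.
#' @return A `channel_image`.
#' @export
read_channel_tiff <- function(path, band, pixel_size_nm = 200) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  channel_image(round(raw * 65535), band, pixel_size_nm)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' @param image A `channel_image`; counts above 65535 are clipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  tiff::writeTIFF(pmin(image$pixels, 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}
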