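#' Generalized polarization (GP) mapping
#'
#' The membrane-order readout of the Laurdan probe. Per pixel,
#' \deqn{GP = \frac{I_{400-460} - G\, I_{470-530}}{I_{400-460} + G\, I_{470-530}}}
#' where G is the instrument calibration factor correcting the relative
#' detection efficiency of the two emission bands. GP ranges from -1
#' (liquid-crystalline, fluid) to +1 (gel, ordered), and, being a
#' normalized intensity ratio, is independent of excitation intensity and
#' probe concentration.
#'
#' @name gp_imaging
NULL

#' Subtract a measured background level from a channel image
#'
#' Per-pixel `max(0, pixel - background)`; the result never goes negative
#' so downstream ratios stay in range.
#'
#' @param image A `channel_image`.
#' @param background Non-negative scalar background level.
#' @return A `channel_image` of the same shape.
#' @export
subtract_background <- function(image, background) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.numeric(background) || length(background) != 1L ||
      is.na(background) || background < 0)
    stop("`background` must be a non-negative scalar", call. = FALSE)
  out <- image
  out$pixels <- pmax(image$pixels - background, 0)
  out
}

# Otsu threshold on an arbitrary-scale raster; returns the threshold on the
# input scale, or NA for a constant raster.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  thr01 <- EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * diff(rng)
}

#' Estimate the image background level
#'
#' The background is taken as the mean intensity of the pixels below the
#' global Otsu threshold of the image (the dark, cell-free class). A
#' constant image has no below-threshold class and returns 0.
#'
#' @param image A `channel_image`.
#' @return Non-negative scalar background estimate.
#' @export
estimate_background <- function(image) {
  stopifnot(inherits(image, "channel_image"))
  px <- image$pixels
  if (length(px) == 0L) stop("empty image", call. = FALSE)
  thr <- otsu_threshold(px)
  if (is.na(thr)) return(0)
  low <- px[px < thr]
  if (length(low) == 0L) return(0)
  mean(low)
}

#' Segment cells and drop debris
#'
#' Otsu threshold on the summed two-channel intensity, followed by an
#' 8-connected component area filter: components smaller than
#' `min_area_px` (debris, aggregates) are discarded. The default of 100 px
#' is 4 square microns at the 200 nm pitch, far below an RBC footprint.
#'
#' @param blue,green The two `channel_image`s of a pair.
#' @param min_area_px Minimum retained component area in pixels.
#' @return Logical matrix, `TRUE` on retained foreground. An all-background
#'   frame yields an empty (all-`FALSE`) mask; downstream operations reject
#'   empty masks themselves.
#' @export
segment_cells <- function(blue, green, min_area_px = 100L) {
  check_pair(blue, green)
  stopifnot(min_area_px >= 1)
  total <- blue$pixels + green$pixels
  thr <- otsu_threshold(total)
  if (is.na(thr)) return(matrix(FALSE, nrow(total), ncol(total)))
  fg <- total > thr
  if (!any(fg)) return(fg)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  matrix(lab %in% keep, nrow(total), ncol(total))
}

#' Compute the per-pixel GP map
#'
#' Applies the ratiometric GP formula to a background-subtracted image
#' pair. Pixels whose total (G-weighted) intensity does not exceed
#' `denom_tol` are removed from the mask rather than producing unstable
#' ratios. Off-mask values are `NA`, never silently zero.
#'
#' @param blue,green Background-subtracted `channel_image`s.
#' @param g Positive G-factor calibration constant (default 1; the value is
#'   instrument-specific and must be supplied by calibration).
#' @param mask Logical matrix of candidate membrane pixels; defaults to the
#'   whole frame.
#' @param denom_tol Positive tolerance on the denominator, on the
#'   background-subtracted intensity scale.
#' @return A `gp_map`: list with `values` (numeric matrix, `NA` off mask),
#'   `mask` (logical matrix), and `g`.
#' @export
compute_gp_map <- function(blue, green, g = 1, mask = NULL,
                           denom_tol = 1e-9) {
  check_pair(blue, green)
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("G-factor must be a positive scalar", call. = FALSE)
  b <- blue$pixels
  gr <- green$pixels
  if (blue$band != "blue_400_460") {
    # accept swapped argument order only if bands identify the channels
    if (blue$band == "green_470_530" && green$band == "blue_400_460") {
      tmp <- b; b <- gr; gr <- tmp
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(b), ncol(b))
  if (!identical(dim(mask), dim(b)))
    stop("mask shape does not match the images", call. = FALSE)
  denom <- b + g * gr
  ok <- mask & denom > denom_tol
  if (!any(ok))
    stop("empty mask after removing zero-intensity pixels", call. = FALSE)
  values <- matrix(NA_real_, nrow(b), ncol(b))
  values[ok] <- (b[ok] - g * gr[ok]) / denom[ok]
  # exact algebra keeps |GP| <= 1 for non-negative inputs; guard rounding
  values[ok] <- pmin(pmax(values[ok], -1), 1)
  structure(list(values = values, mask = ok, g = g), class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<gp_map> %d x %d px, %d valid px, mean GP %.4f\n",
              nrow(x$values), ncol(x$values), sum(x$mask), mean(v)))
  invisible(x)
}

#' Summarize a GP map
#'
#' Mean, population variance and a fixed-edge histogram over \[-1, 1\] of
#' the masked GP values. Fixed edges keep histograms comparable across
#' patients and acquisitions.
#'
#' @param gp A `gp_map`.
#' @param n_bins Number of histogram bins over \[-1, 1\] (default 100).
#' @return A `gp_summary`: list with `mean_gp`, `variance_gp`, `n_pixels`,
#'   `breaks` (length `n_bins + 1`) and `counts` (length `n_bins`,
#'   summing to `n_pixels`).
#' @export
gp_summary <- function(gp, n_bins = 100L) {
  stopifnot(inherits(gp, "gp_map"), n_bins >= 1)
  v <- gp$values[gp$mask]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  counts <- hist(v, breaks = breaks, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  structure(list(
    mean_gp = mean(v),
    variance_gp = mean((v - mean(v))^2),
    n_pixels = length(v),
    breaks = breaks,
    counts = counts
  ), class = "gp_summary")
}

#' Write a GP map to disk
#'
#' Two artifacts: a two-page 32-bit float TIFF holding `(GP + 1) / 2` on
#' page 1 (the TIFF writer only stores \[0, 1\] floats; the shift is inverted
#' by [read_gp_map_tiff()]) and the validity mask on page 2; and an 8-bit
#' RGB PNG on the conventional two-color scale, red = fluid (GP = -1) to
#' green = gel (GP = +1), off-mask pixels black.
#'
#' @param gp A `gp_map`.
#' @param tiff_path,png_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_gp_map <- function(gp, tiff_path = NULL, png_path = NULL) {
  stopifnot(inherits(gp, "gp_map"))
  v01 <- (gp$values + 1) / 2
  v01[!gp$mask] <- 0
  if (!is.null(tiff_path)) {
    tiff::writeTIFF(list(v01, gp$mask * 1), tiff_path, bits.per.sample = 32L)
  }
  if (!is.null(png_path)) {
    rgb <- array(0, dim = c(nrow(v01), ncol(v01), 3L))
    rgb[, , 1][gp$mask] <- 1 - v01[gp$mask]
    rgb[, , 2][gp$mask] <- v01[gp$mask]
    png::writePNG(rgb, png_path)
  }
  invisible(c(tiff = tiff_path, png = png_path))
}

#' Read back a GP map written by [write_gp_map()]
#'
#' @param tiff_path Path to the two-page float TIFF.
#' @return A `gp_map` (G-factor metadata is not stored; `g` is `NA`).
#' @export
read_gp_map_tiff <- function(tiff_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != 2L) stop("expected a two-page GP TIFF", call. = FALSE)
  mask <- pages[[2]] > 0.5
  values <- pages[[1]] * 2 - 1
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, g = NA_real_),
            class = "gp_map")
}
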