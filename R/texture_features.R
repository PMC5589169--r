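#' Texture descriptor configuration: gray-level co-occurrence
#'
#' @param n_levels Quantization levels over the masked intensity range
#'   (default 32; stable matrices at the ~10^4 pixels of one cell).
#' @param offsets List of `(row, col)` integer displacements; defaults to
#'   the four standard directions at distance 1.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @param normalize Normalize the matrix to sum 1 (default `TRUE`).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(n_levels = 32L,
                        offsets = list(c(0L, 1L), c(1L, 1L),
                                       c(1L, 0L), c(1L, -1L)),
                        symmetric = TRUE, normalize = TRUE) {
  stopifnot(n_levels >= 2, length(offsets) >= 1)
  structure(list(n_levels = as.integer(n_levels), offsets = offsets,
                 symmetric = symmetric, normalize = normalize),
            class = "glcm_config")
}

#' Texture descriptor configuration: rotation-invariant co-occurrence LBP
#'
#' @param radius_px Neighborhood radius (chessboard ring of 8 neighbors).
#' @param n_points Neighbors per ring; the implementation requires 8 (the
#'   rotation group is 90-degree steps realized as circular bit-shifts).
#' @param pair_displacement_px Displacement between the two LBP codes of a
#'   co-occurring pair.
#' @return A `riclbp_config` list.
#' @export
riclbp_config <- function(radius_px = 1L, n_points = 8L,
                          pair_displacement_px = 2L) {
  stopifnot(radius_px >= 1, pair_displacement_px >= 1)
  if (n_points != 8L)
    stop("only 8-point neighborhoods are supported", call. = FALSE)
  structure(list(radius_px = as.integer(radius_px), n_points = 8L,
                 pair_displacement_px = as.integer(pair_displacement_px)),
            class = "riclbp_config")
}

as_raster <- function(image) {
  if (inherits(image, "channel_image")) image$pixels else image
}

#' First-order statistical descriptors
#'
#' Mean, population variance, skewness, excess kurtosis, and gray-level
#' histogram energy and entropy (bits) over the masked pixels. Skewness
#' and kurtosis of a constant region are defined as 0; a constant region
#' has entropy 0 and energy 1.
#'
#' @param image Numeric matrix or `channel_image`.
#' @param mask Logical matrix; defaults to the full frame.
#' @param n_gray_bins Histogram bins for energy/entropy (default 64).
#' @return Named numeric `feature_vector`.
#' @export
first_order_features <- function(image, mask = NULL, n_gray_bins = 64L) {
  x <- as_raster(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  v <- x[mask]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 > 0) {
    skew <- mean((v - m)^3) / s2^1.5
    kurt <- mean((v - m)^4) / s2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  rng <- range(v)
  if (diff(rng) == 0) {
    p <- 1
  } else {
    bin <- pmin(floor((v - rng[1]) / diff(rng) * n_gray_bins) + 1L,
                n_gray_bins)
    p <- tabulate(bin, n_gray_bins) / length(v)
    p <- p[p > 0]
  }
  out <- c(fo_mean = m, fo_variance = s2, fo_skewness = skew,
           fo_kurtosis = kurt, fo_energy = sum(p^2),
           fo_entropy = -sum(p * log2(p)))
  structure(out, class = c("feature_vector", "numeric"))
}

# quantize masked intensities to 1..n_levels equal-width bins
quantize_levels <- function(x, mask, n_levels) {
  q <- matrix(NA_integer_, nrow(x), ncol(x))
  v <- x[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(floor((v - rng[1]) / diff(rng) * n_levels) + 1L,
                    n_levels)
  }
  q
}

# co-occurrence counts of quantized levels at one displacement, mask-aware
glcm_matrix_one <- function(q, offset, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  idx <- (b[ok] - 1L) * n_levels + a[ok]
  matrix(tabulate(idx, n_levels * n_levels), n_levels, n_levels)
}

#' Gray-level co-occurrence (second-order) descriptors
#'
#' The image is quantized to `n_levels` equal-width bins over the masked
#' intensity range; for each offset a (symmetric, normalized)
#' co-occurrence matrix is accumulated over pixel pairs lying inside the
#' mask, and `{contrast, correlation, energy, homogeneity, entropy}` are
#' averaged over offsets. Correlation of a degenerate (zero-variance)
#' matrix is defined as 0.
#'
#' @param image Numeric matrix or `channel_image`.
#' @param mask Logical matrix; defaults to the full frame.
#' @param cfg A [glcm_config()].
#' @return Named numeric `feature_vector`.
#' @export
glcm_features <- function(image, mask = NULL, cfg = glcm_config()) {
  x <- as_raster(image)
  stopifnot(inherits(cfg, "glcm_config"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  q <- quantize_levels(x, mask, cfg$n_levels)
  feats <- matrix(0, length(cfg$offsets), 5L)
  got_pairs <- FALSE
  for (i in seq_along(cfg$offsets)) {
    P <- glcm_matrix_one(q, cfg$offsets[[i]], cfg$n_levels)
    if (cfg$symmetric) P <- P + t(P)
    tot <- sum(P)
    if (tot == 0) { feats[i, ] <- NA; next }
    got_pairs <- TRUE
    if (cfg$normalize) P <- P / tot
    lev <- seq_len(cfg$n_levels)
    pi_ <- rowSums(P); pj_ <- colSums(P)
    mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
    sd_i <- sqrt(sum((lev - mu_i)^2 * pi_))
    sd_j <- sqrt(sum((lev - mu_j)^2 * pj_))
    dif <- outer(lev, lev, `-`)
    contrast <- sum(P * dif^2)
    correlation <- if (sd_i > 0 && sd_j > 0)
      sum(P * outer(lev - mu_i, lev - mu_j)) / (sd_i * sd_j) else 0
    energy <- sum(P^2)
    homogeneity <- sum(P / (1 + abs(dif)))
    pnz <- P[P > 0]
    entropy <- -sum(pnz * log2(pnz))
    feats[i, ] <- c(contrast, correlation, energy, homogeneity, entropy)
  }
  if (!got_pairs) stop("no valid pixel pairs under the mask", call. = FALSE)
  out <- colMeans(feats, na.rm = TRUE)
  names(out) <- c("glcm_contrast", "glcm_correlation", "glcm_energy",
                  "glcm_homogeneity", "glcm_entropy")
  structure(out, class = c("feature_vector", "numeric"))
}

# 8-neighbor ring offsets in circular order (45-degree steps); a 90-degree
# image rotation shifts this ring by exactly 2 positions
ring_offsets <- function(r) {
  list(c(0, r), c(-r, r), c(-r, 0), c(-r, -r),
       c(0, -r), c(r, -r), c(r, 0), c(r, r))
}

# minimum over the 8 circular bit-shifts of an 8-bit code
ri_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:255
      best <- codes
      for (s in 1:7) {
        shifted <- bitwOr(bitwAnd(bitwShiftR(codes, s), 255),
                          bitwAnd(bitwShiftL(codes, 8 - s), 255))
        best <- pmin(best, shifted)
      }
      tab <<- best
    }
    tab
  }
})

#' Rotation-invariant local binary pattern codes
#'
#' Per interior pixel, an 8-bit code comparing each ring neighbor to the
#' center (neighbor >= center sets the bit, so ties set bits and a
#' constant image yields the all-ones pattern), mapped to its
#' rotation-invariant representative: the minimum over all circular
#' bit-shifts. Because comparisons are against the center, adding a
#' constant to the image changes no code.
#'
#' @param image Numeric matrix or `channel_image`.
#' @param cfg A [riclbp_config()].
#' @return Integer matrix of representative codes; the border of width
#'   `radius_px` is `NA`.
#' @export
lbp_codes <- function(image, cfg = riclbp_config()) {
  x <- as_raster(image)
  stopifnot(inherits(cfg, "riclbp_config"))
  r <- cfg$radius_px
  nr <- nrow(x); nc <- ncol(x)
  if (nr <= 2 * r || nc <= 2 * r)
    stop("image too small for the LBP radius", call. = FALSE)
  ri <- (r + 1):(nr - r)
  ci <- (r + 1):(nc - r)
  center <- x[ri, ci, drop = FALSE]
  code <- matrix(0L, length(ri), length(ci))
  offs <- ring_offsets(r)
  for (k in seq_along(offs)) {
    nb <- x[ri + offs[[k]][1], ci + offs[[k]][2], drop = FALSE]
    code <- code + bitwShiftL(as.integer(nb >= center), k - 1L)
  }
  out <- matrix(NA_integer_, nr, nc)
  out[ri, ci] <- ri_lookup()[code + 1L]
  out
}

# the 36 rotation-invariant representatives for 8-bit codes
ri_representatives <- function() sort(unique(ri_lookup()))

#' Rotation-invariant co-occurrence LBP descriptor
#'
#' Normalized joint histogram of rotation-invariant LBP code pairs at
#' displacement `pair_displacement_px`, pooled over the four directions
#' (0, 45, 90, 135 degrees) and over pair order, so each unordered,
#' rotation-equivalent pair class occupies one bin. Restricted to pairs
#' whose both pixels carry valid codes (and lie in `mask` if given). By
#' construction the descriptor is exactly invariant to 90/180/270-degree
#' rotations of a square input.
#'
#' @param image Numeric matrix or `channel_image`.
#' @param mask Optional logical matrix restriction.
#' @param cfg A [riclbp_config()].
#' @return Named numeric `feature_vector` of length 666 (unordered pairs
#'   of the 36 code classes), summing to 1.
#' @export
riclbp_features <- function(image, mask = NULL, cfg = riclbp_config()) {
  codes <- lbp_codes(image, cfg)
  reps <- ri_representatives()
  cls <- matrix(match(codes, reps), nrow(codes), ncol(codes))
  if (!is.null(mask)) cls[!mask] <- NA_integer_
  d <- cfg$pair_displacement_px
  n_cls <- length(reps)
  counts <- numeric(n_cls * n_cls)
  for (off in list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))) {
    nr <- nrow(cls); nc <- ncol(cls)
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- cls[r1, c1, drop = FALSE]
    b <- cls[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
    idx <- (hi - 1L) * n_cls + lo
    counts <- counts + tabulate(idx, n_cls * n_cls)
  }
  # unordered pair (lo, hi) with lo <= hi lives at (hi - 1) * n_cls + lo;
  # upper.tri in column-major order gives a fixed bin order
  keep <- which(upper.tri(matrix(0, n_cls, n_cls), diag = TRUE),
                arr.ind = TRUE)
  pair_lo <- keep[, 1]
  pair_hi <- keep[, 2]
  sel <- (pair_hi - 1L) * n_cls + pair_lo
  h <- counts[sel]
  tot <- sum(h)
  if (tot == 0) stop("no valid code pairs under the mask", call. = FALSE)
  h <- h / tot
  names(h) <- sprintf("riclbp_%03d_%03d", reps[pair_lo], reps[pair_hi])
  structure(h, class = c("feature_vector", "numeric"))
}

#' Extract the full per-channel descriptor set for one image pair
#'
#' Concatenates first-order, co-occurrence and RICLBP descriptors per
#' emission channel; the two channel vectors stay separate because they
#' feed separate classification pipelines. Features are computed
#' full-frame by default; pass `mask` to restrict to segmented cells.
#'
#' @param pair List with `blue` and `green` `channel_image`s.
#' @param mask Optional logical matrix (applied to first-order and GLCM
#'   statistics and to RICLBP pair selection).
#' @param glcm_cfg,riclbp_cfg Descriptor configurations.
#' @return List with `blue` and `green` named `feature_vector`s; names are
#'   identical across images of a run (schema stability).
#' @export
extract_features <- function(pair, mask = NULL,
                             glcm_cfg = glcm_config(),
                             riclbp_cfg = riclbp_config()) {
  check_pair(pair$blue, pair$green)
  one <- function(img) {
    c(first_order_features(img, mask),
      glcm_features(img, mask, glcm_cfg),
      riclbp_features(img, mask, riclbp_cfg))
  }
  list(blue = one(pair$blue), green = one(pair$green))
}

#' Extract features for every image of a cohort
#'
#' @param cohort An `rbc_cohort`.
#' @param mask_mode `"full"` (default; descriptors over the whole frame)
#'   or `"cell"` (restricted to the segmented cell mask of each pair).
#' @param glcm_cfg,riclbp_cfg Descriptor configurations.
#' @param min_area_px Debris filter for `mask_mode = "cell"`.
#' @return A `feature_cohort`: list with `patients` (per patient: `id`,
#'   `group`, and `blue` / `green` feature matrices with one row per z)
#'   and `feature_names`.
#' @export
extract_cohort_features <- function(cohort, mask_mode = c("full", "cell"),
                                    glcm_cfg = glcm_config(),
                                    riclbp_cfg = riclbp_config(),
                                    min_area_px = 100L) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  mask_mode <- match.arg(mask_mode)
  patients <- lapply(cohort$patients, function(p) {
    rows <- lapply(p$stack, function(zimg) {
      mask <- if (mask_mode == "cell")
        segment_cells(zimg$blue, zimg$green, min_area_px) else NULL
      extract_features(zimg, mask, glcm_cfg, riclbp_cfg)
    })
    list(
      id = p$id, group = p$group,
      blue = do.call(rbind, lapply(rows, function(r) unclass(r$blue))),
      green = do.call(rbind, lapply(rows, function(r) unclass(r$green)))
    )
  })
  structure(list(
    patients = patients,
    feature_names = colnames(patients[[1]]$blue)
  ), class = "feature_cohort")
}

#' Write a feature cohort as a long-format CSV
#'
#' One row per (patient, z, channel); columns are the descriptor names,
#' written once in the header.
#'
#' @param features A `feature_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_cohort"))
  rows <- list()
  for (p in features$patients) {
    for (ch in c("blue", "green")) {
      m <- p[[ch]]
      for (z in seq_len(nrow(m))) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p$id, group = p$group, z = z, channel = ch,
          t(m[z, ]), check.names = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
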