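#' Membrane-field simulation parameters
#'
#' Conditions for generating class-dependent synthetic GP fields on an
#' annular red-blood-cell footprint. The absolute per-group GP levels are
#' declared simulation settings chosen to reproduce the qualitative
#' disease ordering (means decreasing, heterogeneity increasing from
#' healthy controls G0 through uncomplicated diabetes G1 to complicated
#' diabetes G2); they are not measured values. Fluid-domain geometry
#' follows the reported regime: circular clusters with diameters in
#' 500--1000 nm whose number grows with disease stage.
#'
#' @param base_gp_mean Named numeric, baseline (cluster-free) membrane GP
#'   per group.
#' @param base_gp_sd SD of the smooth baseline GP texture.
#' @param gp_correlation_length_um Correlation length of the baseline
#'   texture (Gaussian smoothing scale), in microns.
#' @param expected_clusters_per_cell Named numeric, expected fluid-domain
#'   count per cell and group; converted internally to a surface density
#'   over the membrane annulus.
#' @param cluster_diameter_nm Length-2 range (low < high) of cluster
#'   diameters, in nanometres.
#' @param cluster_gp_drop GP decrease inside each cluster disc; overlapping
#'   discs stack and the field is clamped to \[-1, 1\].
#' @param cell_outer_radius_um,cell_inner_radius_um Annular footprint radii
#'   (membrane-dominated signal: Laurdan labels only the plasma membrane).
#' @param photon_budget Expected total photon count per membrane pixel
#'   (both channels combined).
#' @param background_photons Expected photon count per off-membrane pixel
#'   and channel.
#' @param read_noise_sd Additive Gaussian read noise SD (0 = off).
#' @param g_factor Instrument G-factor used when rendering the two
#'   channels.
#' @return A `membrane_field_params` list.
#' @export
membrane_field_params <- function(
    base_gp_mean = c(G0 = 0.45, G1 = 0.40, G2 = 0.33),
    base_gp_sd = 0.05,
    gp_correlation_length_um = 1,
    expected_clusters_per_cell = c(G0 = 0, G1 = 40, G2 = 120),
    cluster_diameter_nm = c(500, 1000),
    cluster_gp_drop = 0.25,
    cell_outer_radius_um = 3.5,
    cell_inner_radius_um = 2.5,
    photon_budget = 2000,
    background_photons = 100,
    read_noise_sd = 0,
    g_factor = 1) {
  stopifnot(
    all(GROUP_LEVELS %in% names(base_gp_mean)),
    all(GROUP_LEVELS %in% names(expected_clusters_per_cell)),
    base_gp_sd >= 0,
    length(cluster_diameter_nm) == 2L,
    cluster_diameter_nm[1] > 0,
    cluster_diameter_nm[1] < cluster_diameter_nm[2],
    cluster_gp_drop > 0,
    cell_inner_radius_um > 0,
    cell_inner_radius_um < cell_outer_radius_um,
    photon_budget > 0, background_photons >= 0, read_noise_sd >= 0,
    g_factor > 0
  )
  cl <- expected_clusters_per_cell[GROUP_LEVELS]
  if (is.unsorted(cl))
    stop("cluster counts must be non-decreasing G0 -> G1 -> G2",
         call. = FALSE)
  structure(list(
    base_gp_mean = base_gp_mean,
    base_gp_sd = base_gp_sd,
    gp_correlation_length_um = gp_correlation_length_um,
    expected_clusters_per_cell = expected_clusters_per_cell,
    cluster_diameter_nm = cluster_diameter_nm,
    cluster_gp_drop = cluster_gp_drop,
    cell_outer_radius_um = cell_outer_radius_um,
    cell_inner_radius_um = cell_inner_radius_um,
    photon_budget = photon_budget,
    background_photons = background_photons,
    read_noise_sd = read_noise_sd,
    g_factor = g_factor
  ), class = "membrane_field_params")
}

# membrane annulus area in square microns
membrane_area_um2 <- function(params) {
  pi * (params$cell_outer_radius_um^2 - params$cell_inner_radius_um^2)
}

#' Simulate a ground-truth GP field for one cell
#'
#' Places an annular cell mask centrally (with positional jitter), draws a
#' spatially smooth baseline GP texture around the group's base level
#' (low-pass-filtered white noise rescaled to `base_gp_sd`), then nucleates
#' `N ~ Poisson(density x membrane area)` circular fluid domains with
#' diameters uniform in the configured range, each lowering GP by
#' `cluster_gp_drop` inside its disc (overlaps stack; the field is clamped
#' to \[-1, 1\]). All ground truth is returned for downstream validation.
#'
#' @param group A group label, one of `"G0"`, `"G1"`, `"G2"`.
#' @param params A [membrane_field_params()] object.
#' @param image_size_px Square frame side, in pixels.
#' @param pixel_size_nm Pixel pitch, nanometres.
#' @param base_gp_shift Additive patient-level offset on the baseline GP
#'   (used by the cohort simulator for therapy and between-patient
#'   effects).
#' @param seed Optional integer; when given, the local RNG state is seeded
#'   and restored on exit.
#' @return A `gp_field`: list with `gp` (matrix, `NA` off mask), `mask`
#'   (logical), `clusters` (data.frame of centers, radii and diameters),
#'   `true_mean_gp`, `true_var_gp`, `group`, `pixel_size_nm`.
#' @export
simulate_gp_field <- function(group, params, image_size_px = 256L,
                              pixel_size_nm = 200, base_gp_shift = 0,
                              seed = NULL) {
  group <- match.arg(group, GROUP_LEVELS)
  stopifnot(inherits(params, "membrane_field_params"), image_size_px >= 8)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  n <- as.integer(image_size_px)
  px_um <- pixel_size_nm / 1000
  r_out <- params$cell_outer_radius_um / px_um
  r_in <- params$cell_inner_radius_um / px_um
  if (2 * r_out >= n)
    stop("cell does not fit in the frame at this pixel size", call. = FALSE)
  # central placement with jitter up to 5% of the frame
  jit <- (n / 20)
  cy <- n / 2 + runif(1, -jit, jit)
  cx <- n / 2 + runif(1, -jit, jit)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (rows - cy)^2 + (cols - cx)^2
  mask <- d2 <= r_out^2 & d2 >= r_in^2
  if (!any(mask)) stop("degenerate cell mask (area 0)", call. = FALSE)

  # smooth baseline: low-pass filtered white noise rescaled to base_gp_sd
  base <- params$base_gp_mean[[group]] + base_gp_shift
  gp <- matrix(base, n, n)
  if (params$base_gp_sd > 0) {
    noise <- matrix(rnorm(n * n), n, n)
    sigma_px <- params$gp_correlation_length_um / px_um
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(noise),
                                            sigma = sigma_px))
    sm <- (sm - mean(sm)) / stats::sd(sm) * params$base_gp_sd
    gp <- gp + sm
  }

  # Poisson fluid-domain nucleation over the membrane
  density <- params$expected_clusters_per_cell[[group]] /
    membrane_area_um2(params)
  lambda <- density * membrane_area_um2(params)
  n_cl <- stats::rpois(1, lambda)
  idx <- which(mask)
  clusters <- data.frame(row = integer(0), col = integer(0),
                         radius_px = numeric(0), diameter_nm = numeric(0))
  if (n_cl > 0) {
    centers <- sample(idx, n_cl, replace = TRUE)
    dia_nm <- runif(n_cl, params$cluster_diameter_nm[1],
                    params$cluster_diameter_nm[2])
    r_px <- dia_nm / 2 / pixel_size_nm
    ctr_row <- ((centers - 1L) %% n) + 1L
    ctr_col <- ((centers - 1L) %/% n) + 1L
    for (k in seq_len(n_cl)) {
      r <- r_px[k]
      rr <- max(1L, floor(ctr_row[k] - r)):min(n, ceiling(ctr_row[k] + r))
      cc <- max(1L, floor(ctr_col[k] - r)):min(n, ceiling(ctr_col[k] + r))
      sub <- outer((rr - ctr_row[k])^2, (cc - ctr_col[k])^2, `+`) <= r^2
      gp[rr, cc][sub] <- gp[rr, cc][sub] - params$cluster_gp_drop
    }
    clusters <- data.frame(row = ctr_row, col = ctr_col, radius_px = r_px,
                           diameter_nm = dia_nm)
  }
  gp <- pmin(pmax(gp, -1), 1)
  gp[!mask] <- NA_real_
  v <- gp[mask]
  structure(list(
    gp = gp, mask = mask, clusters = clusters,
    true_mean_gp = mean(v), true_var_gp = mean((v - mean(v))^2),
    group = group, pixel_size_nm = pixel_size_nm
  ), class = "gp_field")
}

#' Render a GP field into a two-channel image pair
#'
#' Inverts the ratiometric GP relation: per membrane pixel the total
#' (G-weighted) signal is the photon budget S, split as
#' `I_blue = S (1 + GP) / 2` and `I_green = S (1 - GP) / (2 G)`, so that
#' recomputing GP from a noiseless pair recovers the field exactly.
#' Off-mask pixels receive the background level in each channel.
#' Independent Poisson noise is applied per channel (plus optional
#' Gaussian read noise).
#'
#' @param field A `gp_field` (or any list with `gp`, `mask`,
#'   `pixel_size_nm`).
#' @param params A [membrane_field_params()] object.
#' @param noise Logical; `FALSE` renders expected values only.
#' @param seed Optional integer seed, restored on exit.
#' @return List with `blue` and `green` `channel_image`s.
#' @export
render_channels <- function(field, params, noise = TRUE, seed = NULL) {
  stopifnot(inherits(params, "membrane_field_params"))
  gp <- field$gp
  mask <- field$mask
  if (any(!is.finite(gp[mask])))
    stop("non-finite GP values in the field", call. = FALSE)
  if (any(abs(gp[mask]) > 1))
    stop("GP values outside [-1, 1]", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  S <- params$photon_budget
  g <- params$g_factor
  blue <- matrix(params$background_photons, nrow(gp), ncol(gp))
  green <- blue
  blue[mask] <- S * (1 + gp[mask]) / 2
  green[mask] <- S * (1 - gp[mask]) / (2 * g)
  if (noise) {
    blue[] <- stats::rpois(length(blue), blue)
    green[] <- stats::rpois(length(green), green)
    if (params$read_noise_sd > 0) {
      blue[] <- pmax(blue + rnorm(length(blue), 0, params$read_noise_sd), 0)
      green[] <- pmax(green + rnorm(length(green), 0, params$read_noise_sd), 0)
    }
  }
  list(
    blue = channel_image(blue, "blue_400_460", field$pixel_size_nm),
    green = channel_image(green, "green_470_530", field$pixel_size_nm)
  )
}

# save/restore helpers so seeded helpers do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
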