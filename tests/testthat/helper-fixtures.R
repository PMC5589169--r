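# shared fixtures and independent oracles

# scalar brute-force GP (the one-pixel formula, independent of the
# vectorized implementation)
scalar_gp <- function(i_blue, i_green, g) {
  (i_blue - g * i_green) / (i_blue + g * i_green)
}

# direct-summation moments over a vector
oracle_moments <- function(v) {
  m <- sum(v) / length(v)
  s2 <- sum((v - m)^2) / length(v)
  list(
    mean = m, variance = s2,
    skewness = if (s2 > 0) (sum((v - m)^3) / length(v)) / s2^1.5 else 0,
    kurtosis = if (s2 > 0) (sum((v - m)^4) / length(v)) / s2^2 - 3 else 0
  )
}

# closed-form normal-equation OLS
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# textbook Welch t statistic and df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

make_channel_pair <- function(blue_px, green_px, pixel_size_nm = 200) {
  list(
    blue = channel_image(blue_px, "blue_400_460", pixel_size_nm),
    green = channel_image(green_px, "green_470_530", pixel_size_nm)
  )
}

# small, fast field parameters for module-level tests (not the study
# defaults; those are exercised in the acceptance suite)
small_field_params <- function(
    expected_clusters_per_cell = c(G0 = 0, G1 = 15, G2 = 45), ...) {
  membrane_field_params(
    cell_outer_radius_um = 2.4, cell_inner_radius_um = 1.6,
    expected_clusters_per_cell = expected_clusters_per_cell, ...
  )
}

small_cohort_config <- function(n_per_group = c(2, 2, 2),
                                images_per_patient = 2,
                                image_size_px = 64, seed = 1) {
  cohort_config(
    n_per_group = n_per_group, images_per_patient = images_per_patient,
    image_size_px = image_size_px,
    field_params = small_field_params(), seed = seed
  )
}

# feature-level patients (no images) for classifier tests. With
# signal > 0 the first two coordinates encode the class exactly (no
# within-class noise); the remaining coordinates are pure noise. With
# signal = 0 every coordinate is noise (permutation-null fixture).
make_feature_patients <- function(n_per_group = c(3, 3, 3), n_images = 3,
                                  n_features = 8, signal = 5,
                                  seed = 1) {
  set.seed(seed)
  groups <- rep(GROUP_LEVELS, times = n_per_group)
  lapply(seq_along(groups), function(i) {
    g <- match(groups[i], GROUP_LEVELS)
    mk <- function() {
      m <- matrix(rnorm(n_images * n_features), n_images, n_features)
      if (signal > 0) {
        m[, 1] <- signal * g
        m[, 2] <- -signal * g
      }
      colnames(m) <- sprintf("f%02d", seq_len(n_features))
      m
    }
    list(id = sprintf("P%02d", i), group = groups[i],
         blue = mk(), green = mk())
  })
}
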