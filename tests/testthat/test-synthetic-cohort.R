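test_that("cohort simulation is deterministic given the config", {
  cfg <- small_cohort_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(cohort_table(a), cohort_table(b))
  expect_identical(a$patients[[3]]$stack[[1]]$blue$pixels,
                   b$patients[[3]]$stack[[1]]$blue$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("cohort sizes follow the configuration", {
  co <- simulate_cohort(small_cohort_config(n_per_group = c(8, 11, 7),
                                            images_per_patient = 1,
                                            image_size_px = 32))
  expect_length(co$patients, 26)
  tab <- cohort_table(co)
  expect_equal(sum(tab$group != "G0"), 18)
  expect_equal(as.vector(table(factor(tab$group, GROUP_LEVELS))),
               c(8, 11, 7))

  empty <- simulate_cohort(small_cohort_config(n_per_group = c(0, 0, 0)))
  expect_length(empty$patients, 0)
})

test_that("fluid-domain geometry respects the configured range", {
  fp <- small_field_params()
  dia <- unlist(lapply(1:20, function(s) {
    simulate_gp_field("G2", fp, image_size_px = 64, seed = s)$clusters$diameter_nm
  }))
  expect_gt(length(dia), 50)
  expect_true(all(dia >= 500 & dia <= 1000))
  # 2.5 - 5 px at the 200 nm pitch
  expect_true(all(dia / 200 >= 2.5 & dia / 200 <= 5))
})

test_that("cluster counts follow the Poisson law and the no-cluster limit", {
  fp <- small_field_params(expected_clusters_per_cell = c(G0 = 0, G1 = 40,
                                                          G2 = 45))
  counts <- vapply(1:400, function(s) {
    nrow(simulate_gp_field("G1", fp, image_size_px = 64, seed = s)$clusters)
  }, 0)
  se <- sqrt(40 / 400)
  expect_lt(abs(mean(counts) - 40), 3 * se)
  expect_gt(var(counts), 20)  # Poisson dispersion, not a fixed count

  f0 <- simulate_gp_field("G0", fp, image_size_px = 64, seed = 1)
  expect_equal(nrow(f0$clusters), 0)
  expect_lt(abs(f0$true_var_gp - fp$base_gp_sd^2), fp$base_gp_sd^2)
})

test_that("noiseless rendering inverts the GP formula exactly", {
  fp <- small_field_params(g_factor = 1.3)
  f <- simulate_gp_field("G2", fp, image_size_px = 64, seed = 6)
  pair <- render_channels(f, fp, noise = FALSE)
  gp <- compute_gp_map(pair$blue, pair$green, g = fp$g_factor,
                       mask = f$mask)
  expect_lt(max(abs(gp$values[f$mask] - f$gp[f$mask])), 1e-9)

  # symmetric split at GP = 0, g = 1
  flat <- f
  flat$gp[flat$mask] <- 0
  p2 <- render_channels(flat, small_field_params(), noise = FALSE)
  S <- small_field_params()$photon_budget
  expect_equal(unique(p2$blue$pixels[flat$mask]), S / 2)
  expect_equal(unique(p2$green$pixels[flat$mask]), S / 2)
})

test_that("photon noise leaves the per-pixel GP estimator nearly unbiased", {
  fp <- small_field_params(photon_budget = 500, base_gp_sd = 0)
  f <- simulate_gp_field("G0", fp, image_size_px = 48, seed = 7)
  f$gp[f$mask] <- 0.4
  est <- rowMeans(vapply(1:100, function(s) {
    pair <- render_channels(f, fp, seed = s)
    gp <- compute_gp_map(pair$blue, pair$green, mask = f$mask)
    gp$values[f$mask]
  }, numeric(sum(f$mask))))
  expect_lt(abs(mean(est) - 0.4), 0.01)
})

test_that("render_channels rejects non-finite or out-of-range GP", {
  fp <- small_field_params()
  f <- simulate_gp_field("G0", fp, image_size_px = 48, seed = 8)
  f$gp[f$mask][1] <- NaN
  expect_error(render_channels(f, fp), "non-finite")
  f$gp[f$mask] <- 1.5
  expect_error(render_channels(f, fp), "outside")
})

test_that("covariates respect the group invariants", {
  cp <- covariate_params()
  g0 <- simulate_covariates("G0", cp, seed = 1)
  expect_equal(g0$therapy, "none")
  expect_equal(g0$insulin_u_per_kg, 0)
  expect_equal(g0$duration_years, 0)

  for (s in 1:50) {
    g1 <- simulate_covariates("G1", cp, seed = s)
    g2 <- simulate_covariates("G2", cp, seed = s + 100)
    expect_lt(g1$duration_years, 15)
    expect_gte(g2$duration_years, 15)
    expect_true(g1$therapy %in% c("MDI", "CSII"))
    expect_gt(g1$insulin_u_per_kg, 0)
  }
})

test_that("HbA1c emulates matched metabolic control between G1 and G2", {
  cp <- covariate_params()
  set.seed(21)
  sig <- vapply(1:400, function(r) {
    h1 <- vapply(1:11, function(i)
      simulate_covariates("G1", cp)$hba1c_pct, 0)
    h2 <- vapply(1:7, function(i)
      simulate_covariates("G2", cp)$hba1c_pct, 0)
    t.test(h1, h2)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(!sig), 0.9)

  # controls are well separated from diabetics
  set.seed(22)
  h0 <- vapply(1:30, function(i) simulate_covariates("G0", cp)$hba1c_pct, 0)
  h1 <- vapply(1:30, function(i) simulate_covariates("G1", cp)$hba1c_pct, 0)
  expect_lt(t.test(h0, h1)$p.value, 0.001)
})

test_that("lipid means rise with disease stage", {
  cp <- covariate_params()
  set.seed(23)
  c0 <- vapply(1:300, function(i)
    simulate_covariates("G0", cp)$cholesterol_mg_dl, 0)
  c2 <- vapply(1:300, function(i)
    simulate_covariates("G2", cp)$cholesterol_mg_dl, 0)
  expect_gt(mean(c2), mean(c0))
})

test_that("group mean GP falls and heterogeneity grows with stage", {
  fp <- small_field_params()
  stats <- sapply(GROUP_LEVELS, function(g) {
    per_cell <- vapply(1:30, function(s) {
      f <- simulate_gp_field(g, fp, image_size_px = 64,
                             seed = s + 500 * match(g, GROUP_LEVELS))
      c(f$true_mean_gp, f$true_var_gp)
    }, numeric(2))
    rowMeans(per_cell)
  })
  expect_true(all(diff(stats[1, ]) < 0))  # means strictly decreasing
  expect_true(all(diff(stats[2, ]) > 0))  # variances strictly increasing
})

test_that("cohort directories round-trip through disk", {
  cfg <- small_cohort_config(n_per_group = c(1, 1, 1), seed = 9)
  co <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  write_cohort_dir(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort_dir(dir)
  expect_length(back$patients, 3)
  expect_equal(back$patients[[1]]$stack[[1]]$blue$pixels,
               co$patients[[1]]$stack[[1]]$blue$pixels)
  expect_equal(vapply(back$patients, `[[`, "", "group"),
               vapply(co$patients, `[[`, "", "group"))
  expect_equal(back$config$seed, cfg$seed)
  unlink(dir, recursive = TRUE)
})
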