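test_that("PCA retains the minimal component count for the threshold", {
  set.seed(50)
  # rank-1 data in 5-D
  t_ <- rnorm(40)
  X1 <- outer(t_, c(1, -2, 0.5, 3, 1))
  p1 <- fit_pca(X1, 0.99)
  expect_equal(p1$k, 1)

  # isotropic 3-D sample: equal eigenvalues force all components
  X3 <- matrix(rnorm(3000), 1000, 3)
  p3 <- fit_pca(X3, 0.99)
  expect_equal(p3$k, 3)

  # minimality contract on a graded spectrum
  X <- cbind(rnorm(200, sd = 10), rnorm(200, sd = 3), rnorm(200, sd = 1),
             rnorm(200, sd = 0.3))
  for (thr in c(0.8, 0.9, 0.99)) {
    p <- fit_pca(X, thr)
    cum <- cumsum(p$explained_variance_ratio)
    expect_gte(cum[p$k], thr)
    if (p$k > 1) expect_lt(cum[p$k - 1], thr)
  }
  expect_error(fit_pca(X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("PCA loadings are orthonormal and reconstruction error matches
           the discarded eigenvalues", {
  set.seed(51)
  X <- matrix(rnorm(600), 100, 6) %*% diag(c(5, 3, 2, 1, 0.5, 0.1))
  p <- fit_pca(X, 0.9)
  expect_equal(crossprod(p$loadings), diag(p$k), tolerance = 1e-10,
               ignore_attr = TRUE)
  scores <- pca_project(p, X)
  recon <- sweep(scores %*% t(p$loadings), 2, p$center, "+")
  resid_ss <- sum((X - recon)^2) / (nrow(X) - 1)
  discarded <- sum(p$sdev[-seq_len(p$k)]^2)
  expect_equal(resid_ss, discarded, tolerance = 1e-8)
})

test_that("channel pipelines separate separable data and are deterministic", {
  set.seed(52)
  X <- rbind(matrix(rnorm(100, 0), 20), matrix(rnorm(100, 6), 20))
  y <- rep(c("G0", "G2"), each = 20)
  pipe <- fit_channel_pipeline(X, y)
  expect_equal(mean(predict(pipe, X) == y), 1)

  pipe2 <- fit_channel_pipeline(X, y)
  probe <- matrix(rnorm(50, 3), 10)
  expect_identical(predict(pipe, probe), predict(pipe2, probe))

  expect_error(fit_channel_pipeline(X, rep("G1", 40)), "single class")
  expect_error(fit_channel_pipeline(X, rep("bad", 40)), "outside")
})

test_that("weighted voting follows the arithmetic and its tie rules", {
  wv <- rbcfluidity:::weighted_vote
  expect_equal(wv("G2", "G2", c(0.5, 0.5)), "G2")          # unanimity
  expect_equal(wv("G1", "G2", c(0.7, 0.3)), "G1")          # heavier blue
  expect_equal(wv("G1", "G2", c(0.3, 0.7)), "G2")
  expect_equal(wv("G0", "G2", c(0.5, 0.5)), "G0")          # tie -> heavier=blue
  expect_equal(wv("G2", "G0", c(0.4, 0.4)), "G2")          # tie, equal -> blue
  expect_error(wv("G0", "G1", c(0, 0)))
})

test_that("patient classification honors degenerate channel weights", {
  pats <- make_feature_patients(c(3, 3, 3), n_images = 3, signal = 6)
  dss <- fit_dss(pats)
  # force all weight on the blue channel: output = blue majority
  dss_blue <- dss
  dss_blue$channel_weights <- c(blue = 1, green = 0)
  for (p in pats) {
    lab_b <- rbcfluidity:::majority_label(
      predict(dss$blue_pipeline, p$blue))
    expect_equal(classify_patient(dss_blue, p), lab_b)
  }
  expect_error(classify_patient(dss, list(blue = NULL)), "empty")
})

test_that("LOPO runs one fold per patient and never leaks the held-out
           patient into training", {
  pats <- make_feature_patients(c(3, 3, 3), n_images = 3, signal = 6)
  ids <- vapply(pats, `[[`, "", "id")
  seen <- list()
  rep <- lopo_evaluate(pats, fold_callback = function(holdout, train_ids) {
    seen[[holdout]] <<- train_ids
  })
  expect_length(seen, 9)                      # n folds
  for (h in names(seen)) {
    expect_false(h %in% seen[[h]])            # isolation
    expect_setequal(seen[[h]], setdiff(ids, h))
    expect_length(seen[[h]], 8)               # test set of size 1
  }
  expect_equal(sum(rep$confusion), 9)
  # perfectly informative features give a perfect LOPO score
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$f1), c(1, 1, 1))
})

test_that("class-independent features score near chance under LOPO", {
  accs <- vapply(1:8, function(s) {
    pats <- make_feature_patients(c(4, 4, 4), n_images = 2, signal = 0,
                                  seed = 100 + s)
    lopo_evaluate(pats)$accuracy
  }, 0)
  se <- sqrt(1 / 3 * 2 / 3 / (8 * 12))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se)
})

test_that("the scalar Bayes classifier matches the posterior rule", {
  v <- c(rnorm(10, 0, 1), rnorm(10, 10, 1), rnorm(10, 20, 1))
  y <- rep(GROUP_LEVELS, each = 10)
  set.seed(53)
  model <- fit_bayes_scalar(v, y)
  expect_equal(predict(model, 10), "G1")

  # equidistant point between two equal-prior unit Gaussians -> lower class
  model2 <- fit_bayes_scalar(c(-1, 0, 1, 1, 2, 3), rep(c("G0", "G1"), each = 3))
  m0 <- model2$stats$G0; m1 <- model2$stats$G1
  x_tie <- (m0$mean + m1$mean) / 2   # equal sds by construction
  expect_equal(m0$sd, m1$sd)
  expect_equal(predict(model2, x_tie), "G0")

  # brute-force posterior oracle on a grid
  set.seed(54)
  v3 <- c(rnorm(8, 2, 1.5), rnorm(12, 5, 2), rnorm(6, 9, 1))
  y3 <- rep(GROUP_LEVELS, times = c(8, 12, 6))
  m3 <- fit_bayes_scalar(v3, y3)
  grid <- seq(-2, 14, length.out = 200)
  oracle <- vapply(grid, function(x) {
    post <- vapply(GROUP_LEVELS, function(g) {
      vv <- v3[y3 == g]
      length(vv) / length(v3) *
        exp(-(x - mean(vv))^2 / (2 * var(vv))) / sqrt(2 * pi * var(vv))
    }, 0)
    GROUP_LEVELS[which.max(post)]
  }, "")
  expect_identical(predict(m3, grid), oracle)
})

test_that("LOPO Bayes baseline separates well-separated biomarkers", {
  set.seed(55)
  v <- c(rnorm(8, 0, 0.5), rnorm(11, 10, 0.5), rnorm(7, 20, 0.5))
  y <- rep(GROUP_LEVELS, times = c(8, 11, 7))
  rep <- lopo_bayes_scalar(v, y)
  expect_equal(rep$accuracy, 1)
  expect_equal(nrow(rep$predictions), 26)
})

test_that("metric formulas follow the 3-class confusion-matrix definitions", {
  perfect <- compute_metrics(diag(c(8, 11, 7)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$precision), c(1, 1, 1))
  expect_equal(unname(perfect$recall), c(1, 1, 1))
  expect_equal(unname(perfect$f1), c(1, 1, 1))

  m <- rbind(c(7, 1, 0), c(1, 9, 1), c(0, 1, 6))
  r <- compute_metrics(m)
  expect_equal(r$accuracy, 22 / 26)
  expect_equal(unname(r$precision), c(7 / 8, 9 / 11, 6 / 7))
  expect_equal(unname(r$recall), c(7 / 8, 9 / 11, 6 / 7))

  # accuracy is a trace formula: transpose-invariant
  set.seed(56)
  for (i in 1:5) {
    mm <- matrix(rpois(9, 5), 3)
    expect_equal(compute_metrics(mm)$accuracy,
                 compute_metrics(t(mm))$accuracy)
  }

  # zero-denominator ratios are flagged, not NaN
  z <- rbind(c(0, 0, 0), c(5, 3, 0), c(0, 2, 6))
  rz <- compute_metrics(z)
  expect_equal(rz$precision[["G0"]], 0)
  expect_true(rz$undefined["precision", "G0"])
  expect_error(compute_metrics(matrix(0, 3, 3)), "empty")
})
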