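test_that("activation capture is deterministic, rectified, and normalized at the softmax", {
  m <- small_cnn(4, canvas = 32, channels = c(4, 8), fc_units = 16, seed = 2)
  img <- make_gaussian_noise(32, 32, seed = 1)
  a <- capture_activations(m, img)
  b <- capture_activations(m, img)
  expect_identical(unclass(a), unclass(b))
  expect_named(a, c("conv1", "conv2", "fc1", "softmax"))
  for (nm in c("conv1", "conv2", "fc1")) expect_true(all(a[[nm]] >= 0))
  expect_equal(sum(a$softmax), 1, tolerance = 1e-6)

  # flat input at the model mean: conv responses reduce to rectified biases
  flat <- gray_image(matrix(m$input_mean, 32, 32))
  f1 <- capture_activations(m, flat)
  expect_equal(f1$conv1, rep(pmax(m$layers[[1]]$b, 0), each = 32 * 32),
               tolerance = 1e-12)

  expect_error(capture_activations(m, make_gaussian_noise(16, 16, seed = 1)),
               "canvas")
})

test_that("an identity layer's correlation threshold matches the closed form", {
  # matched-variance unclipped blends: r(w) = w / sqrt(w^2 + (1-w)^2),
  # crossing 0.5 at 1/(1+sqrt(3))
  idf <- function(img) list(pixels = as.vector(unclass(img)))
  sigs <- lapply(1:20, function(i) make_gaussian_noise(64, 64,
                                                       seed = 300 + i))
  prof <- corr_susceptibility(idf, sigs, "gaussian",
                              levels = seq(0, 1, by = 0.05), n_noise = 1,
                              seed = 6, clip = FALSE)
  expect_true(prof$valid)
  expect_lt(abs(prof$threshold - 1 / (1 + sqrt(3))), 0.01)

  # r at level 1 is exactly 1, and thresholds are invariant to positive
  # affine rescaling of the features (Pearson invariance)
  curves <- attr(prof, "curves")
  expect_equal(unname(curves[nrow(curves), "pixels"]), 1)
  aff <- function(img) list(pixels = as.vector(unclass(img)),
                            scaled = 2 * as.vector(unclass(img)) + 3)
  p2 <- corr_susceptibility(aff, sigs[1:8], "gaussian",
                            levels = seq(0, 1, by = 0.1), n_noise = 1,
                            seed = 7, clip = FALSE)
  expect_equal(p2$threshold[1], p2$threshold[2], tolerance = 1e-10)
})

test_that("the rescale rule maps a positive-floor correlation curve onto [0, 1]", {
  # features with a strong shared component keep r(0) well above 0
  common <- as.vector(unclass(make_gaussian_noise(64, 64, seed = 999)))
  f <- function(img) list(off = as.vector(unclass(img)) + 0.75 * common)
  sigs <- lapply(1:10, function(i) make_gaussian_noise(64, 64,
                                                       seed = 500 + i))
  lv <- seq(0, 1, by = 0.1)
  pr <- corr_susceptibility(f, sigs, "gaussian", levels = lv, n_noise = 1,
                            seed = 8, clip = FALSE, rescale = TRUE)
  pn <- corr_susceptibility(f, sigs, "gaussian", levels = lv, n_noise = 1,
                            seed = 8, clip = FALSE, rescale = FALSE)
  raw <- attr(pn, "curves")[, "off"]
  expect_gt(raw[1], 0.2)             # the floor the rule is meant to remove
  # thresholding the rescaled curve is not the same as the raw curve
  expect_gt(pr$threshold, pn$threshold)
  # and reproduces a by-hand rescale of the same curve
  y <- (raw - min(raw)) / (max(raw) - min(raw))
  by_hand <- threshold_at(fit_logistic4(psychometric_curve(lv, y)), 0.5)
  expect_equal(pr$threshold, by_hand$threshold, tolerance = 1e-6)
})

test_that("classification-based susceptibility hits chance at SSNR 0 and improves with depth", {
  mods <- fixture_models()
  ds <- fixture_dataset()
  tr <- dataset_split(ds, "train"); te <- dataset_split(ds, "test")
  sub <- seq(1, 200, by = 2)
  prof <- clf_susceptibility(mods$clean, tr$images[sub], tr$labels[sub],
                             te$images, te$labels, "gaussian",
                             levels = seq(0, 1, by = 0.125), n_noise = 1,
                             seed = 7)
  curves <- attr(prof, "curves")
  expect_lt(abs(mean(curves[1, -1]) - 0.25), 0.15)   # near 1/K at SSNR 0
  clean_acc <- attr(prof, "clean_accuracy")
  expect_true(all(clean_acc > 0.5))
  # clean readout accuracy improves across the convolutional hierarchy, and
  # is non-decreasing overall up to 0.05 plus one test image of granularity
  # (the low-dimensional fc/softmax stages can dip slightly at this scale)
  expect_gt(clean_acc[["conv4"]], clean_acc[["conv1"]])
  tol <- 0.05 + 1 / length(te$images)
  expect_true(all(diff(clean_acc) >= -tol - 1e-9))
  expect_error(clf_susceptibility(mods$clean, tr$images[1:3], rep(1, 3),
                                  te$images[1:2], te$labels[1:2]),
               "2 categories")
})

test_that("threshold-by-layer slopes are exact on lines and flag degenerate profiles", {
  p <- structure(data.frame(layer = c("a", "b", "c"), index = 1:3,
                            threshold = c(0.3, 0.4, 0.5), valid = TRUE,
                            kind = "correlation", noise_type = "gaussian"),
                 class = c("layer_threshold_profile", "data.frame"))
  s <- threshold_slope(p)
  expect_equal(s$slope, 0.1, tolerance = 1e-12)

  p$threshold <- rep(0.4, 3)
  s0 <- threshold_slope(p)
  expect_equal(s0$slope, 0)
  expect_equal(s0$p, 1)
  expect_true(s0$zero_variance)

  p2 <- p[1:2, ]
  expect_error(threshold_slope(p2), "3 valid layers")
})

test_that("weight CCA is 1 for self and unit-mixed copies and low for independent weights", {
  mods <- fixture_models()
  self <- weight_cca(mods$clean, mods$clean, "conv2")
  expect_equal(self$mean, 1, tolerance = 1e-5)
  expect_true(all(abs(self$correlations - 1) < 1e-5))

  # invariance to orthogonal mixing (plus permutation) of the unit axis
  X <- t(layer_weights(mods$clean, "conv2"))   # coords x units
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(ncol(X)^2), ncol(X))))
  P <- diag(ncol(X))[sample(ncol(X)), ]
  mixed <- visnoise:::cca_regularized(X, X %*% Q %*% P, ridge = 1e-9)
  expect_equal(mixed$mean, 1, tolerance = 1e-6)

  # independent random weights: mean canonical correlation well below the
  # self case (null-distribution check, coords >> units)
  set.seed(2)
  A <- matrix(rnorm(500 * 10), 500, 10); B <- matrix(rnorm(500 * 10), 500, 10)
  null <- visnoise:::cca_regularized(A, B)
  expect_lt(null$mean, 0.3)
  expect_lt(null$mean, self$mean)

  # agreement with the classical implementation on well-conditioned input
  set.seed(3)
  Xa <- matrix(rnorm(100 * 5), 100, 5); Yb <- matrix(rnorm(100 * 5), 100, 5)
  expect_equal(visnoise:::cca_regularized(Xa, Yb, ridge = 0)$correlations,
               stats::cancor(Xa, Yb)$cor, tolerance = 1e-8)

  expect_error(weight_cca(mods$clean, mods$clean, "nope"), "no layer")
})
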