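logistic4 <- function(w, L, U, m, k) L + (U - L) / (1 + exp(-k * (w - m)))

test_that("the 4-parameter logistic fit recovers exact and noisy curves", {
  lv <- seq(0.05, 0.95, by = 0.1)
  y <- logistic4(lv, 0.0625, 1, 0.3, 20)
  fit <- fit_logistic4(psychometric_curve(lv, y), floor_max = 0.3)
  expect_true(fit$converged)
  expect_lt(abs(fit$lower - 0.0625), 0.01)
  expect_lt(abs(fit$upper - 1), 0.01)
  expect_lt(abs(fit$midpoint - 0.3), 0.003)
  expect_lt(abs(fit$slope - 20) / 20, 0.01)

  # binomial sampling noise, n = 50 per level: median |error| of the 50%
  # threshold over 100 simulations stays within 0.03
  set.seed(31)
  true_thr <- threshold_at(
    list(lower = 0.0625, upper = 1, midpoint = 0.3, slope = 20,
         converged = TRUE), 0.5)$threshold
  errs <- replicate(100, {
    p <- logistic4(lv, 0.0625, 1, 0.3, 20)
    acc <- rbinom(length(lv), 50, p) / 50
    f <- fit_logistic4(psychometric_curve(lv, acc), floor_max = 0.3)
    th <- threshold_at(f, 0.5)
    if (th$valid) th$threshold - true_thr else NA_real_
  })
  expect_lt(median(abs(errs), na.rm = TRUE), 0.03)

  # degenerate inputs
  flat <- fit_logistic4(psychometric_curve(lv, rep(0.0625, length(lv))))
  expect_false(flat$converged)
  expect_error(fit_logistic4(psychometric_curve(c(0.1, 0.5, 0.9),
                                                c(0, 0.5, 1))),
               "4 distinct levels")
})

test_that("threshold inversion is analytic, criterion-aware, and matches bisection", {
  fit <- list(lower = 0, upper = 1, midpoint = 0.3, slope = 17,
              converged = TRUE)
  expect_equal(threshold_at(fit, 0.5)$threshold, 0.3)   # midpoint symmetry

  expect_false(threshold_at(fit, 1.1)$valid)            # unreachable

  f2 <- list(lower = 0.0625, upper = 1, midpoint = 0.3, slope = 20,
             converged = TRUE)
  th <- threshold_at(f2, 0.9)
  # bisection oracle on the forward curve
  g <- function(w) logistic4(w, 0.0625, 1, 0.3, 20) - 0.9
  lo <- 0; hi <- 1
  for (i in 1:60) { mid <- (lo + hi) / 2; if (g(mid) < 0) lo <- mid else hi <- mid }
  expect_lt(abs(th$threshold - (lo + hi) / 2), 1e-9)

  # shifting a curve rightward by delta shifts the threshold by delta
  lv <- seq(0, 1, by = 0.05)
  for (delta in c(0.05, 0.12)) {
    fa <- fit_logistic4(psychometric_curve(lv, logistic4(lv, 0, 1, 0.3, 15)))
    fb <- fit_logistic4(psychometric_curve(lv, logistic4(lv, 0, 1,
                                                         0.3 + delta, 15)))
    expect_lt(abs(threshold_at(fb, 0.5)$threshold -
                    threshold_at(fa, 0.5)$threshold - delta), 1e-4)
  }
})

test_that("confusion matrices are row-stochastic and match hand tallies", {
  tr <- data.frame(true_category = c(1, 1, 1, 2, 2, 3),
                   response = c(1, 1, 2, 2, 3, 3))
  m <- confusion_matrix(tr, K = 4)
  expect_equal(m[1, ], c(2 / 3, 1 / 3, 0, 0), ignore_attr = TRUE)
  expect_equal(m[2, ], c(0, 1 / 2, 1 / 2, 0), ignore_attr = TRUE)
  expect_equal(m[3, ], c(0, 0, 1, 0), ignore_attr = TRUE)
  expect_true(all(is.na(m[4, ])))
  expect_equal(attr(m, "empty_rows"), c(`4` = 4L))

  all_correct <- data.frame(true_category = rep(1:3, 5),
                            response = rep(1:3, 5))
  expect_equal(unname(unclass(confusion_matrix(all_correct, 3))), diag(3),
               ignore_attr = TRUE)

  set.seed(40)
  unif <- data.frame(true_category = sample(1:4, 8000, TRUE),
                     response = sample(1:4, 8000, TRUE))
  expect_lt(max(abs(confusion_matrix(unif, 4) - 0.25)), 0.05)
})

test_that("split-half reliability matches the Spearman-Brown prediction", {
  # thresholds = shared per-image signal + iid observer noise of known ratio
  set.seed(17)
  n_obs <- 20; n_img <- 1500
  sd_sig <- 0.06; sd_noise <- 0.06
  signal <- rnorm(n_img, 0.3, sd_sig)
  thr <- t(replicate(n_obs, signal + rnorm(n_img, 0, sd_noise)))
  sh <- split_half_reliability(thr, n_splits = 300, seed = 5)
  k <- n_obs / 2
  pred <- sd_sig^2 / (sd_sig^2 + sd_noise^2 / k)   # corr of two half-means
  expect_lt(abs(sh$mean_r - pred), 0.02)

  # identical observers agree perfectly on every split
  same <- thr[rep(1, 6), ]
  expect_equal(split_half_reliability(same, n_splits = 20, seed = 1)$mean_r,
               1, tolerance = 1e-12)

  # two observers: each split is one vs one
  two <- thr[1:2, ]
  sh2 <- split_half_reliability(two, n_splits = 50, seed = 2)
  expect_equal(sh2$sd_r, 0, tolerance = 1e-12)
  expect_error(split_half_reliability(thr[1, , drop = FALSE]),
               "2 observers")
})

test_that("the Fisher z test reproduces its closed form, symmetry, and type-I rate", {
  expect_equal(compare_correlations_fisher(0.4, 50, 0.4, 80)$z, 0)
  expect_equal(compare_correlations_fisher(0.4, 50, 0.4, 80)$p, 1)

  a <- compare_correlations_fisher(0.53, 716, 0.24, 723)
  b <- compare_correlations_fisher(0.24, 723, 0.53, 716)
  expect_equal(a$z, -b$z)

  expect_error(compare_correlations_fisher(1, 10, 0.5, 10), "\\|r\\| < 1")
  expect_error(compare_correlations_fisher(0.5, 3, 0.5, 10), "exceed 3")

  # under the null, rejection at alpha = 0.05 stays near 0.05
  set.seed(23)
  n <- 100
  rej <- replicate(4000, {
    z <- matrix(rnorm(2 * n), n, 2); x <- z[, 1]
    y1 <- 0.3 * x + sqrt(1 - 0.09) * z[, 2]
    z2 <- matrix(rnorm(2 * n), n, 2)
    y2 <- 0.3 * z2[, 1] + sqrt(1 - 0.09) * z2[, 2]
    compare_correlations_fisher(cor(x, y1), n, cor(z2[, 1], y2), n)$p < 0.05
  })
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})

test_that("per-image thresholds recover engineered orderings and apply both exclusion rules", {
  # template-matching observer: identifies the best-matching reference image
  # and answers correctly only once its pattern correlation exceeds a
  # per-image criterion, so the per-image SSNR thresholds are ordered by
  # that criterion.  One image is made unrecognizable at every level.
  set.seed(44)
  K <- 4L; n_img <- 12; canvas <- 24
  refs <- lapply(seq_len(n_img), function(i)
    gray_image(matrix(runif(canvas^2, 0, 255), canvas)))
  labels <- rep(seq_len(K), length.out = n_img)
  crit <- seq(0.25, 0.8, length.out = n_img)
  crit[5] <- Inf   # never correct: must be excluded as unreachable
  classify <- function(img) {
    v <- as.vector(unclass(img))
    cors <- vapply(refs, function(r) cor(v, as.vector(unclass(r))), 0)
    j <- which.max(cors)
    if (cors[j] >= crit[j]) labels[j] else (labels[j] %% K) + 1L
  }
  res <- per_image_thresholds(classify, refs, labels,
                              levels = seq(0.1, 1, by = 0.1), n_noise = 8,
                              criterion = 0.9, n_bias_probe = 30, seed = 2,
                              canvas = canvas, n_classes = K)
  tab <- res$thresholds
  expect_true("unreachable" %in% tab$reason[5] ||
                tab$reason[5] == "bias")      # image 5 never passes
  # bias rule: every image of the modal pure-noise category is excluded
  expect_true(all(tab$excluded[tab$label == res$noise_modal_category]))
  expect_true(all(tab$reason[tab$label == res$noise_modal_category] ==
                    "bias"))
  # engineered ordering is recovered on the valid images
  ok <- tab$valid
  expect_gte(sum(ok), 6)
  expect_gt(cor(crit[ok], tab$threshold[ok], method = "spearman"), 0.9)
})

test_that("threshold regression uses human thresholds as predictor and drops incomplete pairs", {
  h <- c(0.2, 0.25, 0.3, 0.35, 0.4, NA)
  m <- 0.5 * h + 0.1
  m[2] <- NA
  fit <- threshold_regression(h, m)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_equal(fit$n, 4)
  expect_error(threshold_regression(c(1, 2), c(1, 2)), "at least 3")
})
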