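test_that("amplitude extraction averages TRs 3-5 of percent signal change", {
  # constructed pulse: baseline 100, +2% over TRs 3-5 post-onset
  series <- matrix(100, 30, 3)
  series[10:12, ] <- 102
  bold <- list(list(series = series,
                    events = data.frame(onset = 8, stimulus = 1,
                                        condition = "clean")))
  out <- amplitudes_from_timeseries(bold, normalize = FALSE)
  # the run mean includes the pulse: mu = (27*100 + 3*102)/30, and percent
  # signal change is measured against that baseline
  mu <- (27 * 100 + 3 * 102) / 30
  expect_equal(as.vector(out$responses), rep(100 * (102 - mu) / mu, 3),
               tolerance = 1e-9)

  # constant series: all amplitudes 0 and zero variance flagged
  cst <- list(list(series = matrix(100, 20, 2),
                   events = data.frame(onset = c(3, 10), stimulus = 1:2,
                                       condition = "clean")))
  outc <- amplitudes_from_timeseries(cst, normalize = TRUE)
  expect_true(all(outc$responses == 0))
  expect_equal(attr(outc, "zero_variance_runs"), 1L)

  # an onset too close to the run end is dropped and logged
  late <- list(list(series = matrix(100, 10, 2),
                    events = data.frame(onset = c(2, 8), stimulus = 1:2,
                                        condition = "clean")))
  outl <- amplitudes_from_timeseries(late, normalize = FALSE)
  expect_equal(nrow(outl$responses), 1L)
  expect_length(attr(outl, "dropped"), 1L)
})

test_that("the synthetic time-series path reproduces the direct amplitude path", {
  set.seed(1)
  f <- matrix(rnorm(8 * 30), 8, 30)
  vp <- simulate_voxel_patterns(f, n_voxels = 20, n_runs = 3, snr = 2,
                                seed = 6, timeseries = TRUE,
                                tr_noise_sd = 0.05)
  rec <- amplitudes_from_timeseries(vp$bold, normalize = TRUE)
  dn <- normalize_patterns(vp)
  expect_gt(cor(as.vector(rec$responses), as.vector(dn$responses)), 0.99)
  # percent signal change against the run mean leaves a per-voxel offset
  # (event responses enter the baseline); compare after removing it
  center_by_voxel_run <- function(p) {
    for (r in unique(p$run)) {
      rows <- p$run == r
      p$responses[rows, ] <- scale(p$responses[rows, , drop = FALSE],
                                   scale = FALSE)
    }
    p$responses
  }
  # after removing the offset, a second-order scale distortion of order
  # amplitude * offset / baseline remains
  expect_lt(max(abs(center_by_voxel_run(rec) - center_by_voxel_run(dn))),
            0.15)
})

test_that("leave-one-run-out decoding partitions by run and separates separable patterns", {
  set.seed(2)
  f <- matrix(rnorm(6 * 20), 6, 20)
  vp <- simulate_voxel_patterns(f, n_voxels = 50, n_runs = 10, snr = 8,
                                seed = 3)
  res <- decode_category(normalize_patterns(vp))
  expect_equal(res$n_folds, 10L)          # each run held out exactly once
  expect_length(res$fold_accuracy, 10L)
  expect_equal(res$accuracy, 1)           # perfectly separable at high snr

  # a training fold missing a category is skipped with a warning
  vp2 <- simulate_voxel_patterns(f, n_voxels = 10, n_runs = 3, snr = 1,
                                 seed = 4)
  vp2$condition[vp2$run != 1 & vp2$stimulus == 1] <- "other"
  expect_warning(decode_category(vp2, categories = 1:6), "misses a category")
})

test_that("subject inclusion uses the mean-over-conditions 20% rule with boundary inclusion", {
  expect_true(qc_subject(c(0.30, 0.25, 0.20)))
  expect_false(qc_subject(c(0.15, 0.15, 0.15)))
  expect_true(qc_subject(c(0.50, 0.05, 0.05)))   # mean exactly 0.20
  expect_error(qc_subject(c(0.3, 0.2)), "3 condition")
})

test_that("representational similarity matrices match hand-computed correlations", {
  p <- matrix(c(1, 2, 3,
                2, 4, 6.5,
                3, -1, 0), 3, byrow = TRUE)
  r <- build_rdm(p)
  expect_equal(unclass(r), cor(t(p)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(unclass(r)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)

  dup <- build_rdm(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(dup[1, 2], 1)
  orth <- build_rdm(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
  expect_equal(orth[1, 2], 0, tolerance = 1e-12)
  flagged <- build_rdm(rbind(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(attr(flagged, "zero_variance"), 1L)

  # invariance to per-stimulus affine transformation of the patterns
  p2 <- p * c(2, 0.5, 3) + c(10, -4, 1)
  expect_equal(unclass(build_rdm(p2)), unclass(build_rdm(p)),
               tolerance = 1e-12)
})

test_that("RSA comparison is exact for self, null for permuted stimuli, and recovers generators", {
  set.seed(5)
  pats <- matrix(rnorm(12 * 30), 12, 30)
  rdm <- build_rdm(pats)
  expect_equal(rsa_compare(rdm, rdm)$r, 1)

  perm_r <- replicate(200, {
    p <- sample(nrow(rdm))
    rsa_compare(rdm, unclass(rdm)[p, p])$r
  })
  expect_lt(abs(mean(perm_r)), 0.05)

  # machinery-level generating-"layer" recovery on independent feature sets
  layers <- lapply(1:4, function(i) matrix(rnorm(12 * 40), 12, 40))
  names(layers) <- paste0("L", 1:4)
  vp <- simulate_voxel_patterns(layers$L3, n_voxels = 150, n_runs = 4,
                                snr = 5, seed = 6)
  prof <- rsa_layer_profile(vp, layers)
  expect_equal(prof$layer[which.max(prof$r)], "L3")

  expect_error(rsa_compare(rdm, build_rdm(pats[1:5, ])), "sizes differ")
})

test_that("group layer statistics flag degenerate input and detect real effects", {
  zeroes <- matrix(0, 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  g0 <- group_layer_profile(zeroes)
  expect_true(all(g0$zero_variance))
  expect_equal(g0$t, rep(0, 3))

  # true mean z = 0.5, SD 0.1, n = 8: essentially always significant at 0.01
  set.seed(7)
  hits <- replicate(200, {
    r <- tanh(matrix(rnorm(8, 0.5, 0.1), 8, 1))
    group_layer_profile(r, alpha = 0.01)$significant
  })
  expect_gt(mean(hits), 0.95)

  # paired comparison of statistically identical models: false-positive rate
  # stays near alpha
  set.seed(8)
  fp <- replicate(2000, {
    a <- tanh(matrix(rnorm(8, 0.3, 0.1), 8, 1))
    b <- tanh(matrix(rnorm(8, 0.3, 0.1), 8, 1))
    group_layer_profile(a, alpha = 0.05, paired_with = b)$significant
  })
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.08)

  expect_error(group_layer_profile(zeroes[1, , drop = FALSE]),
               ">= 2 subjects")
})
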