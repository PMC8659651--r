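# Synthetic inputs with known ground truth: procedural object images,
# simulated observers for the fixed-SSNR and ascending-SSNR designs, and
# run-structured voxel patterns that are noisy linear readouts of model
# features.  Every generator is a pure function of its seed and parameters.

shape_families <- c("blob", "bar", "ring", "cross",
                    "triangle", "diamond", "grating", "ell")

# mask of one shape instance on a canvas x canvas grid
shape_mask <- function(family, canvas, cx, cy, size, angle) {
  xs <- matrix(rep(seq_len(canvas), each = canvas), canvas) - cx
  ys <- matrix(rep(seq_len(canvas), times = canvas), canvas) - cy
  xr <- cos(angle) * xs + sin(angle) * ys
  yr <- -sin(angle) * xs + cos(angle) * ys
  s <- size
  switch(family,
    blob     = (xr / s)^2 + (yr / (0.65 * s))^2 <= 1,
    bar      = abs(xr) <= s & abs(yr) <= 0.25 * s,
    ring     = { r <- sqrt(xr^2 + yr^2); r <= s & r >= 0.55 * s },
    cross    = (abs(xr) <= 0.28 * s & abs(yr) <= s) |
               (abs(yr) <= 0.28 * s & abs(xr) <= s),
    triangle = yr >= -0.6 * s & yr <= 0.6 * s &
               abs(xr) <= 0.75 * (0.6 * s - yr) / 1.2,
    diamond  = abs(xr) + abs(yr) <= s,
    grating  = abs(xr) <= s & abs(yr) <= s &
               (floor((yr + s) / (0.5 * s)) %% 2 == 0),
    ell      = (xr >= -s & xr <= -0.4 * s & abs(yr) <= s) |
               (yr >= -s & yr <= -0.4 * s & abs(xr) <= s),
    stop("unknown shape family: ", family, call. = FALSE)
  )
}

#' Generate a procedural object-image dataset
#'
#' Draws `K` visually distinct parametric shape families (blobs, bars,
#' rings, crosses, ...) with jittered position, size, orientation and
#' intensity, plus pixel texture noise, on a square canvas.  Stands in for
#' natural object photographs: categories are linearly separable from raw
#' pixels, each image has a known shape mask usable as ground truth for
#' diagnostic-region analyses.
#'
#' @param K number of categories (2--8).
#' @param n_train,n_test images per category in each split.
#' @param canvas side length in pixels.
#' @param seed integer seed; the full dataset is deterministic given the seed.
#' @param jitter relative positional jitter (fraction of canvas).
#' @return An `image_dataset`: list with `images` (list of [gray_image()]),
#'   `labels` (integer 1..K), `split` ("train"/"test"), `masks` (logical
#'   shape masks), `category_names`, and `params`.
#' @export
generate_image_dataset <- function(K, n_train, n_test, canvas = 64L,
                                   seed = 1L, jitter = 0.08) {
  if (K < 2L || K > length(shape_families))
    stop("`K` must be between 2 and ", length(shape_families), call. = FALSE)
  if (n_train < 1L || n_test < 1L) stop("counts must be >= 1", call. = FALSE)
  if (canvas < 32L) stop("`canvas` too small for the shape families",
                         call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  fams <- shape_families[seq_len(K)]
  n_per <- n_train + n_test
  images <- vector("list", K * n_per)
  masks <- vector("list", K * n_per)
  labels <- integer(K * n_per)
  split <- character(K * n_per)
  i <- 0L
  for (k in seq_len(K)) {
    for (j in seq_len(n_per)) {
      i <- i + 1L
      cx <- canvas / 2 + stats::rnorm(1, 0, jitter * canvas)
      cy <- canvas / 2 + stats::rnorm(1, 0, jitter * canvas)
      size <- canvas * stats::runif(1, 0.22, 0.3)
      ang <- stats::runif(1, -pi / 6, pi / 6)
      fg <- stats::runif(1, 180, 220)
      bg <- stats::runif(1, 35, 55)
      msk <- shape_mask(fams[k], canvas, cx, cy, size, ang)
      m <- matrix(bg, canvas, canvas)
      m[msk] <- fg
      m <- m + matrix(stats::rnorm(canvas^2, 0, 8), canvas, canvas)
      m[m < 0] <- 0; m[m > 255] <- 255
      images[[i]] <- gray_image(m, meta = list(family = fams[k]))
      masks[[i]] <- msk
      labels[i] <- k
      split[i] <- if (j <= n_train) "train" else "test"
    }
  }
  structure(list(images = images, labels = labels, split = split,
                 masks = masks, category_names = fams,
                 params = list(K = K, n_train = n_train, n_test = n_test,
                               canvas = as.integer(canvas), seed = seed,
                               jitter = jitter)),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset: %d categories, %d train + %d test, canvas %d>\n",
              x$params$K, sum(x$split == "train"), sum(x$split == "test"),
              x$params$canvas))
  invisible(x)
}

#' Subset an image dataset by split
#' @param dataset an `image_dataset`.
#' @param split `"train"` or `"test"`.
#' @return List with `images`, `labels`, `masks`, `index` (positions in the
#'   full dataset).
#' @export
dataset_split <- function(dataset, split = c("train", "test")) {
  split <- match.arg(split)
  i <- which(dataset$split == split)
  list(images = dataset$images[i], labels = dataset$labels[i],
       masks = dataset$masks[i], index = i)
}

#' Ground-truth diagnostic map of an image
#'
#' The shape mask eroded to its core and smoothed with a disc kernel of
#' 15 pixels diameter (emulating the thick pen with which observers paint
#' informative regions), rescaled to \[0, 1\].
#'
#' @param dataset an `image_dataset`.
#' @param i image index in the full dataset.
#' @param pen_diameter smoothing disc diameter in pixels.
#' @return Numeric matrix in \[0, 1\].
#' @export
diagnostic_map <- function(dataset, i, pen_diameter = 15) {
  msk <- dataset$masks[[i]] * 1.0
  er <- EBImage::erode(msk, EBImage::makeBrush(5L, shape = "disc"))
  if (sum(er) == 0) er <- msk
  br <- EBImage::makeBrush(as.integer(pen_diameter), shape = "disc")
  br <- br / sum(br)
  sm <- as.matrix(EBImage::filter2(er, br, boundary = "replicate"))
  rng <- range(sm)
  if (diff(rng) == 0) return(sm * 0)
  (sm - rng[1]) / diff(rng)
}

#' Simulated observer specification
#'
#' Fixes, per image of a dataset, a true SSNR threshold, plus the shared
#' psychometric slope, lapse rate, guess rate 1/K, a category confusability
#' matrix, and the decision noise of the ascending (stop-when-confident)
#' design.  The probability of a correct response at SSNR `w` for an image
#' with threshold `t` follows the 4-parameter logistic
#' `1/K + (1 - lapse - 1/K) / (1 + exp(-slope (w - t)))`.
#'
#' The default confusability has block structure: errors fall preferentially
#' within one of two superordinate clusters of categories (first vs second
#' half), emulating the greater mutual confusability of related categories.
#'
#' @param dataset an `image_dataset`.
#' @param mean_threshold,threshold_sd mean and SD of per-image true
#'   thresholds (SSNR units); draws are clamped to \[0.05, 0.9\].
#' @param slope psychometric slope (logistic rate, SSNR^-1).
#' @param lapse lapse rate (upper asymptote is `1 - lapse`).
#' @param decision_sd SD of the stopping-rule decision noise (SSNR units).
#' @param block_strength fraction of error mass kept within the same
#'   superordinate cluster (0.5 = uniform).
#' @param seed integer seed for the per-image thresholds.
#' @return An `observer_model`.
#' @export
observer_model <- function(dataset, mean_threshold = 0.3, threshold_sd = 0.08,
                           slope = 20, lapse = 0.02, decision_sd = 0.05,
                           block_strength = 0.75, seed = 1L) {
  K <- dataset$params$K
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  t_img <- stats::rnorm(length(dataset$images), mean_threshold, threshold_sd)
  t_img <- pmin(pmax(t_img, 0.05), 0.9)
  # row-stochastic error matrix (diagonal zero): where errors go
  cluster <- as.integer(seq_len(K) > K / 2)
  E <- matrix(0, K, K)
  for (a in seq_len(K)) {
    same <- which(cluster == cluster[a] & seq_len(K) != a)
    diff_ <- which(cluster != cluster[a])
    if (length(same) == 0L) { E[a, diff_] <- 1 / length(diff_); next }
    if (length(diff_) == 0L) { E[a, same] <- 1 / length(same); next }
    E[a, same] <- block_strength / length(same)
    E[a, diff_] <- (1 - block_strength) / length(diff_)
  }
  structure(list(t_img = t_img, slope = slope, lapse = lapse,
                 guess = 1 / K, K = K, decision_sd = decision_sd,
                 confusability = E, seed = seed),
            class = "observer_model")
}

#' Psychometric law of a simulated observer
#' @param model an `observer_model`.
#' @param w SSNR level(s).
#' @param t true threshold(s).
#' @return Probability of a correct categorization.
#' @export
observer_p_correct <- function(model, w, t) {
  model$guess + (1 - model$lapse - model$guess) /
    (1 + exp(-model$slope * (w - t)))
}

draw_response <- function(model, true_cat, p_correct) {
  if (stats::runif(1) < p_correct) return(true_cat)
  sample.int(model$K, 1L, prob = model$confusability[true_cat, ])
}

#' Simulate the fixed-SSNR design
#'
#' Each image is shown once at every requested SSNR level; the response is
#' correct with the observer's psychometric probability, and errors follow
#' the confusability matrix.
#'
#' @param dataset an `image_dataset`.
#' @param levels SSNR levels in \[0, 1\].
#' @param model an `observer_model`.
#' @param observer_id identifier stored in the trial table.
#' @param seed seed for the response draws.
#' @param index image indices to use (default: the test split).
#' @return A `trial_table` data frame with columns `observer`, `image_id`,
#'   `true_category`, `ssnr`, `response`, `correct`.
#' @export
simulate_observer_fixed <- function(dataset, levels, model, observer_id = 1L,
                                    seed = 1L, index = NULL) {
  if (any(levels < 0 | levels > 1))
    stop("`levels` must be within [0, 1]", call. = FALSE)
  if (is.null(index)) index <- which(dataset$split == "test")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  n <- length(index) * length(levels)
  out <- data.frame(observer = rep(observer_id, n),
                    image_id = rep(index, times = length(levels)),
                    true_category = rep(dataset$labels[index],
                                        times = length(levels)),
                    ssnr = rep(levels, each = length(index)),
                    response = integer(n))
  for (r in seq_len(n)) {
    p <- observer_p_correct(model, out$ssnr[r], model$t_img[out$image_id[r]])
    out$response[r] <- draw_response(model, out$true_category[r], p)
  }
  out$correct <- out$response == out$true_category
  class(out) <- c("trial_table", class(out))
  out
}

#' Simulate the ascending-SSNR (stop-when-confident) design
#'
#' SSNR rises from 0 in steps of `step`; the simulated observer stops when
#' internal detectability crosses the per-image threshold plus Gaussian
#' decision noise, so the stop SSNR is `t_img + noise` rounded *up* to the
#' step grid (and clamped to \[`step`, 1\]).  The categorization response at
#' the stop level follows the psychometric law.  Each trial also carries the
#' image's ground-truth diagnostic map.
#'
#' @inheritParams simulate_observer_fixed
#' @param step SSNR increment per frame (0 < step < 1).
#' @return A list: `trials` (a `trial_table` with a `stop_ssnr` column) and
#'   `maps` (diagnostic maps named by image id).
#' @export
simulate_observer_ascending <- function(dataset, model, step = 0.025,
                                        observer_id = 1L, seed = 1L,
                                        index = NULL) {
  if (step <= 0 || step >= 1) stop("`step` must be in (0, 1)", call. = FALSE)
  if (is.null(index)) index <- which(dataset$split == "test")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  n <- length(index)
  stop_raw <- model$t_img[index] +
    (if (model$decision_sd > 0) stats::rnorm(n, 0, model$decision_sd) else 0)
  stop_ssnr <- pmin(pmax(ceiling(stop_raw / step) * step, step), 1)
  resp <- integer(n)
  for (r in seq_len(n)) {
    p <- observer_p_correct(model, stop_ssnr[r], model$t_img[index[r]])
    resp[r] <- draw_response(model, dataset$labels[index[r]], p)
  }
  trials <- data.frame(observer = observer_id, image_id = index,
                       true_category = dataset$labels[index],
                       stop_ssnr = stop_ssnr, response = resp,
                       correct = resp == dataset$labels[index])
  class(trials) <- c("trial_table", class(trials))
  maps <- lapply(index, function(i) diagnostic_map(dataset, i))
  names(maps) <- as.character(index)
  list(trials = trials, maps = maps)
}

#' Simulate run-structured voxel response patterns
#'
#' Voxel responses are a fixed random linear readout of the supplied feature
#' matrix plus run-specific Gaussian noise: for each run,
#' `response = snr * Z + noise`, where `Z` is the standardized readout and
#' the noise is standard normal.  Every run contains every stimulus exactly
#' once, in a per-run randomized order.  With `timeseries = TRUE` a
#' synthetic BOLD series is also emitted per run (baseline 100, each
#' stimulus adding its amplitude as percent signal change over TRs 3--5
#' post-onset) so amplitude extraction can be tested end to end.
#'
#' @param features numeric matrix, stimulus x feature (e.g. a model layer's
#'   activations to the stimulus set).
#' @param n_voxels number of synthetic voxels.
#' @param n_runs number of acquisition runs (>= 2 for leave-one-run-out).
#' @param snr signal-to-noise scaling of the readout (0 = pure noise).
#' @param seed integer seed.
#' @param conditions optional character vector, one condition label per
#'   stimulus row (default `"clean"`).
#' @param timeseries also emit synthetic BOLD runs.
#' @param tr_noise_sd SD of the TR-level noise in the synthetic BOLD series
#'   (percent-signal-change units).
#' @return A `voxel_pattern_set`: list with `responses`
#'   (trial x voxel matrix), `run`, `stimulus`, `condition`, `roi`,
#'   `normalized`, and (optionally) `bold`, a list of per-run
#'   `list(series, events)`.
#' @export
simulate_voxel_patterns <- function(features, n_voxels, n_runs, snr,
                                    seed = 1L, conditions = NULL,
                                    timeseries = FALSE, tr_noise_sd = 0.1) {
  features <- as.matrix(features)
  n_stim <- nrow(features)
  if (n_runs < 2L) stop("`n_runs` must be >= 2", call. = FALSE)
  if (is.null(conditions)) conditions <- rep("clean", n_stim)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  # global (scalar) standardization only: per-feature or per-voxel z-scoring
  # would distort the stimulus correlation structure the readout carries
  f <- features - mean(features)
  if (stats::sd(f) > 0) f <- f / stats::sd(f)
  W <- matrix(stats::rnorm(ncol(f) * n_voxels), ncol(f), n_voxels)
  S <- f %*% W / sqrt(ncol(f))
  S <- S - mean(S)
  if (stats::sd(S) > 0) S <- S / stats::sd(S)
  resp <- matrix(0, n_runs * n_stim, n_voxels)
  run <- integer(0); stim <- integer(0)
  bold <- if (timeseries) vector("list", n_runs) else NULL
  for (r in seq_len(n_runs)) {
    ord <- sample.int(n_stim)
    amp <- snr * S[ord, , drop = FALSE] +
      matrix(stats::rnorm(n_stim * n_voxels), n_stim, n_voxels)
    rows <- (r - 1L) * n_stim + seq_len(n_stim)
    resp[rows, ] <- amp
    run <- c(run, rep(r, n_stim)); stim <- c(stim, ord)
    if (timeseries) {
      gap <- 8L
      onsets <- 3L + gap * (seq_len(n_stim) - 1L)
      n_tr <- max(onsets) + 4L + 3L
      series <- matrix(100, n_tr, n_voxels) +
        matrix(stats::rnorm(n_tr * n_voxels, 0, tr_noise_sd), n_tr, n_voxels)
      for (s in seq_len(n_stim))  # amplitude in % of baseline over TRs 3-5
        series[onsets[s] + 2:4, ] <- series[onsets[s] + 2:4, ] +
          rep(amp[s, ], each = 3L)
      bold[[r]] <- list(series = series,
                        events = data.frame(onset = onsets, stimulus = ord,
                                            condition = conditions[ord]))
    }
  }
  structure(list(responses = resp, run = run, stimulus = stim,
                 condition = conditions[stim], roi = "synthetic",
                 snr = snr, normalized = FALSE, bold = bold, seed = seed),
            class = "voxel_pattern_set")
}
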