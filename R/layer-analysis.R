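#' Capture per-layer activations for a stimulus
#'
#' Runs a deterministic forward pass and returns the flattened activation
#' vector of every analyzed layer: each convolutional layer after
#' rectification, the rectified fully connected layer(s), and the softmax
#' output.  `model` may also be a plain function mapping an image to a named
#' list of feature vectors (e.g. an identity "layer" of raw pixels), which
#' lets analytic oracles run through the same analysis path.
#'
#' @param model a `vision_model`, or a function `image -> named list`.
#' @param image a `gray_image`.
#' @return A named list of numeric vectors (class `layer_activation_set`).
#' @export
capture_activations <- function(model, image) {
  acts <- if (is.function(model)) model(image)
  else cnn_forward(model, image, keep = TRUE)$acts
  structure(acts, class = "layer_activation_set")
}

# draw one noise field of the requested type
draw_noise_field <- function(noise_type, canvas, spectrum = NULL) {
  if (noise_type == "gaussian")
    gray_image(matrix(stats::rnorm(canvas^2, 127.5, 255 / 6), canvas, canvas))
  else
    make_phase_scrambled_noise(spectrum,
                               seed = sample.int(.Machine$integer.max, 1L))
}

# fixed random unit subsample per layer to bound memory (Pearson r is
# consistent under random coordinate subsampling)
layer_subsample <- function(acts, max_units, seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  lapply(acts, function(v) {
    if (length(v) > max_units) sort(sample.int(length(v), max_units))
    else seq_along(v)
  })
}

profile_frame <- function(layers, thresholds, valid, kind, noise_type) {
  d <- data.frame(layer = layers, index = seq_along(layers),
                  threshold = thresholds, valid = valid, kind = kind,
                  noise_type = noise_type)
  class(d) <- c("layer_threshold_profile", class(d))
  d
}

#' Correlation-based layer noise susceptibility
#'
#' For each analyzed layer, correlates (Pearson) the activation pattern
#' evoked by each noise-free image with the pattern evoked by the same image
#' at each SSNR level, averaged over images and noise draws.  If the
#' correlation at SSNR 0 is still positive, the curve is linearly rescaled
#' to span 0 to 1 before thresholding.  A logistic is then fitted and the
#' SSNR at which the (rescaled) correlation reaches 0.5 is the layer's
#' threshold.  Higher thresholds mean greater susceptibility to noise.
#'
#' @param model a `vision_model` or feature function (see
#'   [capture_activations()]).
#' @param images list of `gray_image`s.
#' @param noise_type `"gaussian"` or `"phase_scrambled"`.
#' @param levels SSNR levels; should span values near 0 and 1.
#' @param n_noise noise draws per image and level.
#' @param seed seed for noise draws and unit subsampling.
#' @param clip clip blends into \[0, 255\] (set `FALSE` for analytic
#'   oracles on unclipped blends).
#' @param spectrum amplitude spectrum for phase-scrambled noise.
#' @param max_units layers with more units are randomly subsampled.
#' @param rescale apply the rescale-to-\[0,1\] rule when r(0) > 0.
#' @return A `layer_threshold_profile` data frame, with the per-layer
#'   correlation curves in `attr(, "curves")`.
#' @export
corr_susceptibility <- function(model, images,
                                noise_type = c("gaussian", "phase_scrambled"),
                                levels = seq(0, 1, by = 0.05), n_noise = 2L,
                                seed = 1L, clip = TRUE, spectrum = NULL,
                                max_units = 50000L, rescale = TRUE) {
  noise_type <- match.arg(noise_type)
  levels <- sort(levels)
  canvas <- nrow(as.matrix(unclass(images[[1L]])))
  if (noise_type == "phase_scrambled" && is.null(spectrum))
    spectrum <- mean_amplitude_spectrum(images)
  clean <- lapply(images, function(im) capture_activations(model, im))
  lyr <- names(clean[[1L]])
  sub <- layer_subsample(clean[[1L]], max_units, seed)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  curves <- matrix(NA_real_, length(levels), length(lyr),
                   dimnames = list(NULL, lyr))
  for (li in seq_along(levels)) {
    w <- levels[li]
    acc <- matrix(NA_real_, length(images) * n_noise, length(lyr))
    row <- 0L
    for (i in seq_along(images)) {
      for (d in seq_len(n_noise)) {
        row <- row + 1L
        noisy <- if (w == 1) images[[i]] else
          blend_ssnr(images[[i]], draw_noise_field(noise_type, canvas,
                                                   spectrum), w, clip = clip)
        a <- capture_activations(model, noisy)
        for (L in seq_along(lyr)) {
          cv <- clean[[i]][[L]][sub[[L]]]; nv <- a[[L]][sub[[L]]]
          if (stats::sd(cv) == 0 || stats::sd(nv) == 0) next
          acc[row, L] <- stats::cor(cv, nv)
        }
      }
    }
    curves[li, ] <- colMeans(acc, na.rm = TRUE)
  }
  th <- rep(NA_real_, length(lyr)); ok <- rep(FALSE, length(lyr))
  fits <- vector("list", length(lyr))
  for (L in seq_along(lyr)) {
    y <- curves[, L]
    if (any(!is.finite(y))) next  # constant-activation layer: flagged invalid
    if (rescale && y[1L] > 0) y <- (y - min(y)) / (max(y) - min(y))
    fit <- fit_logistic4(psychometric_curve(levels, pmin(pmax(y, 0), 1)),
                         floor_max = 0.5)
    est <- threshold_at(fit, 0.5)
    fits[[L]] <- fit
    if (est$valid) { th[L] <- est$threshold; ok[L] <- TRUE }
  }
  out <- profile_frame(lyr, th, ok, "correlation", noise_type)
  attr(out, "curves") <- cbind(level = levels, curves)
  attr(out, "fits") <- fits
  out
}

#' Classification-based layer noise susceptibility
#'
#' Trains a linear multiclass support-vector classifier (one-vs-one, default
#' regularization) on each layer's activation patterns for *noise-free*
#' training images, then tests it on held-out images blended at each SSNR
#' level.  A logistic fit of accuracy by SSNR is inverted at 50% accuracy to
#' give the layer's classification-based threshold.
#'
#' @inheritParams corr_susceptibility
#' @param train_images,train_labels noise-free training set for the readout.
#' @param test_images,test_labels held-out images (disjoint from training).
#' @param cost SVM regularization constant.
#' @return A `layer_threshold_profile`, with accuracy curves in
#'   `attr(, "curves")` and the clean readout accuracies (level 1) in
#'   `attr(, "clean_accuracy")`.
#' @export
clf_susceptibility <- function(model, train_images, train_labels,
                               test_images, test_labels,
                               noise_type = c("gaussian", "phase_scrambled"),
                               levels = seq(0, 1, by = 0.1), n_noise = 1L,
                               seed = 1L, spectrum = NULL,
                               max_units = 50000L, cost = 1) {
  noise_type <- match.arg(noise_type)
  if (length(unique(train_labels)) < 2L)
    stop("need at least 2 categories", call. = FALSE)
  levels <- sort(levels)
  canvas <- nrow(as.matrix(unclass(train_images[[1L]])))
  if (noise_type == "phase_scrambled" && is.null(spectrum))
    spectrum <- mean_amplitude_spectrum(train_images)
  tr_acts <- lapply(train_images, function(im) capture_activations(model, im))
  lyr <- names(tr_acts[[1L]])
  sub <- layer_subsample(tr_acts[[1L]], max_units, seed)
  lvls <- sort(unique(train_labels))
  svms <- vector("list", length(lyr)); scalers <- vector("list", length(lyr))
  for (L in seq_along(lyr)) {
    X <- t(vapply(tr_acts, function(a) a[[L]][sub[[L]]],
                  numeric(length(sub[[L]]))))
    mu <- colMeans(X); sdev <- apply(X, 2, stats::sd); sdev[sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    scalers[[L]] <- list(mu = mu, sd = sdev)
    svms[[L]] <- e1071::svm(Xs, factor(train_labels, levels = lvls),
                            kernel = "linear", cost = cost, scale = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  curves <- matrix(NA_real_, length(levels), length(lyr),
                   dimnames = list(NULL, lyr))
  for (li in seq_along(levels)) {
    w <- levels[li]
    hits <- matrix(NA, length(test_images) * n_noise, length(lyr))
    row <- 0L
    draws <- if (w == 1) 1L else n_noise
    for (d in seq_len(draws)) {
      for (i in seq_along(test_images)) {
        row <- row + 1L
        noisy <- if (w == 1) test_images[[i]] else
          blend_ssnr(test_images[[i]],
                     draw_noise_field(noise_type, canvas, spectrum), w)
        a <- capture_activations(model, noisy)
        for (L in seq_along(lyr)) {
          v <- (a[[L]][sub[[L]]] - scalers[[L]]$mu) / scalers[[L]]$sd
          pred <- stats::predict(svms[[L]], matrix(v, nrow = 1L))
          hits[row, L] <- as.character(pred) == as.character(test_labels[i])
        }
      }
    }
    curves[li, ] <- colMeans(hits, na.rm = TRUE)
  }
  th <- rep(NA_real_, length(lyr)); ok <- rep(FALSE, length(lyr))
  for (L in seq_along(lyr)) {
    fit <- fit_logistic4(psychometric_curve(levels, curves[, L]),
                         floor_max = 1 / length(lvls) + 0.2)
    est <- threshold_at(fit, 0.5)
    if (est$valid) { th[L] <- est$threshold; ok[L] <- TRUE }
  }
  out <- profile_frame(lyr, th, ok, "classification", noise_type)
  attr(out, "curves") <- cbind(level = levels, curves)
  attr(out, "clean_accuracy") <- curves[length(levels), ]
  out
}

#' Slope of SSNR threshold across layers
#'
#' Ordinary least-squares slope of layer threshold against 1-based layer
#' index, over the valid layers of a profile; a positive slope means noise
#' susceptibility grows with depth.
#'
#' @param profile a `layer_threshold_profile`.
#' @return List with `slope`, `p` (two-sided), `n`, `zero_variance` flag.
#' @export
threshold_slope <- function(profile) {
  d <- profile[profile$valid, ]
  if (nrow(d) < 3L) stop("need at least 3 valid layers", call. = FALSE)
  if (stats::var(d$threshold) == 0)
    return(list(slope = 0, p = 1, n = nrow(d), zero_variance = TRUE))
  fit <- stats::lm(threshold ~ index, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  list(slope = unname(sm[2, 1]), p = unname(sm[2, 4]), n = nrow(d),
       zero_variance = FALSE)
}

#' Canonical correlation between two models' layer weights
#'
#' Quantifies how similar a layer's learned features are across two models
#' (e.g. before and after noise training).  The layer's weights are
#' reshaped to a units x incoming-weights matrix; canonical correlation
#' analysis then treats the incoming-weight coordinates as observations and
#' the units as variables, so the result is invariant to any invertible
#' linear mixing of one model's units (in particular to unit permutation
#' and rotation) and measures overlap of the weight subspaces themselves.
#' Covariances are whitened with a small ridge for numerical stability;
#' rank-deficient inputs are truncated to the numerically positive spectrum
#' and flagged.
#'
#' @param model_a,model_b `vision_model`s sharing the layer's shape.
#' @param layer layer name.
#' @param ridge ridge added to the covariance diagonals.
#' @return List with `mean` (mean canonical correlation), `correlations`
#'   (full spectrum), `n_components`, `rank_deficient` flag.
#' @export
weight_cca <- function(model_a, model_b, layer, ridge = 1e-6) {
  X <- layer_weights(model_a, layer)
  Y <- layer_weights(model_b, layer)
  if (!all(dim(X) == dim(Y)))
    stop("layer shapes differ between models", call. = FALSE)
  cca_regularized(t(X), t(Y), ridge = ridge)
}

# regularized CCA on two n x p matrices (rows = observations)
cca_regularized <- function(X, Y, ridge = 1e-6, tol = 1e-8) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1); Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  whiten <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > tol * max(e$values)  # rank before regularization
    list(W = e$vectors[, keep, drop = FALSE] %*%
           diag(1 / sqrt(e$values[keep] + ridge * mean(diag(S))),
                sum(keep)),
         rank = sum(keep))
  }
  wx <- whiten(Sxx); wy <- whiten(Syy)
  M <- t(wx$W) %*% Sxy %*% wy$W
  d <- svd(M)$d
  ncomp <- min(wx$rank, wy$rank)
  cors <- pmin(pmax(d[seq_len(ncomp)], 0), 1)
  list(mean = mean(cors), correlations = cors, n_components = ncomp,
       rank_deficient = wx$rank < ncol(X) || wy$rank < ncol(Y))
}
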