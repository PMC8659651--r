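#' Clean/noisy training mixture specification
#'
#' Describes the stream a model is trained on: each training sample draws a
#' condition (clean, pixelated Gaussian noise, or Fourier phase-scrambled
#' noise) with the given proportion; noisy conditions draw an SSNR level
#' uniformly from `[lo, hi]`.  The canonical noise-training recipe mixes
#' noise-free objects with objects at SSNR levels spanning 0.2 to 0.99.
#'
#' @param condition character vector: `"clean"`, `"gaussian"`,
#'   `"phase_scrambled"`.
#' @param lo,hi SSNR range per condition (ignored for `"clean"`; for a single
#'   level set `lo == hi`).  Noisy levels must lie in (0, 1\].
#' @param prop sampling proportions; must sum to 1.
#' @return A `noise_mix` data frame.
#' @examples
#' noise_mix("clean", prop = 1)                        # clean-only control
#' noise_mix(c("clean", "gaussian"), lo = c(NA, 0.2),
#'           hi = c(NA, 0.99), prop = c(0.5, 0.5))     # noise training
#' @export
noise_mix <- function(condition, lo = NA_real_, hi = NA_real_, prop) {
  ok <- c("clean", "gaussian", "phase_scrambled")
  if (!all(condition %in% ok))
    stop("conditions must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  d <- data.frame(condition = condition,
                  lo = rep_len(lo, length(condition)),
                  hi = rep_len(hi, length(condition)),
                  prop = rep_len(prop, length(condition)))
  if (abs(sum(d$prop) - 1) > 1e-8)
    stop("`prop` must sum to 1", call. = FALSE)
  noisy <- d$condition != "clean"
  if (any(noisy & (is.na(d$lo) | is.na(d$hi) | d$lo <= 0 | d$hi > 1 |
                   d$lo > d$hi)))
    stop("noisy conditions need SSNR ranges within (0, 1]", call. = FALSE)
  class(d) <- c("noise_mix", class(d))
  d
}

#' Training hyperparameters
#'
#' Defaults follow the standard recipe for this training protocol:
#' stochastic gradient descent over 20 epochs with fixed learning rate
#' 0.001, batch size 24, weight decay 0.0005 and momentum 0.9.
#'
#' @param learning_rate,batch_size,momentum,weight_decay,epochs
#'   positive hyperparameters.
#' @param augment apply the random crop/resize/intensity-jitter pipeline to
#'   each training sample.
#' @param seed seed controlling shuffling, augmentation, noise draws.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 24L,
                         momentum = 0.9, weight_decay = 0.0005,
                         epochs = 20L, augment = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, momentum >= 0,
            weight_decay >= 0, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 augment = augment, seed = seed),
            class = "train_config")
}

#' Random crop / resize / intensity-jitter augmentation
#'
#' Crops a rectangular region subtending 87.5% of the image's linear extent
#' with an aspect ratio drawn uniformly from \[2/3, 3/2\], resizes it back to
#' `canvas` (bilinear), and shifts the whole image by a per-image intensity
#' offset drawn from Normal(0, 3).  SSNR blending is applied *after*
#' augmentation; mean-intensity subtraction happens inside the model.
#'
#' @param image a `gray_image`.
#' @param canvas output side length.
#' @param crop_fraction linear extent of the crop.
#' @param aspect_range range of width-to-height aspect ratios.
#' @param intensity_sd SD of the per-image intensity offset.
#' @param seed optional seed for a reproducible single draw.
#' @return A `gray_image` of dimension `canvas x canvas`.
#' @export
augment <- function(image, canvas = NULL, crop_fraction = 0.875,
                    aspect_range = c(2 / 3, 3 / 2), intensity_sd = 3,
                    seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  m <- as.matrix(unclass(image))
  h <- nrow(m); w <- ncol(m)
  if (is.null(canvas)) canvas <- min(h, w)
  L <- crop_fraction * min(h, w)
  a <- stats::runif(1, aspect_range[1], aspect_range[2])
  cw <- max(2L, min(w, round(L * sqrt(a))))
  ch <- max(2L, min(h, round(L / sqrt(a))))
  top <- if (h > ch) sample.int(h - ch + 1L, 1L) else 1L
  left <- if (w > cw) sample.int(w - cw + 1L, 1L) else 1L
  crop <- m[top:(top + ch - 1L), left:(left + cw - 1L), drop = FALSE]
  out <- as.matrix(EBImage::resize(crop, w = canvas, h = canvas))
  off <- if (intensity_sd > 0) stats::rnorm(1, 0, intensity_sd) else 0
  gray_image(out + off)
}

# one training stimulus: augmented image blended per the drawn mix condition
draw_training_sample <- function(img, canvas, mix, spectrum, cfg) {
  x <- if (cfg$augment) augment(img, canvas = canvas) else img
  ci <- if (nrow(mix) == 1L) 1L else
    sample.int(nrow(mix), 1L, prob = mix$prop)
  cond <- mix$condition[ci]
  if (cond == "clean") return(clip_image(x))
  w <- if (mix$lo[ci] == mix$hi[ci]) mix$lo[ci] else
    stats::runif(1, mix$lo[ci], mix$hi[ci])
  noise <- if (cond == "gaussian") {
    gray_image(matrix(stats::rnorm(canvas^2, 127.5, 255 / 6), canvas, canvas))
  } else {
    make_phase_scrambled_noise(spectrum,
                               seed = sample.int(.Machine$integer.max, 1L))
  }
  blend_ssnr(x, noise, w)
}

#' Train a model on a clean/noisy image stream
#'
#' Minimizes the multinomial logistic (cross-entropy) loss by stochastic
#' gradient descent with momentum and weight decay.  Each sample of each
#' minibatch independently draws its condition from `mix` (per-sample
#' stochastic mixing), is augmented (if configured) and SSNR-blended, and
#' the frozen mean-intensity constant -- estimated from a pre-pass over the
#' same stream -- is subtracted inside the model.
#'
#' @param model a `vision_model` (see [small_cnn()]).
#' @param dataset an `image_dataset`; the train split is used.
#' @param mix a [noise_mix()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss/accuracy.
#' @return The trained `vision_model`, with `$train_log` (epoch, loss,
#'   accuracy) attached.
#' @export
train_model <- function(model, dataset, mix, cfg = train_config(),
                        verbose = FALSE) {
  tr <- dataset_split(dataset, "train")
  K <- model$n_classes
  if (max(tr$labels) > K)
    stop("dataset labels exceed the model's number of classes", call. = FALSE)
  canvas <- model$canvas
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  spectrum <- if (any(mix$condition == "phase_scrambled"))
    mean_amplitude_spectrum(tr$images) else NULL

  # frozen mean-intensity constant from a pre-pass over the training stream
  n_pre <- min(100L, length(tr$images))
  pre_idx <- sample.int(length(tr$images), n_pre)
  model$input_mean <- mean(vapply(pre_idx, function(i) {
    mean(unclass(draw_training_sample(tr$images[[i]], canvas, mix, spectrum,
                                      cfg)))
  }, 0))

  state <- lapply(model$layers, function(ly) {
    if (is.null(ly$W)) NULL else list(W = ly$W * 0, b = ly$b * 0)
  })
  n <- length(tr$images)
  log <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                    accuracy = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0); hits <- logical(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bgrads <- NULL
      for (i in idx) {
        x <- draw_training_sample(tr$images[[i]], canvas, mix, spectrum, cfg)
        fw <- cnn_forward(model, x, keep = TRUE)
        lab <- tr$labels[i]
        losses <- c(losses, -log(max(fw$probs[lab], 1e-12)))
        hits <- c(hits, which.max(fw$probs) == lab)
        g <- cnn_backward(model, fw, lab)
        bgrads <- if (is.null(bgrads)) g else
          mapply(function(a, b) {
            if (is.null(a)) NULL else list(W = a$W + b$W, b = a$b + b$b)
          }, bgrads, g, SIMPLIFY = FALSE)
      }
      up <- sgd_update(model, bgrads, state, cfg$learning_rate, cfg$momentum,
                       cfg$weight_decay, length(idx))
      model <- up$model; state <- up$state
    }
    log$loss[ep] <- mean(losses); log$accuracy[ep] <- mean(hits)
    if (!is.finite(log$loss[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep,
           call. = FALSE)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.3f", ep, log$loss[ep],
                      log$accuracy[ep]))
  }
  model$train_log <- log
  model$mix <- mix
  model
}

#' Psychometric curve container
#'
#' @param levels strictly increasing SSNR levels.
#' @param values accuracy (or correlation) at each level.
#' @param n number of observations per level.
#' @return A `psychometric_curve` data frame.
#' @export
psychometric_curve <- function(levels, values, n = NA_integer_) {
  if (is.unsorted(levels, strictly = TRUE))
    stop("`levels` must be strictly increasing", call. = FALSE)
  d <- data.frame(level = levels, value = values, n = rep_len(n,
                                                              length(levels)))
  class(d) <- c("psychometric_curve", class(d))
  d
}

#' Accuracy as a function of SSNR
#'
#' Presents every test image at every SSNR level (with `n_noise` freshly
#' drawn noise fields per image and level), classifies by the highest
#' softmax response among the trained categories, and averages accuracy per
#' level.  At level 1 the blend equals the clean image, so the clean test
#' accuracy is reproduced exactly.
#'
#' @param model a trained `vision_model`.
#' @param images list of `gray_image`s.
#' @param labels integer true categories (1-based).
#' @param noise_type `"gaussian"` or `"phase_scrambled"`.
#' @param levels SSNR levels.
#' @param n_noise noise resamples per image and level.
#' @param seed seed for the noise draws.
#' @param spectrum amplitude spectrum for phase-scrambled noise (defaults to
#'   the mean spectrum of `images`).
#' @return A [psychometric_curve()].
#' @export
accuracy_by_ssnr <- function(model, images, labels,
                             noise_type = c("gaussian", "phase_scrambled"),
                             levels = seq(0.05, 1, by = 0.05), n_noise = 1L,
                             seed = 1L, spectrum = NULL) {
  noise_type <- match.arg(noise_type)
  if (n_noise < 1L) stop("`n_noise` must be >= 1", call. = FALSE)
  canvas <- model$canvas
  if (noise_type == "phase_scrambled" && is.null(spectrum))
    spectrum <- mean_amplitude_spectrum(images)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  levels <- sort(levels)
  acc <- numeric(length(levels))
  for (li in seq_along(levels)) {
    w <- levels[li]
    hits <- 0L; total <- 0L
    draws <- if (w == 1) 1L else n_noise
    for (d in seq_len(draws)) {
      for (i in seq_along(images)) {
        noise <- if (w == 1) images[[i]] else if (noise_type == "gaussian")
          gray_image(matrix(stats::rnorm(canvas^2, 127.5, 255 / 6),
                            canvas, canvas))
        else make_phase_scrambled_noise(
          spectrum, seed = sample.int(.Machine$integer.max, 1L))
        x <- blend_ssnr(images[[i]], noise, w)
        hits <- hits + (predict_class(model, x) == labels[i])
        total <- total + 1L
      }
    }
    acc[li] <- hits / total
  }
  psychometric_curve(levels, acc, n = length(images) * n_noise)
}
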