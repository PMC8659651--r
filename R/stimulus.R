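#' Pixelated Gaussian noise field
#'
#' Draws every pixel independently from a Gaussian centred at the intensity
#' midpoint 127.5, with standard deviation 255/6 so that the 0--255 intensity
#' range spans +/- 3 SD.  The field is returned *unclipped*: clipping is
#' applied only after SSNR blending (see [blend_ssnr()]), so the modest
#' Gaussian tails survive until then.
#'
#' @param height,width positive integer dimensions.
#' @param seed integer seed; the same seed gives a bit-identical field.
#' @return An unclipped `gray_image`.
#' @seealso [make_phase_scrambled_noise()] for spatially correlated noise.
#' @export
make_gaussian_noise <- function(height, width, seed = NULL) {
  if (height < 1 || width < 1)
    stop("`height` and `width` must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  m <- matrix(stats::rnorm(height * width, mean = 127.5, sd = 255 / 6),
              nrow = height, ncol = width)
  gray_image(m, meta = list(noise = "gaussian", seed = seed))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mean Fourier amplitude spectrum of a set of images
#'
#' Element-wise mean of the modulus of each image's 2-D discrete Fourier
#' transform.  Used as the target spectrum for phase-scrambled noise so the
#' noise shares the (approximately 1/f) power spectrum of the image set as a
#' whole, rather than of any single image.
#'
#' @param images a list of `gray_image`s (or matrices) of equal dimensions.
#' @return An `amplitude_spectrum`: a nonnegative matrix of the same
#'   dimensions as the images.
#' @export
mean_amplitude_spectrum <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list", call. = FALSE)
  dims <- dim(as.matrix(images[[1L]]))
  acc <- matrix(0, dims[1L], dims[2L])
  for (img in images) {
    m <- as.matrix(unclass(img))
    if (!identical(dim(m), dims))
      stop("all images must have identical dimensions", call. = FALSE)
    acc <- acc + Mod(stats::fft(m))
  }
  structure(acc / length(images), class = "amplitude_spectrum")
}

#' Fourier phase-scrambled noise field
#'
#' Combines a target amplitude spectrum with phases drawn uniformly on
#' (-pi, pi], imposed with Hermitian (conjugate) symmetry so the inverse
#' transform is exactly real.  The DC phase is fixed at 0 and Nyquist bins
#' (present for even dimensions) receive phase 0 or pi only, as those bins
#' must stay real.  The real part of the inverse transform is shifted to
#' mean 127.5; no variance rescaling is applied, so the contrast of the
#' field is carried entirely by the supplied spectrum.  Off-DC Fourier
#' magnitudes of the output equal the input spectrum exactly.
#'
#' @param spectrum an `amplitude_spectrum` (nonnegative matrix).
#' @param seed integer seed for the random phases.
#' @return An unclipped `gray_image` with mean exactly 127.5.
#' @export
make_phase_scrambled_noise <- function(spectrum, seed = NULL) {
  a <- unclass(spectrum)
  if (!is.matrix(a) || any(!is.finite(a)) || any(a < 0))
    stop("`spectrum` must be a finite nonnegative matrix", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  phi <- matrix(stats::runif(h * w, -pi, pi), h, w)

  # index of the conjugate partner of bin (u, v), 1-based
  u <- (seq_len(h) - 1L); v <- (seq_len(w) - 1L)
  cu <- ((-u) %% h) + 1L; cv <- ((-v) %% w) + 1L
  self_u <- which(cu == seq_len(h))  # DC and (even h) Nyquist rows
  self_v <- which(cv == seq_len(w))

  # antisymmetrize: phi(k) <- (phi(k) - phi(-k)) / 2, exact Hermitian phases
  phi_conj <- phi[cu, cv, drop = FALSE]
  phi <- (phi - phi_conj) / 2
  # self-conjugate bins must be real: phase 0 or pi, chosen at random
  for (i in self_u) for (j in self_v)
    phi[i, j] <- sample(c(0, pi), 1L)
  phi[1L, 1L] <- 0  # DC phase fixed: preserves the sign of the mean

  z <- a * exp(1i * phi)
  field <- stats::fft(z, inverse = TRUE) / (h * w)
  re <- Re(field)
  re <- re - mean(re) + 127.5
  gray_image(re, meta = list(noise = "phase_scrambled", seed = seed,
                             intensity_mapping = "shift to mean 127.5, no variance rescaling",
                             max_imag_residual = max(abs(Im(field)))))
}

#' Blend a signal image with a noise field at a given SSNR level
#'
#' Computes the target image `T = w * S + (1 - w) * N` pixel-wise, then clips
#' the result into \[0, 255\].  `w` is the SSNR (signal-to-signal-plus-noise
#' ratio): 0 is pure noise, 1 is the pure signal.
#'
#' @param signal,noise `gray_image`s (or matrices) of equal dimensions; the
#'   noise field may be unclipped.
#' @param w SSNR level in \[0, 1\].
#' @param clip clip the blend into \[0, 255\] (the default).  `clip = FALSE`
#'   is useful for analyses that need the raw linear blend.
#' @return A `gray_image`.
#' @export
blend_ssnr <- function(signal, noise, w, clip = TRUE) {
  s <- as.matrix(unclass(signal)); n <- as.matrix(unclass(noise))
  if (!identical(dim(s), dim(n)))
    stop("`signal` and `noise` dimensions differ", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("`w` must be a single value in [0, 1]", call. = FALSE)
  out <- gray_image(w * s + (1 - w) * n, meta = list(ssnr = w))
  if (clip) clip_image(out) else out
}

#' SSNR series over a fixed noise field
#'
#' Applies [blend_ssnr()] at each requested level while holding the *same*
#' noise field fixed, as in an ascending-SSNR trial where a single noise
#' image is generated and the target gradually increases in SSNR.
#'
#' @inheritParams blend_ssnr
#' @param levels numeric vector of SSNR levels in \[0, 1\].
#' @return A list of `gray_image`s, one per level.
#' @export
ssnr_series <- function(signal, noise, levels, clip = TRUE) {
  if (length(levels) == 0L) stop("`levels` must be non-empty", call. = FALSE)
  lapply(levels, function(w) blend_ssnr(signal, noise, w, clip = clip))
}

#' Ascending-SSNR level grid
#'
#' Convenience constructor for the ascending staircase used in the
#' stop-when-confident design: levels rise from 0 to 1 in steps of `step`
#' (0.025 by default, giving 41 frames).
#'
#' @param step step size in SSNR units.
#' @return Numeric vector of levels.
#' @export
ssnr_ascending_levels <- function(step = 0.025) seq(0, 1, by = step)
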