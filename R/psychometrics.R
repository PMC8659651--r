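#' Fit a 4-parameter logistic psychometric function
#'
#' Least-squares fit of `f(w) = L + (U - L) / (1 + exp(-k (w - m)))` to an
#' accuracy-by-SSNR (or correlation-by-SSNR) curve, by Levenberg-Marquardt
#' with one heuristic start plus `n_restarts` random restarts (fixed restart
#' seed); the best converged fit by residual sum of squares wins.  The lower
#' asymptote is bounded to `[0, floor_max]` (set `floor_max` near
#' `1/K + 0.2` when the guessing floor 1/K is known) to prevent degenerate
#' fits.  A constant curve yields `converged = FALSE` rather than an error.
#'
#' @param curve a [psychometric_curve()] (or data frame with `level`,
#'   `value`).
#' @param floor_max upper bound for the lower asymptote.
#' @param n_restarts number of random restarts.
#' @param restart_seed seed for the restart draws.
#' @return A `logistic_fit`: list with `lower`, `upper`, `midpoint`,
#'   `slope`, `sse`, `converged`.
#' @export
fit_logistic4 <- function(curve, floor_max = 0.5, n_restarts = 5L,
                          restart_seed = 42L) {
  w <- curve$level; y <- curve$value
  bad <- list(lower = NA_real_, upper = NA_real_, midpoint = NA_real_,
              slope = NA_real_, sse = NA_real_, converged = FALSE)
  class(bad) <- "logistic_fit"
  if (length(unique(w)) < 4L)
    stop("need at least 4 distinct levels", call. = FALSE)
  if (diff(range(y)) < 1e-9) return(bad)

  f <- function(p) p[1] + (p[2] - p[1]) / (1 + exp(-p[4] * (w - p[3])))
  resid_fun <- function(p) f(p) - y
  lowerb <- c(0, 0, min(w) - 0.5, 1e-3)
  upperb <- c(floor_max, 1, max(w) + 0.5, 500)
  mid_guess <- w[which.min(abs(y - (min(y) + max(y)) / 2))]
  starts <- list(c(min(max(min(y), 0), floor_max), min(max(y), 1),
                   mid_guess, 10))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(restart_seed)
  for (i in seq_len(n_restarts))
    starts[[i + 1L]] <- c(stats::runif(1, 0, floor_max),
                          stats::runif(1, max(min(max(y) - 0.05, 0.95), 0), 1),
                          stats::runif(1, min(w), max(w)),
                          10^stats::runif(1, 0.3, 2.2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lowerb), upperb),
                         lower = lowerb, upper = upperb, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par,
                                                     sse = sse)
  }
  if (is.null(best)) return(bad)
  out <- list(lower = best$par[1], upper = best$par[2],
              midpoint = best$par[3], slope = best$par[4], sse = best$sse,
              converged = TRUE)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) cat("<logistic_fit: not converged>\n")
  else cat(sprintf(
    "<logistic_fit: L=%.3f U=%.3f m=%.3f k=%.2f, sse=%.2e>\n",
    x$lower, x$upper, x$midpoint, x$slope, x$sse))
  invisible(x)
}

#' Evaluate a fitted 4-parameter logistic
#' @param fit a `logistic_fit`.
#' @param w SSNR level(s).
#' @return Fitted values.
#' @export
predict_logistic4 <- function(fit, w) {
  fit$lower + (fit$upper - fit$lower) /
    (1 + exp(-fit$slope * (w - fit$midpoint)))
}

#' SSNR threshold at a criterion level
#'
#' Analytic inversion of the fitted logistic:
#' `t = m - log((U - L) / (c - L) - 1) / k`.  The estimate is invalid when
#' the criterion lies outside the open interval `(L, U)` or the crossing
#' falls above SSNR 1 (the function never reaches the criterion within the
#' stimulus range); a crossing below 0 is clamped to 0 (the curve is above
#' criterion from the start).
#'
#' @param fit a `logistic_fit`.
#' @param criterion criterion level (e.g. 0.5 accuracy, 0.9 accuracy, or
#'   correlation 0.5).
#' @return A `threshold_estimate`: list with `threshold`, `criterion`,
#'   `valid`, `reason`.
#' @export
threshold_at <- function(fit, criterion) {
  bad <- function(reason) structure(
    list(threshold = NA_real_, criterion = criterion, valid = FALSE,
         reason = reason), class = "threshold_estimate")
  if (!isTRUE(fit$converged)) return(bad("fit did not converge"))
  if (criterion <= fit$lower || criterion >= fit$upper)
    return(bad("criterion outside the asymptotes"))
  t <- fit$midpoint -
    log((fit$upper - fit$lower) / (criterion - fit$lower) - 1) / fit$slope
  if (!is.finite(t)) return(bad("degenerate inversion"))
  if (t > 1) return(bad("criterion not reached by SSNR 1"))
  structure(list(threshold = max(t, 0), criterion = criterion, valid = TRUE,
                 reason = NULL), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<threshold: %.4f at criterion %.2f>\n", x$threshold,
                x$criterion))
  else cat(sprintf("<threshold: invalid (%s)>\n", x$reason))
  invisible(x)
}

#' Per-image SSNR thresholds of a model, with exclusion rules
#'
#' For each image, presents the object with `n_noise` freshly generated
#' noise fields at each SSNR level, fits the 4-parameter logistic to the
#' per-image accuracy curve, and inverts it at `criterion` (0.9 by
#' default).  Two exclusion rules apply: (a) images of the category the
#' model is modally biased toward when shown pure noise (`reason "bias"`),
#' and (b) images whose fitted curve never reaches the criterion by SSNR 1
#' (`reason "unreachable"`).
#'
#' @param model a trained `vision_model`, or a classifier function
#'   `image -> category index` (then `canvas` and `n_classes` must be
#'   given).
#' @param images,labels test images and their true categories.
#' @param levels SSNR levels for the per-image curves.
#' @param n_noise noise resamples per image and level.
#' @param criterion accuracy criterion for the threshold.
#' @param n_bias_probe number of pure-noise probes used to find the model's
#'   noise-bias category.
#' @param seed seed for noise draws.
#' @param canvas,n_classes image size and category count; taken from the
#'   model unless it is a plain function.
#' @return List with `thresholds` (data frame: `image_id`, `label`,
#'   `threshold`, `valid`, `excluded`, `reason`), `noise_modal_category`,
#'   and `noise_modal_freq`.
#' @export
per_image_thresholds <- function(model, images, labels,
                                 levels = seq(0.05, 1, by = 0.05),
                                 n_noise = 50L, criterion = 0.9,
                                 n_bias_probe = 50L, seed = 1L,
                                 canvas = NULL, n_classes = NULL) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  classify <- if (is.function(model)) model else
    function(img) predict_class(model, img)
  canvas <- canvas %||% model$canvas
  K <- n_classes %||% model$n_classes
  probe <- vapply(seq_len(n_bias_probe), function(i) {
    as.numeric(classify(gray_image(
      matrix(stats::rnorm(canvas^2, 127.5, 255 / 6), canvas, canvas))))
  }, 0)
  tab <- tabulate(as.integer(probe), nbins = K)
  modal <- which.max(tab)
  modal_freq <- tab[modal] / n_bias_probe

  res <- data.frame(image_id = seq_along(images), label = labels,
                    threshold = NA_real_, valid = FALSE, excluded = FALSE,
                    reason = NA_character_)
  levels <- sort(levels)
  for (i in seq_along(images)) {
    if (labels[i] == modal) {
      res$excluded[i] <- TRUE; res$reason[i] <- "bias"; next
    }
    acc <- vapply(levels, function(w) {
      if (w == 1) return(mean(classify(images[[i]]) == labels[i]))
      hits <- vapply(seq_len(n_noise), function(d) {
        noise <- gray_image(matrix(stats::rnorm(canvas^2, 127.5, 255 / 6),
                                   canvas, canvas))
        classify(blend_ssnr(images[[i]], noise, w)) == labels[i]
      }, NA)
      mean(hits)
    }, 0)
    fit <- fit_logistic4(psychometric_curve(levels, acc),
                         floor_max = 1 / K + 0.2)
    th <- threshold_at(fit, criterion)
    if (th$valid) {
      res$threshold[i] <- th$threshold; res$valid[i] <- TRUE
    } else {
      res$excluded[i] <- TRUE; res$reason[i] <- "unreachable"
    }
  }
  list(thresholds = res, noise_modal_category = modal,
       noise_modal_freq = modal_freq)
}

#' Confusion matrix from a trial table
#'
#' @param trials a `trial_table` with `true_category` and `response`.
#' @param K number of categories.
#' @return A K x K row-stochastic matrix (true categories in rows, responses
#'   in columns).  Rows with no trials are NA and listed in the
#'   `"empty_rows"` attribute.
#' @export
confusion_matrix <- function(trials, K) {
  if (nrow(trials) == 0L) stop("`trials` is empty", call. = FALSE)
  tab <- table(factor(trials$true_category, levels = seq_len(K)),
               factor(trials$response, levels = seq_len(K)))
  m <- unclass(tab / pmax(rowSums(tab), 1L))
  empty <- which(rowSums(tab) == 0L)
  m[empty, ] <- NA_real_
  attr(m, "empty_rows") <- empty
  m
}

#' Split-half reliability of per-image thresholds
#'
#' Repeatedly splits the observers into two random halves, averages each
#' half's per-image thresholds, and correlates the two half-means across
#' images.  With an odd observer count the halves are floor/ceil sized.
#'
#' @param thresholds observer x image numeric matrix (NAs allowed, e.g.
#'   incorrect trials removed upstream).
#' @param n_splits number of random splits.
#' @param seed seed for the splits.
#' @return List with `mean_r`, `sd_r`, and the per-split correlations `r`.
#' @export
split_half_reliability <- function(thresholds, n_splits = 10000L, seed = 1L) {
  n_obs <- nrow(thresholds)
  if (is.null(n_obs) || n_obs < 2L)
    stop("need at least 2 observers", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  half <- n_obs %/% 2L
  rs <- vapply(seq_len(n_splits), function(s) {
    a <- sample.int(n_obs, half)
    ma <- colMeans(thresholds[a, , drop = FALSE], na.rm = TRUE)
    mb <- colMeans(thresholds[-a, , drop = FALSE], na.rm = TRUE)
    stats::cor(ma, mb, use = "complete.obs")
  }, 0)
  list(mean_r = mean(rs), sd_r = stats::sd(rs), r = rs)
}

#' Compare two independent correlations (Fisher z test)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 sample correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must satisfy |r| < 1", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Model-vs-human threshold regression
#'
#' Ordinary least squares of model thresholds on human thresholds (human
#' thresholds as the predictor), with the Pearson correlation.
#'
#' @param human,model paired threshold vectors (NAs dropped pairwise).
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
threshold_regression <- function(human, model) {
  keep <- stats::complete.cases(human, model)
  h <- human[keep]; m <- model[keep]
  if (length(h) < 3L) stop("need at least 3 paired thresholds", call. = FALSE)
  fit <- stats::lm(m ~ h)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(h, m), n = length(h))
}
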