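#' Per-run z-normalization of response amplitudes
#'
#' Normalizes each run's amplitudes to an overall mean of 0 and standard
#' deviation of 1 (across all trials and voxels of the run).
#'
#' @param patterns a `voxel_pattern_set`.
#' @return The pattern set with `normalized = TRUE`; zero-variance runs are
#'   flagged in `attr(, "zero_variance_runs")` and left centered only.
#' @export
normalize_patterns <- function(patterns) {
  flagged <- integer(0)
  for (r in unique(patterns$run)) {
    rows <- patterns$run == r
    v <- patterns$responses[rows, , drop = FALSE]
    s <- stats::sd(as.vector(v))
    if (!is.finite(s) || s == 0) { flagged <- c(flagged, r); s <- 1 }
    patterns$responses[rows, ] <- (v - mean(v)) / s
  }
  patterns$normalized <- TRUE
  attr(patterns, "zero_variance_runs") <- flagged
  patterns
}

#' Response amplitudes from synthetic BOLD time series
#'
#' Converts each voxel's time series to percent signal change relative to
#' its run mean, then estimates each stimulus response as the average of
#' TRs 3 to 5 post-onset (1-based, onset = TR 1), and finally applies
#' per-run z-normalization.  Events too close to the run end for the full
#' window are dropped and logged.
#'
#' @param bold list of runs, each `list(series, events)` where `series` is a
#'   TR x voxel matrix and `events` has columns `onset` (TR index),
#'   `stimulus`, `condition`.
#' @param normalize apply [normalize_patterns()] afterwards.
#' @return A `voxel_pattern_set`; dropped trials in `attr(, "dropped")`.
#' @export
amplitudes_from_timeseries <- function(bold, normalize = TRUE) {
  resp <- NULL; run <- integer(0); stim <- integer(0); cond <- character(0)
  dropped <- character(0)
  for (r in seq_along(bold)) {
    series <- bold[[r]]$series; ev <- bold[[r]]$events
    mu <- colMeans(series)
    psc <- 100 * sweep(sweep(series, 2, mu), 2, mu, "/")
    for (e in seq_len(nrow(ev))) {
      win <- ev$onset[e] + 2:4  # TRs 3-5 post-onset, 1-based inclusive
      if (max(win) > nrow(series)) {
        dropped <- c(dropped, paste0("run", r, ":onset", ev$onset[e]))
        next
      }
      resp <- rbind(resp, colMeans(psc[win, , drop = FALSE]))
      run <- c(run, r); stim <- c(stim, ev$stimulus[e])
      cond <- c(cond, as.character(ev$condition[e]))
    }
  }
  out <- structure(list(responses = resp, run = run, stimulus = stim,
                        condition = cond, roi = "synthetic",
                        normalized = FALSE, bold = NULL),
                   class = "voxel_pattern_set")
  if (normalize) out <- normalize_patterns(out)
  attr(out, "dropped") <- dropped
  out
}

#' Leave-one-run-out category decoding
#'
#' Trains a linear multiclass support-vector classifier (one-vs-one,
#' default regularization) on `train_condition` trials of the held-in runs
#' and tests on `test_condition` trials of the held-out run; every run is
#' held out once.  Training always uses held-in runs only, even when train
#' and test conditions differ, so train and test responses stay independent.
#'
#' @param patterns a `voxel_pattern_set`.
#' @param categories integer vector mapping stimulus id to category; by
#'   default each stimulus is its own category (image-level decoding).
#' @param train_condition,test_condition condition labels.
#' @param cost SVM regularization constant.
#' @return List with `accuracy` (mean over folds), `fold_accuracy`,
#'   `n_folds`; folds whose training set misses a category are skipped with
#'   a warning.
#' @export
decode_category <- function(patterns, categories = NULL,
                            train_condition = "clean",
                            test_condition = train_condition, cost = 1) {
  runs <- sort(unique(patterns$run))
  if (length(runs) < 2L) stop("need at least 2 runs", call. = FALSE)
  if (is.null(categories))
    categories <- seq_len(max(patterns$stimulus))
  lab <- categories[patterns$stimulus]
  all_cats <- sort(unique(lab))
  fold_acc <- rep(NA_real_, length(runs))
  for (fi in seq_along(runs)) {
    tr <- patterns$run != runs[fi] & patterns$condition == train_condition
    te <- patterns$run == runs[fi] & patterns$condition == test_condition
    if (!any(te)) next
    if (!all(all_cats %in% lab[tr])) {
      warning("fold ", runs[fi], " skipped: training set misses a category")
      next
    }
    fit <- e1071::svm(patterns$responses[tr, , drop = FALSE],
                      factor(lab[tr], levels = all_cats),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, patterns$responses[te, , drop = FALSE])
    fold_acc[fi] <- mean(as.integer(as.character(pred)) == lab[te])
  }
  list(accuracy = mean(fold_acc, na.rm = TRUE), fold_accuracy = fold_acc,
       n_folds = sum(!is.na(fold_acc)))
}

#' Subject inclusion check from V1 decoding accuracy
#'
#' A subject is included iff decoding accuracy averaged across the three
#' viewing conditions reaches at least 20% (chance 12.5% for 8 categories);
#' a mean of exactly 0.20 is included.
#'
#' @param v1_accuracy_by_condition numeric vector of 3 condition accuracies.
#' @return Logical include flag.
#' @export
qc_subject <- function(v1_accuracy_by_condition) {
  if (length(v1_accuracy_by_condition) != 3L)
    stop("expected 3 condition accuracies", call. = FALSE)
  mean(v1_accuracy_by_condition) >= 0.20
}

#' Representational similarity matrix (pattern correlations)
#'
#' Pearson correlation between the response patterns of every pair of
#' stimuli: symmetric with unit diagonal.  Zero-variance patterns yield NA
#' entries and are flagged.
#'
#' @param patterns stimulus x feature (or voxel) matrix, one row per
#'   stimulus.
#' @param source label stored with the matrix (ROI or model layer).
#' @return An `rdm` matrix.
#' @export
build_rdm <- function(patterns, source = "patterns") {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L) stop("need at least 2 stimuli", call. = FALSE)
  m <- suppressWarnings(stats::cor(t(patterns)))
  diag(m) <- 1
  flagged <- which(apply(patterns, 1, stats::sd) == 0)
  structure(m, class = c("rdm", "matrix", "array"), source = source,
            zero_variance = flagged)
}

#' Correlate two representational similarity matrices
#'
#' Pearson correlation over the vectorized upper triangle (main diagonal
#' excluded; by symmetry the full off-diagonal set is equivalent up to
#' duplication), plus its Fisher z-transform.
#'
#' @param rdm_a,rdm_b square matrices of equal size.
#' @return List with `r` and `z = atanh(r)`.
#' @export
rsa_compare <- function(rdm_a, rdm_b) {
  if (!all(dim(rdm_a) == dim(rdm_b)))
    stop("matrix sizes differ", call. = FALSE)
  ut <- upper.tri(rdm_a)
  r <- stats::cor(rdm_a[ut], rdm_b[ut], use = "complete.obs")
  list(r = r, z = atanh(r))
}

#' RSA profile of a model against neural patterns
#'
#' Builds the neural representational similarity matrix from (normalized)
#' voxel patterns -- averaging trials of the same stimulus across runs --
#' and correlates it with each model layer's matrix for the same stimuli.
#'
#' @param patterns a `voxel_pattern_set`.
#' @param layer_features named list: per layer, a stimulus x feature
#'   activation matrix (rows in stimulus-id order).
#' @return Data frame (layer, r, z), plus the neural `rdm` in
#'   `attr(, "neural_rdm")`.
#' @export
rsa_layer_profile <- function(patterns, layer_features) {
  if (!isTRUE(patterns$normalized)) patterns <- normalize_patterns(patterns)
  stims <- sort(unique(patterns$stimulus))
  avg <- t(vapply(stims, function(s) {
    colMeans(patterns$responses[patterns$stimulus == s, , drop = FALSE])
  }, numeric(ncol(patterns$responses))))
  neural <- build_rdm(avg, source = patterns$roi)
  res <- data.frame(layer = names(layer_features), r = NA_real_,
                    z = NA_real_)
  for (i in seq_along(layer_features)) {
    cmp <- rsa_compare(neural, build_rdm(layer_features[[i]],
                                         source = res$layer[i]))
    res$r[i] <- cmp$r; res$z[i] <- cmp$z
  }
  attr(res, "neural_rdm") <- neural
  res
}

#' Group-level layer profile of RSA correlations
#'
#' Fisher z-transforms per-subject correlations and runs a two-sided
#' one-sample t test per layer (or a paired test against a second matrix),
#' flagging layers at `p < alpha` uncorrected.
#'
#' @param per_subject_r subject x layer matrix of correlations.
#' @param alpha significance level (uncorrected).
#' @param paired_with optional second subject x layer matrix; if given, a
#'   paired test of the z difference is run per layer.
#' @return Data frame (layer, mean_r, t, p, significant, zero_variance).
#' @export
group_layer_profile <- function(per_subject_r, alpha = 0.01,
                                paired_with = NULL) {
  if (nrow(per_subject_r) < 2L) stop("need >= 2 subjects", call. = FALSE)
  L <- ncol(per_subject_r)
  nm <- colnames(per_subject_r) %||% paste0("layer", seq_len(L))
  out <- data.frame(layer = nm, mean_r = NA_real_, t = NA_real_,
                    p = NA_real_, significant = FALSE,
                    zero_variance = FALSE)
  for (j in seq_len(L)) {
    z <- atanh(per_subject_r[, j])
    if (!is.null(paired_with)) z <- z - atanh(paired_with[, j])
    out$mean_r[j] <- mean(per_subject_r[, j])
    if (stats::sd(z) == 0) {
      out$zero_variance[j] <- TRUE
      out$t[j] <- if (mean(z) == 0) 0 else NA_real_
      next
    }
    tt <- stats::t.test(z)
    out$t[j] <- unname(tt$statistic); out$p[j] <- tt$p.value
    out$significant[j] <- tt$p.value < alpha
  }
  out
}
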