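# Layer-wise relevance propagation (LRP).
#
# Relevance entering a unit j is redistributed to its inputs i in proportion
# to the contributions x_i * w_ij, i.e. R_i = sum_j (x_i w_ij / z_j) R_j with
# z_j = sum_i x_i w_ij (+ bias).  Rule variants stabilize or constrain the
# redistribution: epsilon adds a sign-matched stabilizer to z_j, gamma boosts
# positive weights (w + gamma*max(w, 0)), and z-beta bounds the input layer
# by the feasible intensity range.  Biases enter the denominator but receive
# no back-distributed relevance, so conservation is exact only on bias-free
# networks.

sign_pos <- function(z) ifelse(z >= 0, 1, -1)

safe_div <- function(a, b) ifelse(b == 0, 0, a / b)

rho_weights <- function(W, rule, gamma) {
  if (rule == "gamma") W + gamma * pmax(W, 0) else W
}

#' Relevance propagation through one fully connected layer
#'
#' Low-level rule application, useful for toy networks and oracles:
#' redistributes output relevances `R` to the inputs `x` of a dense layer.
#'
#' @param x input activation vector.
#' @param W weight matrix (inputs x outputs).
#' @param b bias vector (enters the denominator only).
#' @param R relevance of the output units.
#' @param rule one of `"basic"`, `"epsilon"`, `"gamma"`, `"zbeta"`.
#' @param epsilon,gamma rule parameters.
#' @param bounds length-2 feasible input range `(l, h)` for `"zbeta"`.
#' @return Relevance of the input units.
#' @export
lrp_fc <- function(x, W, b, R, rule = "basic", epsilon = 0.25, gamma = 0.05,
                   bounds = c(-1, 1)) {
  if (rule == "zbeta") {
    Wp <- pmax(W, 0); Wm <- pmin(W, 0)
    z <- drop(crossprod(W, x)) + b -
      bounds[1] * colSums(Wp) - bounds[2] * colSums(Wm)
    s <- safe_div(R, z)
    return(x * drop(W %*% s) - bounds[1] * drop(Wp %*% s) -
             bounds[2] * drop(Wm %*% s))
  }
  Wr <- rho_weights(W, rule, gamma)
  br <- if (rule == "gamma") b + gamma * pmax(b, 0) else b
  z <- drop(crossprod(Wr, x)) + br
  if (rule == "epsilon") z <- z + epsilon * sign_pos(z)
  s <- safe_div(R, z)
  x * drop(Wr %*% s)
}

# relevance propagation through one convolution layer, via the cached
# im2col matrix; R_out is (positions x C_out)
lrp_conv <- function(cache, W, b, R_out, rule, epsilon, gamma, bounds) {
  g <- cache$g
  if (rule == "zbeta") {
    Wp <- pmax(W, 0); Wm <- pmin(W, 0)
    z <- add_bias_rows(cache$cols %*% W,
                       b - bounds[1] * colSums(Wp) - bounds[2] * colSums(Wm))
    s <- safe_div(R_out, z)
    return(cache$input * conv_bwd_data(s, W, g) -
             bounds[1] * conv_bwd_data(s, Wp, g) -
             bounds[2] * conv_bwd_data(s, Wm, g))
  }
  Wr <- rho_weights(W, rule, gamma)
  br <- if (rule == "gamma") b + gamma * pmax(b, 0) else b
  z <- add_bias_rows(cache$cols %*% Wr, br)
  if (rule == "epsilon") z <- z + epsilon * sign_pos(z)
  s <- safe_div(R_out, z)
  cache$input * conv_bwd_data(s, Wr, g)
}

#' Composite LRP rule schedule for a model
#'
#' Assigns one propagation rule to each weight-bearing layer by fractional
#' depth, mirroring the composite recipe used for 19-layer networks: the
#' input layer gets z-beta; of the remaining layers, the first ~40% get
#' gamma, the next ~35% epsilon, and the final ~25% the basic rule.  For a
#' 19-layer network this reproduces the canonical assignment exactly
#' (z-beta on layer 1, gamma on 2--8, epsilon with 0.25 on 9--14, basic on
#' 15--19).
#'
#' The z-beta bounds default to the model's own standardized input range,
#' `(0 - input_mean) / input_scale` to `(255 - input_mean) / input_scale`;
#' pass `zbeta_bounds` to override.
#'
#' @param model a `vision_model`.
#' @param preset `"composite"` or `"basic"` (basic rule everywhere;
#'   conservation is exact on bias-free networks).
#' @param epsilon,gamma rule parameters.
#' @param zbeta_bounds optional length-2 feasible input range.
#' @return An `lrp_schedule` data frame (layer, rule, parameters).
#' @export
lrp_schedule <- function(model, preset = c("composite", "basic"),
                         epsilon = 0.25, gamma = 0.05, zbeta_bounds = NULL) {
  preset <- match.arg(preset)
  nm <- vapply(model$layers, function(l) l$name, "")
  tp <- vapply(model$layers, function(l) l$type, "")
  wl <- nm[tp %in% c("conv", "fc")]
  n <- length(wl)
  if (is.null(zbeta_bounds))
    zbeta_bounds <- c((0 - model$input_mean) / model$input_scale,
                      (255 - model$input_mean) / model$input_scale)
  rule <- rep("basic", n)
  if (preset == "composite" && n >= 3L) {
    rule[1L] <- "zbeta"
    rest <- n - 1L
    n_gamma <- round(0.389 * rest)
    n_eps <- round(0.333 * rest)
    if (n_gamma > 0) rule[1L + seq_len(n_gamma)] <- "gamma"
    if (n_eps > 0) rule[1L + n_gamma + seq_len(n_eps)] <- "epsilon"
  }
  d <- data.frame(layer = wl, rule = rule, epsilon = epsilon, gamma = gamma,
                  lower = zbeta_bounds[1], upper = zbeta_bounds[2])
  class(d) <- c("lrp_schedule", class(d))
  d
}

#' Pixel-wise relevance map by layer-wise relevance propagation
#'
#' Seeds relevance at the output unit of `target_class` (with its softmax
#' score) and propagates it back through every layer using the per-layer
#' rule of `schedule`: through max-pooling relevance follows the pooling
#' winner, through rectification it passes unchanged.  At the input,
#' negative relevances are zeroed and the map is rescaled to \[0, 1\] (this
#' final rescaling makes the map invariant to positive rescaling of the
#' seed).  The raw signed input relevances are kept in `attr(, "raw")`.
#'
#' @param model a `vision_model`.
#' @param image a `gray_image` matching the model canvas.
#' @param target_class category whose evidence is attributed (1-based).
#' @param schedule an [lrp_schedule()]; default composite.
#' @param seed_relevance optional relevance value to seed at the target unit
#'   instead of its softmax score; the final map is invariant to positive
#'   rescaling of this seed.
#' @return A `relevance_map`: matrix in \[0, 1\] with attributes `raw`
#'   (pre-rescale signed relevances), `target`, and `all_zero` flag.
#' @export
lrp <- function(model, image, target_class, schedule = NULL,
                seed_relevance = NULL) {
  if (target_class < 1L || target_class > model$n_classes)
    stop("`target_class` out of range", call. = FALSE)
  if (is.null(schedule)) schedule <- lrp_schedule(model)
  fw <- cnn_forward(model, image, keep = TRUE)
  R <- numeric(model$n_classes)
  R[target_class] <- seed_relevance %||% fw$probs[target_class]
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- fw$caches[[li]]
    if (ly$type == "pool") {
      Rn <- numeric(cc$g$in_len)
      Rn[cc$win_idx] <- as.vector(R)
      R <- array(Rn, cc$in_dim)
    } else {
      row <- schedule[schedule$layer == ly$name, ]
      if (nrow(row) != 1L)
        stop("schedule is missing a rule for layer '", ly$name, "'",
             call. = FALSE)
      if (ly$type == "fc") {
        Rv <- lrp_fc(cc$v, ly$W, ly$b, as.vector(R), rule = row$rule,
                     epsilon = row$epsilon, gamma = row$gamma,
                     bounds = c(row$lower, row$upper))
        R <- array(Rv, cc$in_dim)
      } else {
        Rmat <- matrix(as.vector(R), ncol = ly$cout)
        R <- lrp_conv(cc, ly$W, ly$b, Rmat, rule = row$rule,
                      epsilon = row$epsilon, gamma = row$gamma,
                      bounds = c(row$lower, row$upper))
      }
    }
  }
  raw <- matrix(as.vector(R), model$canvas, model$canvas)
  m <- pmax(raw, 0)
  all_zero <- max(m) == 0
  if (!all_zero) m <- m / max(m)
  structure(m, class = c("relevance_map", "matrix", "array"), raw = raw,
            target = target_class, all_zero = all_zero,
            schedule = schedule)
}

#' Gaussian smoothing of a relevance map
#'
#' Blurs with a normalized Gaussian kernel (replicate boundary padding, so
#' mass is conserved up to edge effects), then rescales back to \[0, 1\].
#' Used to thicken model maps before comparison with maps painted by a
#' thick pen.
#'
#' @param map a `relevance_map` or numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @param renormalize rescale the result to \[0, 1\].
#' @return A matrix (a `relevance_map` if renormalized).
#' @export
smooth_map <- function(map, sigma = 3, renormalize = TRUE) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  max_size <- min(dim(as.matrix(map))) - 1L  # kernel must fit inside the map
  size <- min(size, 2L * (max_size %/% 2L) + 1L)
  br <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  br <- br / sum(br)
  sm <- as.matrix(EBImage::filter2(unclass(as.matrix(map)), br,
                                   boundary = "replicate"))
  if (!renormalize) return(sm)
  rng <- range(sm)
  if (diff(rng) > 0) sm <- (sm - rng[1]) / diff(rng)
  structure(sm, class = c("relevance_map", "matrix", "array"))
}

#' Binarize a map at a threshold
#' @param map numeric matrix on a 0--1 scale.
#' @param threshold threshold in (0, 1); pixels `>= threshold` become TRUE.
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  unclass(as.matrix(map)) >= threshold
}

#' Overlap (intersection-over-union) ratio of two masks
#'
#' Area of the intersection divided by the area of the union.  Two empty
#' masks give 0, flagged via `attr(, "empty")`.
#'
#' @param mask_a,mask_b logical matrices of equal dimensions.
#' @return Scalar in \[0, 1\].
#' @export
overlap_ratio <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask dimensions differ", call. = FALSE)
  uni <- sum(mask_a | mask_b)
  if (uni == 0L) return(structure(0, empty = TRUE))
  sum(mask_a & mask_b) / uni
}

#' Compare model relevance maps with human diagnostic maps across SSNR
#'
#' For each of `n_bins` bins, samples (without replacement within bin) one
#' image per category, and computes at every SSNR level the mean spatial
#' Pearson correlation and the mean overlap ratio between the human map and
#' the (Gaussian-smoothed) model map of the sampled images.  Human maps are
#' binarized at 0.5 and model maps at 0.2; only the model maps are
#' smoothed, since human maps are already pen-thickened.  Reports mean and
#' SD over bins, per level.
#'
#' @param human_maps list of human maps keyed by image id (character).
#' @param model_maps list keyed by level (character, e.g. `"0.3"`), each a
#'   list of model maps keyed by image id.
#' @param labels named integer vector: category of each image id.
#' @param n_bins number of sampling bins.
#' @param seed sampling seed.
#' @param smooth_sigma SD of the Gaussian applied to model maps.
#' @param human_threshold,model_threshold binarization thresholds.
#' @return Data frame (level, mean_r, sd_r, mean_overlap, sd_overlap);
#'   skipped image-level pairs are listed in `attr(, "skipped")`.
#' @export
diagnostic_comparison <- function(human_maps, model_maps, labels,
                                  n_bins = 50L, seed = 1L, smooth_sigma = 3,
                                  human_threshold = 0.5,
                                  model_threshold = 0.2) {
  levels <- names(model_maps)
  ids <- names(human_maps)
  labels <- labels[ids]
  cats <- sort(unique(labels))
  skipped <- character(0)
  smoothed <- lapply(model_maps, function(lv) {
    out <- lapply(lv, smooth_map, sigma = smooth_sigma)
    names(out) <- names(lv)
    out
  })
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  bin_r <- matrix(NA_real_, n_bins, length(levels))
  bin_ov <- matrix(NA_real_, n_bins, length(levels))
  for (b in seq_len(n_bins)) {
    pick <- vapply(cats, function(k) {
      pool <- ids[labels == k]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, "")
    for (li in seq_along(levels)) {
      rs <- c(); ovs <- c()
      for (id in pick) {
        mm <- smoothed[[levels[li]]][[id]]
        if (is.null(mm)) {
          skipped <- c(skipped, paste(levels[li], id, sep = ":"))
          next
        }
        hm <- as.matrix(human_maps[[id]])
        rs <- c(rs, suppressWarnings(stats::cor(as.vector(hm),
                                                as.vector(mm))))
        ovs <- c(ovs, overlap_ratio(binarize(hm, human_threshold),
                                    binarize(mm, model_threshold)))
      }
      bin_r[b, li] <- mean(rs, na.rm = TRUE)
      bin_ov[b, li] <- mean(ovs, na.rm = TRUE)
    }
  }
  out <- data.frame(level = as.numeric(levels),
                    mean_r = colMeans(bin_r, na.rm = TRUE),
                    sd_r = apply(bin_r, 2, stats::sd, na.rm = TRUE),
                    mean_overlap = colMeans(bin_ov, na.rm = TRUE),
                    sd_overlap = apply(bin_ov, 2, stats::sd, na.rm = TRUE))
  attr(out, "skipped") <- unique(skipped)
  out
}
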