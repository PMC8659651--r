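# Compact convolutional-network engine.
#
# The package needs full access to every layer's weights, pre-activations and
# pooling winners (for layer-wise susceptibility analysis and relevance
# propagation), so the network is implemented directly on base R matrix
# algebra: convolutions run as im2col + GEMM, training is plain stochastic
# gradient descent with momentum and weight decay.
#
# Conventions: activations are arrays of dim (height, width, channels);
# convolution kernels are stored as a matrix of dim (k*k*C_in, C_out) whose
# row order matches the column-major layout of an array(k, k, C_in).

.geom_cache <- new.env(parent = emptyenv())

# im2col index map for stride-1 "same" convolution
conv_geometry <- function(h, w, C, k, pad) {
  key <- paste(h, w, C, k, pad, sep = "x")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- h + 2L * pad; Wp <- w + 2L * pad
  pi <- rep(seq_len(h), times = w)       # output row
  pj <- rep(seq_len(w), each = h)        # output col
  k2c <- k * k * C
  idx <- matrix(0L, h * w, k2c)
  col <- 0L
  for (ch in seq_len(C)) for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    col <- col + 1L
    idx[, col] <- (pi + dr) + (pj + dc - 1L) * Hp + (ch - 1L) * Hp * Wp
  }
  # interior mask of the padded array, to crop gradients back
  inner <- array(FALSE, c(Hp, Wp, C))
  inner[pad + seq_len(h), pad + seq_len(w), ] <- TRUE
  g <- list(h = h, w = w, C = C, k = k, pad = pad, Hp = Hp, Wp = Wp,
            idx = idx, idxvec = as.vector(idx), inner = which(inner))
  .geom_cache[[key]] <- g
  g
}

pad_input <- function(x, g) {
  xp <- array(0, c(g$Hp, g$Wp, g$C))
  xp[g$pad + seq_len(g$h), g$pad + seq_len(g$w), ] <- x
  xp
}

im2col <- function(x, g) {
  xp <- pad_input(x, g)
  matrix(xp[g$idx], nrow = g$h * g$w)
}

# scatter-add column gradients back to input positions (transposed conv);
# reference implementation, kept as the oracle for conv_bwd_data
col2im <- function(dcols, g) {
  rs <- rowsum(as.vector(dcols), group = g$idxvec)
  dxp <- numeric(g$Hp * g$Wp * g$C)
  dxp[as.integer(rownames(rs))] <- rs
  array(dxp[g$inner], c(g$h, g$w, g$C))
}

# transposed stride-1 same convolution: routes per-position output gradients
# (or relevances) back to the input grid.  Equivalent to col2im(dmat %*%
# t(Wmat)) but runs as a same-convolution with the 180-degree-rotated kernel,
# reusing the im2col + GEMM path.
conv_bwd_data <- function(dmat, Wmat, g) {
  k <- g$k; cin <- g$C; cout <- ncol(dmat)
  arr <- array(Wmat, c(k, k, cin, cout))[k:1, k:1, , , drop = FALSE]
  wrot <- matrix(aperm(arr, c(1, 2, 4, 3)), k * k * cout, cin)
  gd <- conv_geometry(g$h, g$w, cout, k, g$pad)
  array(im2col(array(dmat, c(g$h, g$w, cout)), gd) %*% wrot,
        c(g$h, g$w, cin))
}

add_bias_rows <- function(z, b) z + matrix(b, nrow(z), length(b), byrow = TRUE)

# 2x2 max pooling, stride 2; returns pooled array + linear winner indices
pool_geometry <- function(h, w, C) {
  key <- paste("pool", h, w, C, sep = "x")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  ho <- h %/% 2L; wo <- w %/% 2L
  oi <- rep(seq_len(ho), times = wo * C)
  oj <- rep(rep(seq_len(wo), each = ho), times = C)
  ch <- rep(seq_len(C), each = ho * wo)
  base <- function(dr, dc) (2L * oi - 1L + dr) + (2L * oj - 1L + dc - 1L) * h +
    (ch - 1L) * h * w
  cand <- cbind(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L))
  g <- list(ho = ho, wo = wo, C = C, cand = cand, in_len = h * w * C)
  .geom_cache[[key]] <- g
  g
}

max_pool <- function(x, g) {
  m <- matrix(x[g$cand], nrow(g$cand), 4L)
  win <- max.col(m, ties.method = "first")
  widx <- g$cand[cbind(seq_len(nrow(m)), win)]
  list(out = array(x[widx], c(g$ho, g$wo, g$C)), win_idx = widx)
}

#' Construct a compact convolutional network
#'
#' A "SmallCNN": `length(channels)` convolution blocks (3x3 convolution,
#' rectification, 2x2 max pooling) followed by one rectified fully connected
#' layer and a fully connected softmax output over `n_classes` categories.
#' The taxonomy mirrors large feedforward vision networks (convolutional
#' layers after rectification, fully connected layers, softmax output) at a
#' size that trains in minutes on a CPU.
#'
#' Inputs on the 0--255 intensity scale are standardized internally as
#' `(x - input_mean) / input_scale`; `input_mean` is re-estimated from the
#' training stream by [train_model()] (the mean-subtraction constant is
#' computed once and frozen for evaluation).
#'
#' @param n_classes number of output categories (K).
#' @param canvas input side length in pixels (square input).
#' @param channels integer vector of convolution output channels, one per block.
#' @param fc_units width of the penultimate fully connected layer.
#' @param seed seed for He-style weight initialization.
#' @return An object of class `vision_model`.
#' @export
small_cnn <- function(n_classes, canvas = 64L, channels = c(8L, 16L, 16L, 32L),
                      fc_units = 64L, seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (canvas %% 2^length(channels) != 0L)
    stop("`canvas` must be divisible by 2^number of blocks", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  k <- 3L
  layers <- list()
  cin <- 1L; side <- as.integer(canvas)
  for (i in seq_along(channels)) {
    cout <- channels[i]
    fan_in <- k * k * cin
    W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
    layers[[length(layers) + 1L]] <- list(
      type = "conv", name = paste0("conv", i), W = W, b = numeric(cout),
      k = k, pad = 1L, cin = cin, cout = cout)
    layers[[length(layers) + 1L]] <- list(type = "pool",
                                          name = paste0("pool", i))
    cin <- cout; side <- side %/% 2L
  }
  n_flat <- side * side * cin
  W1 <- matrix(stats::rnorm(n_flat * fc_units, sd = sqrt(2 / n_flat)),
               n_flat, fc_units)
  layers[[length(layers) + 1L]] <- list(type = "fc", name = "fc1", W = W1,
                                        b = numeric(fc_units),
                                        activation = "relu")
  W2 <- matrix(stats::rnorm(fc_units * n_classes, sd = sqrt(1 / fc_units)),
               fc_units, n_classes)
  layers[[length(layers) + 1L]] <- list(type = "fc", name = "fc_out", W = W2,
                                        b = numeric(n_classes),
                                        activation = "linear")
  structure(list(layers = layers, canvas = as.integer(canvas),
                 n_classes = as.integer(n_classes),
                 input_mean = 127.5, input_scale = 127.5,
                 train_log = NULL, seed = seed),
            class = "vision_model")
}

#' @export
print.vision_model <- function(x, ...) {
  nm <- vapply(x$layers, `[[`, "", "name")
  cat(sprintf("<vision_model: %d classes, canvas %d, layers: %s>\n",
              x$n_classes, x$canvas, paste(nm, collapse = " ")))
  invisible(x)
}

#' Names of the analyzed layers of a model
#'
#' The layers entering layer-wise analyses: each convolutional layer after
#' rectification, the rectified fully connected layer(s), and the softmax
#' output.  Pooling stages are traversal details, not analyzed layers.
#'
#' @param model a `vision_model`.
#' @return Character vector of layer names, ordered by depth.
#' @export
analysis_layers <- function(model) {
  nm <- vapply(model$layers, `[[`, "", "name")
  tp <- vapply(model$layers, `[[`, "", "type")
  keep <- nm[tp %in% c("conv", "fc")]
  keep[keep == "fc_out"] <- "softmax"
  keep
}

# forward pass; keep = TRUE also returns per-layer caches for backprop / LRP
cnn_forward <- function(model, img, keep = FALSE) {
  x <- (as.matrix(unclass(img)) - model$input_mean) / model$input_scale
  if (!identical(dim(x), c(model$canvas, model$canvas)))
    stop("image dimensions do not match the model canvas", call. = FALSE)
  cur <- array(x, c(model$canvas, model$canvas, 1L))
  caches <- if (keep) vector("list", length(model$layers)) else NULL
  acts <- if (keep) list() else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      d <- dim(cur)
      g <- conv_geometry(d[1L], d[2L], d[3L], ly$k, ly$pad)
      cols <- im2col(cur, g)
      z <- add_bias_rows(cols %*% ly$W, ly$b)
      a <- z; a[a < 0] <- 0
      if (keep) {
        caches[[li]] <- list(input = cur, cols = cols, zpos = z > 0, g = g)
        acts[[ly$name]] <- as.vector(a)
      }
      cur <- array(a, c(d[1L], d[2L], ly$cout))
    } else if (ly$type == "pool") {
      d <- dim(cur)
      g <- pool_geometry(d[1L], d[2L], d[3L])
      p <- max_pool(cur, g)
      if (keep) caches[[li]] <- list(win_idx = p$win_idx, in_dim = d, g = g)
      cur <- p$out
    } else {  # fc
      v <- as.vector(cur)
      z <- drop(crossprod(ly$W, v)) + ly$b
      a <- if (ly$activation == "relu") pmax(z, 0) else z
      if (keep) {
        caches[[li]] <- list(v = v, zpos = z > 0,
                             in_dim = dim(cur) %||% length(cur))
        if (ly$activation == "relu") acts[[ly$name]] <- a
      }
      cur <- a
    }
  }
  logits <- cur
  pm <- exp(logits - max(logits))
  probs <- pm / sum(pm)
  if (keep) acts[["softmax"]] <- probs
  list(probs = probs, logits = logits, caches = caches, acts = acts)
}

# gradients of the multinomial logistic loss w.r.t. all parameters
cnn_backward <- function(model, fw, label) {
  K <- model$n_classes
  grad_out <- fw$probs
  grad_out[label] <- grad_out[label] - 1
  grads <- vector("list", length(model$layers))
  d <- grad_out  # gradient w.r.t. current layer output (post-activation)
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- fw$caches[[li]]
    if (ly$type == "fc") {
      dz <- if (ly$activation == "relu") d * cc$zpos else d
      grads[[li]] <- list(W = cc$v %o% dz, b = dz)
      d <- array(drop(ly$W %*% dz), cc$in_dim)
    } else if (ly$type == "pool") {
      dn <- numeric(cc$g$in_len)
      dn[cc$win_idx] <- as.vector(d)
      d <- array(dn, cc$in_dim)
    } else {  # conv
      dmat <- matrix(as.vector(d), ncol = ly$cout)
      dz <- dmat * cc$zpos
      grads[[li]] <- list(W = crossprod(cc$cols, dz), b = colSums(dz))
      d <- conv_bwd_data(dz, ly$W, cc$g)
    }
  }
  grads
}

# classify a single image (0-255 scale); returns the softmax vector
#' Softmax response of a model to an image
#'
#' @param model a `vision_model`.
#' @param img a `gray_image` matching the model canvas.
#' @return Numeric vector of K class probabilities (sums to 1).
#' @export
predict_proba <- function(model, img) cnn_forward(model, img)$probs

#' @rdname predict_proba
#' @return `predict_class()` returns the index (1-based) of the most probable
#'   category.
#' @export
predict_class <- function(model, img) which.max(predict_proba(model, img))

# momentum SGD update in place; weight decay on weights only
sgd_update <- function(model, grads, state, lr, momentum, weight_decay,
                       batch_size) {
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    gw <- g$W / batch_size + weight_decay * model$layers[[li]]$W
    gb <- g$b / batch_size
    state[[li]]$W <- momentum * state[[li]]$W - lr * gw
    state[[li]]$b <- momentum * state[[li]]$b - lr * gb
    model$layers[[li]]$W <- model$layers[[li]]$W + state[[li]]$W
    model$layers[[li]]$b <- model$layers[[li]]$b + state[[li]]$b
  }
  list(model = model, state = state)
}

#' Extract a layer's weights as a units-by-inputs matrix
#'
#' Convolution kernels are reshaped so each row is one output unit's
#' flattened incoming weights; fully connected weights are transposed to the
#' same orientation.
#'
#' @param model a `vision_model`.
#' @param layer layer name (e.g. `"conv2"`, `"fc1"`).
#' @return Numeric matrix, units x incoming weights.
#' @export
layer_weights <- function(model, layer) {
  nm <- vapply(model$layers, function(l) l$name, "")
  i <- match(layer, nm)
  if (is.na(i)) stop("no layer named '", layer, "'", call. = FALSE)
  t(model$layers[[i]]$W)
}
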