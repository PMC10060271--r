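# Compact encoder-decoder semantic-segmentation network, written with
# plain matrix algebra. Images are stored as (H*W) x C matrices with
# column-major pixel indexing; convolutions use im2col so every layer is
# a single BLAS product. One encoder level (3x3 conv -> 2x2 mean pool ->
# 3x3 conv), nearest-neighbour upsampling, a skip concatenation with the
# encoder features, and a 3x3 + 1x1 head ending in a per-pixel sigmoid.

# 3x3 neighbourhood indices with zero padding: (H*W) x 9, 0 = outside.
conv_index <- function(h, w) {
  p <- seq_len(h * w)
  row <- (p - 1L) %% h + 1L
  col <- (p - 1L) %/% h + 1L
  idx <- matrix(0L, h * w, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- row + dr; c2 <- col + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    idx[ok, k] <- r2[ok] + (c2[ok] - 1L) * h
  }
  idx
}

im2col <- function(x, idx) {
  c_in <- ncol(x)
  out <- matrix(0, nrow(idx), 9L * c_in)
  for (k in 1:9) {
    ok <- idx[, k] > 0L
    out[ok, ((k - 1L) * c_in + 1L):(k * c_in)] <- x[idx[ok, k], , drop = FALSE]
  }
  out
}

col2im <- function(dcols, idx, c_in) {
  dx <- matrix(0, nrow(idx), c_in)
  for (k in 1:9) {
    ok <- idx[, k] > 0L
    tgt <- idx[ok, k]
    dx[tgt, ] <- dx[tgt, ] +
      dcols[ok, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
  }
  dx
}

# 2x2 mean-pool source indices: (h/2*w/2) x 4.
pool_index <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  q <- seq_len(h2 * w2)
  r2 <- (q - 1L) %% h2 + 1L
  c2 <- (q - 1L) %/% h2 + 1L
  r <- 2L * r2 - 1L; cc <- 2L * c2 - 1L
  cbind(r + (cc - 1L) * h, r + 1L + (cc - 1L) * h,
        r + cc * h, r + 1L + cc * h)
}

# For each fine pixel, its coarse source pixel (nearest-neighbour upsample).
upsample_index <- function(h, w) {
  h2 <- h %/% 2L
  p <- seq_len(h * w)
  row <- (p - 1L) %% h + 1L
  col <- (p - 1L) %/% h + 1L
  (row + 1L) %/% 2L + ((col + 1L) %/% 2L - 1L) * h2
}

fcn_geometry <- function(h, w) {
  list(h = h, w = w,
       idx1 = conv_index(h, w),
       idx2 = conv_index(h %/% 2L, w %/% 2L),
       pool = pool_index(h, w),
       up = upsample_index(h, w))
}

fcn_init <- function(channels, seed) {
  set.seed(seed)
  c1 <- channels[1]; c2 <- channels[2]
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  list(W1 = he(9, c1),            b1 = numeric(c1),
       W2 = he(9 * c1, c2),       b2 = numeric(c2),
       W3 = he(9 * (c1 + c2), c1), b3 = numeric(c1),
       W4 = he(c1, 1),            b4 = numeric(1))
}

fcn_forward <- function(wts, x, geom) {
  cols1 <- im2col(x, geom$idx1)
  a1 <- pmax(sweep(cols1 %*% wts$W1, 2, wts$b1, `+`), 0)      # H*W x c1
  p1 <- (a1[geom$pool[, 1], ] + a1[geom$pool[, 2], ] +
           a1[geom$pool[, 3], ] + a1[geom$pool[, 4], ]) / 4    # H/2*W/2 x c1
  cols2 <- im2col(p1, geom$idx2)
  a2 <- pmax(sweep(cols2 %*% wts$W2, 2, wts$b2, `+`), 0)      # coarse x c2
  u2 <- a2[geom$up, , drop = FALSE]                            # H*W x c2
  cat3 <- cbind(a1, u2)
  cols3 <- im2col(cat3, geom$idx1)
  a3 <- pmax(sweep(cols3 %*% wts$W3, 2, wts$b3, `+`), 0)      # H*W x c1
  z <- drop(a3 %*% wts$W4) + wts$b4                            # H*W logits
  list(cols1 = cols1, a1 = a1, p1 = p1, cols2 = cols2, a2 = a2,
       cat3 = cat3, cols3 = cols3, a3 = a3, z = z,
       prob = 1 / (1 + exp(-z)))
}

fcn_backward <- function(wts, fw, x, y, geom) {
  n <- length(fw$z)
  c1 <- ncol(fw$a1); c2 <- ncol(fw$a2)
  dz <- matrix((fw$prob - y) / n, ncol = 1)                    # BCE on logits
  dW4 <- crossprod(fw$a3, dz); db4 <- sum(dz)
  da3 <- (dz %*% t(wts$W4)) * (fw$a3 > 0)
  dW3 <- crossprod(fw$cols3, da3); db3 <- colSums(da3)
  dcat3 <- col2im(da3 %*% t(wts$W3), geom$idx1, c1 + c2)
  da1 <- dcat3[, seq_len(c1), drop = FALSE]
  du2 <- dcat3[, c1 + seq_len(c2), drop = FALSE]
  da2 <- rowsum(du2, geom$up) * (fw$a2 > 0)
  dW2 <- crossprod(fw$cols2, da2); db2 <- colSums(da2)
  dp1 <- col2im(da2 %*% t(wts$W2), geom$idx2, c1)
  for (k in 1:4) da1[geom$pool[, k], ] <-
    da1[geom$pool[, k], ] + dp1 / 4
  da1 <- da1 * (fw$a1 > 0)
  dW1 <- crossprod(fw$cols1, da1); db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

adam_step <- function(state, wts, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(wts)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, wts = wts)
}

fcn_normalize <- function(bf) {
  s <- stats::sd(bf)
  if (s == 0) s <- 1
  matrix((as.vector(bf) - mean(bf)) / s, ncol = 1)
}

#' Train the semantic-segmentation network
#'
#' Trains the compact encoder-decoder on (brightfield, label-mask) pairs,
#' mirroring the methodology in which fluorescence-derived masks serve as
#' the per-pixel binary ground truth. Optimization is per-image Adam on a
#' binary cross-entropy loss; given a fixed `seed` the result is
#' deterministic.
#'
#' @param pairs non-empty list; each element a list with `bf` (matrix)
#'   and `mask` (a [labeled_mask()] or binary matrix). All rasters must
#'   share one even-sided size.
#' @param hyper training settings: `epochs` (default 10), `lr` (default
#'   0.005), `seed` (default 1), `channels` (encoder widths, default
#'   `c(8, 16)`).
#' @return A `seg_model`: `weights`, `channels`, `input_spec` (size and
#'   normalization) and `training_meta` (epochs, lr, seed and the mean
#'   training loss per epoch).
#' @export
train_seg_model <- function(pairs, hyper = list()) {
  if (!length(pairs)) stop("need at least one training pair", call. = FALSE)
  epochs <- hyper$epochs %||% 10L
  lr <- hyper$lr %||% 0.005
  seed <- hyper$seed %||% 1L
  channels <- hyper$channels %||% c(8L, 16L)
  dims <- dim(pairs[[1]]$bf)
  if (any(dims %% 2L != 0L))
    abort_field("pairs", "raster sides must be even (one 2x pooling level)")
  for (p in pairs) {
    if (!identical(dim(p$bf), dims))
      abort_field("pairs", "all rasters must share the same dimensions")
  }
  geom <- fcn_geometry(dims[1], dims[2])
  wts <- fcn_init(channels, seed)
  adam <- list(m = lapply(wts, function(w) w * 0),
               v = lapply(wts, function(w) w * 0))
  xs <- lapply(pairs, function(p) fcn_normalize(p$bf))
  ys <- lapply(pairs, function(p) as.numeric(mask_binary(p$mask)))
  loss_per_epoch <- numeric(epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(pairs))
    losses <- numeric(length(pairs))
    for (i in seq_along(ord)) {
      j <- ord[i]
      fw <- fcn_forward(wts, xs[[j]], geom)
      pcl <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      losses[i] <- -mean(ys[[j]] * log(pcl) + (1 - ys[[j]]) * log(1 - pcl))
      grads <- fcn_backward(wts, fw, xs[[j]], ys[[j]], geom)
      step <- step + 1L
      upd <- adam_step(adam, wts, grads, lr, step)
      adam <- upd$state; wts <- upd$wts
    }
    loss_per_epoch[ep] <- mean(losses)
  }
  structure(list(weights = wts, channels = channels,
                 input_spec = list(size = dims,
                                   normalization = "per-image z-score"),
                 training_meta = list(epochs = epochs, lr = lr, seed = seed,
                                      loss = loss_per_epoch)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "<seg_model> encoder-decoder (%s ch), input %dx%d, %d epochs, final loss %.4f\n",
    paste(x$channels, collapse = "/"), x$input_spec$size[1],
    x$input_spec$size[2], x$training_meta$epochs,
    utils::tail(x$training_meta$loss, 1)))
  invisible(x)
}

#' Per-pixel foreground probability from a trained model
#'
#' @param model a `seg_model` from [train_seg_model()].
#' @param bf brightfield raster conforming to the model's `input_spec`.
#' @return Matrix of foreground probabilities in `[0, 1]`.
#' @export
predict_seg_prob <- function(model, bf) {
  assert_matrix(bf, "bf")
  sz <- model$input_spec$size
  if (!identical(dim(bf), as.integer(sz)) && !identical(dim(bf), sz))
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 nrow(bf), ncol(bf), sz[1], sz[2]), call. = FALSE)
  geom <- fcn_geometry(sz[1], sz[2])
  fw <- fcn_forward(model$weights, fcn_normalize(bf), geom)
  matrix(fw$prob, sz[1], sz[2])
}

#' Network-based segmentation
#'
#' Applies the trained encoder-decoder to a brightfield raster,
#' thresholds the probability map and runs the same post-processing
#' chain as [segment_classical()] (closing, hole fill, components,
#' minimum-area filter, optional splitting).
#'
#' @inheritParams predict_seg_prob
#' @param threshold probability cut in `[0, 1]`; pixels with probability
#'   strictly above it are foreground, so `threshold = 1` yields an
#'   empty mask.
#' @param params a [seg_params()].
#' @param frame frame index recorded on the output mask.
#' @return A [labeled_mask()] with `provenance = "fcn"`.
#' @export
segment_fcn <- function(bf, model, threshold = 0.5, params = seg_params(),
                        frame = 0L) {
  prob <- predict_seg_prob(model, bf)
  labels <- postprocess_binary(prob > threshold, params)
  out <- labeled_mask(labels, frame = frame, provenance = "fcn")
  out$boundary_labels <- boundary_labels(labels)
  out
}

#' Save / load a trained segmentation model
#'
#' The weights go to a single plain-text file (one value per line, with a
#' shape header) and `input_spec`/`training_meta` to a JSON sidecar at
#' `<path>.json`.
#'
#' @param model a `seg_model`.
#' @param path weights file path.
#' @return `load_seg_model()` returns the restored `seg_model`.
#' @export
save_seg_model <- function(model, path) {
  shapes <- lapply(model$weights, function(w)
    if (is.matrix(w)) dim(w) else length(w))
  sidecar <- list(shapes = shapes, channels = model$channels,
                  input_spec = model$input_spec,
                  training_meta = model$training_meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  vals <- unlist(lapply(model$weights, as.numeric), use.names = FALSE)
  writeLines(formatC(vals, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(path))
  wts <- list()
  off <- 0L
  for (nm in names(sidecar$shapes)) {
    sh <- sidecar$shapes[[nm]]
    n <- prod(sh)
    w <- vals[(off + 1L):(off + n)]
    wts[[nm]] <- if (length(sh) == 2L) matrix(w, sh[1], sh[2]) else w
    off <- off + n
  }
  structure(list(weights = wts, channels = sidecar$channels,
                 input_spec = list(
                   size = as.integer(sidecar$input_spec$size),
                   normalization = sidecar$input_spec$normalization),
                 training_meta = sidecar$training_meta),
            class = "seg_model")
}
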