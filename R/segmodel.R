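# T-U-Net: 1D encoder-decoder with skip connections for point-wise ON/OFF
# classification of force windows, plus post-processing of the per-sample
# probabilities into continuous force-ON blocks.

#' T-U-Net configuration
#'
#' Defaults mirror the best published hyperparameters: window 224, base
#' filter size 16, learning rate 0.001, batch size 128. The window length
#' must be divisible by 2^depth (three pooling levels bring 224 down to 28
#' at the bottleneck).
#'
#' @param L Window length, samples.
#' @param channels Input channels (left/right prong = 2).
#' @param filters Base filter count; doubles at each level.
#' @param depth Number of pooling levels.
#' @param lr Learning rate (Adam).
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Early-stopping schedule.
#' @param seed Seed for initialization and batching.
#' @export
tunet_config <- function(L = 224L, channels = 2L, filters = 16L, depth = 3L,
                         lr = 1e-3, batch_size = 128L, max_epochs = 30L,
                         patience = 10L, seed = 1L) {
  cfg <- list(L = as.integer(L), channels = as.integer(channels),
              filters = as.integer(filters), depth = as.integer(depth),
              lr = lr, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$L %% 2^cfg$depth != 0)
    stop_labeled("config_error", "L=%d not divisible by 2^depth=%d",
                 cfg$L, 2^cfg$depth)
  if (cfg$filters < 4)
    stop_labeled("config_error", "filter size must be >= 4")
  structure(cfg, class = "tunet_config")
}

#' Build a T-U-Net model
#'
#' Encoder: per level two kernel-3 convolutions with batch normalization
#' and ReLU, filters doubling per level from the base size, followed by
#' width-2 max pooling. Decoder: learned x2 upsampling, concatenation with
#' the same-level encoder activation (skip connection), and two further
#' convolutions. Head: a 1-wide convolution to a per-time-point 2-class
#' softmax (OFF, ON).
#'
#' @param cfg A [tunet_config()].
#' @return Untrained model of class `tunet_model`.
#' @export
build_tunet <- function(cfg = tunet_config()) {
  with_seed(cfg$seed, {
    f <- cfg$filters
    layers <- list()
    cin <- cfg$channels
    for (i in seq_len(cfg$depth)) {
      fo <- f * 2^(i - 1)
      layers[[sprintf("enc%d_conv1", i)]] <- new_conv1d(3, cin, fo)
      layers[[sprintf("enc%d_bn1", i)]] <- new_bn(fo)
      layers[[sprintf("enc%d_conv2", i)]] <- new_conv1d(3, fo, fo)
      layers[[sprintf("enc%d_bn2", i)]] <- new_bn(fo)
      cin <- fo
    }
    fb <- f * 2^cfg$depth
    layers[["bott_conv1"]] <- new_conv1d(3, cin, fb)
    layers[["bott_bn1"]] <- new_bn(fb)
    layers[["bott_conv2"]] <- new_conv1d(3, fb, fb)
    layers[["bott_bn2"]] <- new_bn(fb)
    cin <- fb
    for (i in rev(seq_len(cfg$depth))) {
      fo <- f * 2^(i - 1)
      layers[[sprintf("up%d", i)]] <- new_upsample(cin, fo)
      layers[[sprintf("dec%d_conv1", i)]] <- new_conv1d(3, 2 * fo, fo)
      layers[[sprintf("dec%d_bn1", i)]] <- new_bn(fo)
      layers[[sprintf("dec%d_conv2", i)]] <- new_conv1d(3, fo, fo)
      layers[[sprintf("dec%d_bn2", i)]] <- new_bn(fo)
      cin <- fo
    }
    layers[["head"]] <- new_conv1d(1, cin, 2)
    structure(list(arch = "tunet", loss = "pointwise", cfg = cfg,
                   layers = layers),
              class = c("tunet_model", "nn_model"))
  })
}

conv_bn_relu_fwd <- function(layers, conv_nm, bn_nm, X, training, bn_states) {
  c1 <- conv1d_fwd(layers[[conv_nm]], X)
  b1 <- bn_fwd(layers[[bn_nm]], c1$out, training)
  if (training) bn_states[[bn_nm]] <- b1$state
  r1 <- relu_fwd(b1$out)
  list(out = r1$out, cache = list(conv = c1, bn = b1, relu = r1),
       bn_states = bn_states)
}

conv_bn_relu_bwd <- function(layers, conv_nm, bn_nm, cache, dY) {
  dr <- relu_bwd(cache$relu, dY)
  bb <- bn_bwd(layers[[bn_nm]], cache$bn, dr)
  cb <- conv1d_bwd(layers[[conv_nm]], cache$conv, bb$dX)
  list(dX = cb$dX, grads = c(prefix_grads(conv_nm, cb$grads),
                             prefix_grads(bn_nm, bb$grads)))
}

tunet_forward <- function(model, X, training = FALSE) {
  ly <- model$layers
  depth <- model$cfg$depth
  caches <- list()
  bn_states <- list()
  z <- X
  for (i in seq_len(depth)) {
    s1 <- conv_bn_relu_fwd(ly, sprintf("enc%d_conv1", i),
                           sprintf("enc%d_bn1", i), z, training, bn_states)
    bn_states <- s1$bn_states
    s2 <- conv_bn_relu_fwd(ly, sprintf("enc%d_conv2", i),
                           sprintf("enc%d_bn2", i), s1$out, training,
                           bn_states)
    bn_states <- s2$bn_states
    p <- pool2_fwd(s2$out)
    caches[[sprintf("enc%d", i)]] <- list(s1 = s1$cache, s2 = s2$cache,
                                          pool = p)
    z <- p$out
  }
  s1 <- conv_bn_relu_fwd(ly, "bott_conv1", "bott_bn1", z, training, bn_states)
  bn_states <- s1$bn_states
  s2 <- conv_bn_relu_fwd(ly, "bott_conv2", "bott_bn2", s1$out, training,
                         bn_states)
  bn_states <- s2$bn_states
  caches[["bott"]] <- list(s1 = s1$cache, s2 = s2$cache)
  z <- s2$out
  for (i in rev(seq_len(depth))) {
    up <- upsample_fwd(ly[[sprintf("up%d", i)]], z)
    skip_out <- relu_from_cache(caches[[sprintf("enc%d", i)]]$s2)
    cat_out <- abind3(skip_out, up$out)
    d1 <- conv_bn_relu_fwd(ly, sprintf("dec%d_conv1", i),
                           sprintf("dec%d_bn1", i), cat_out, training,
                           bn_states)
    bn_states <- d1$bn_states
    d2 <- conv_bn_relu_fwd(ly, sprintf("dec%d_conv2", i),
                           sprintf("dec%d_bn2", i), d1$out, training,
                           bn_states)
    bn_states <- d2$bn_states
    caches[[sprintf("dec%d", i)]] <- list(up = up, d1 = d1$cache,
                                          d2 = d2$cache,
                                          skip_ch = dim(skip_out)[3])
    z <- d2$out
  }
  head <- conv1d_fwd(ly[["head"]], z)
  caches[["head"]] <- head
  list(logits = head$out, caches = caches,
       bn_states = if (training) bn_states else NULL)
}

relu_from_cache <- function(block_cache) block_cache$relu$out

# concatenate along the channel axis
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

tunet_backward <- function(model, fw, dlogits) {
  ly <- model$layers
  depth <- model$cfg$depth
  caches <- fw$caches
  hb <- conv1d_bwd(ly[["head"]], caches[["head"]], dlogits)
  grads <- prefix_grads("head", hb$grads)
  dz <- hb$dX
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {
    cc <- caches[[sprintf("dec%d", i)]]
    b2 <- conv_bn_relu_bwd(ly, sprintf("dec%d_conv2", i),
                           sprintf("dec%d_bn2", i), cc$d2, dz)
    b1 <- conv_bn_relu_bwd(ly, sprintf("dec%d_conv1", i),
                           sprintf("dec%d_bn1", i), cc$d1, b2$dX)
    grads <- flat_grads(grads, b2$grads, b1$grads)
    sc <- cc$skip_ch
    dskip[[i]] <- b1$dX[, , seq_len(sc), drop = FALSE]
    dup <- b1$dX[, , sc + seq_len(dim(b1$dX)[3] - sc), drop = FALSE]
    ub <- upsample_bwd(ly[[sprintf("up%d", i)]], cc$up, dup)
    grads <- flat_grads(grads, prefix_grads(sprintf("up%d", i), ub$grads))
    dz <- ub$dX
  }
  b2 <- conv_bn_relu_bwd(ly, "bott_conv2", "bott_bn2", caches$bott$s2, dz)
  b1 <- conv_bn_relu_bwd(ly, "bott_conv1", "bott_bn1", caches$bott$s1, b2$dX)
  grads <- flat_grads(grads, b2$grads, b1$grads)
  dz <- b1$dX
  for (i in rev(seq_len(depth))) {
    cc <- caches[[sprintf("enc%d", i)]]
    dpool <- pool2_bwd(cc$pool, dz)
    d2 <- dpool + dskip[[i]]
    b2 <- conv_bn_relu_bwd(ly, sprintf("enc%d_conv2", i),
                           sprintf("enc%d_bn2", i), cc$s2, d2)
    b1 <- conv_bn_relu_bwd(ly, sprintf("enc%d_conv1", i),
                           sprintf("enc%d_bn1", i), cc$s1, b2$dX)
    grads <- flat_grads(grads, b2$grads, b1$grads)
    dz <- b1$dX
  }
  grads
}

#' Count trainable parameters of a model
#' @param model A built model.
#' @export
n_params <- function(model)
  sum(vapply(nn_collect_params(model$layers), length, 0L))

#' Train the T-U-Net segmenter
#'
#' Point-wise cross-entropy with Adam; early stopping restores the weights
#' of the minimum-validation-loss epoch. Deterministic per seed.
#'
#' @param model A [build_tunet()] model.
#' @param train,val `window_batch` objects (standardized, with point
#'   labels).
#' @param cfg Optional [tunet_config()] override; defaults to the model's.
#' @return Trained model; `$history` holds per-epoch train/val loss and
#'   accuracy.
#' @export
train_segmenter <- function(model, train, val = NULL, cfg = model$cfg) {
  if (is.null(train$x) || dim(train$x)[1] == 0)
    stop_labeled("empty_batch", "empty training batch")
  if (is.null(train$y))
    stop_labeled("value_error", "training windows need point labels")
  nn_train(model, train$x, train$y,
           if (!is.null(val)) val$x, if (!is.null(val)) val$y,
           lr = cfg$lr, batch_size = cfg$batch_size,
           max_epochs = cfg$max_epochs, patience = cfg$patience,
           seed = cfg$seed)
}

#' Exhaustive grid search over T-U-Net hyperparameters
#'
#' Trains one model per configuration in the grid and selects the one with
#' minimum validation loss.
#'
#' @param cfg_space Named list of vectors (e.g. `list(filters = c(8, 16),
#'   lr = c(1e-3, 1e-2))`); unnamed fields take [tunet_config()] defaults.
#' @param train,val `window_batch` objects.
#' @param base Base configuration for fields not in the grid.
#' @return List with `best` (trained model), `best_cfg`, and `leaderboard`
#'   (one row per configuration, sorted by validation loss).
#' @export
grid_search <- function(cfg_space, train, val, base = tunet_config()) {
  grid <- expand.grid(cfg_space, stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  losses <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- base
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][r]
    cfg <- do.call(tunet_config, unclass(cfg))
    m <- build_tunet(cfg)
    m <- train_segmenter(m, train, val, cfg)
    results[[r]] <- m
    losses[r] <- m$best_val_loss
  }
  lb <- cbind(grid, val_loss = losses)
  lb <- lb[order(lb$val_loss), , drop = FALSE]
  best_i <- which.min(losses)
  list(best = results[[best_i]],
       best_cfg = results[[best_i]]$cfg,
       leaderboard = lb)
}

#' Per-sample ON probability for a whole recording
#'
#' The recording (already standardized with the training standardizer) is
#' tiled into non-overlapping L-windows; a final partial window is handled
#' by edge-padding and truncating its predictions. Output length equals the
#' recording length.
#'
#' @param model Trained `tunet_model`.
#' @param rec A `force_recording` or n x 2 matrix of standardized forces.
#' @return Numeric vector of ON probabilities in [0, 1].
#' @export
predict_pointwise <- function(model, rec) {
  m <- if (inherits(rec, "force_recording"))
    cbind(rec$left_force_n, rec$right_force_n) else rec
  L <- model$cfg$L
  n <- nrow(m)
  n_full <- floor(n / L)
  pad <- n - n_full * L
  nw <- n_full + (pad > 0)
  x <- array(0, c(nw, L, 2))
  for (i in seq_len(n_full))
    x[i, , ] <- m[((i - 1) * L + 1):(i * L), ]
  if (pad > 0) {
    tail_idx <- (n_full * L + 1):n
    xt <- m[tail_idx, , drop = FALSE]
    x[nw, , ] <- rbind(xt, xt[rep(nrow(xt), L - pad), , drop = FALSE])
  }
  probs <- numeric(n)
  for (s in seq.int(1L, nw, 128L)) {
    idx <- s:min(nw, s + 127L)
    fw <- model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    d <- dim(fw$logits)
    p <- softmax_rows(matrix(fw$logits, d[1] * d[2], d[3]))[, 2]
    p <- matrix(p, d[1], d[2])
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (i <= n_full) probs[((i - 1) * L + 1):(i * L)] <- p[j, ]
      else probs[(n_full * L + 1):n] <- p[j, seq_len(pad)]
    }
  }
  probs
}

#' Extract continuous force-ON blocks from point-wise probabilities
#'
#' Binarizes at `threshold`, merges ON runs separated by OFF gaps of at
#' most `gap_tol` samples (reconciling noise-driven discontinuities), then
#' discards merged runs shorter than `min_len` samples. Returned intervals
#' are 0-based, half-open, sorted and disjoint.
#'
#' @param probabilities ON probabilities (or a 0/1 mask).
#' @param threshold Binarization threshold (default 0.5).
#' @param min_len Minimum block length, samples (default 40 = 2 s).
#' @param gap_tol Maximum OFF gap to bridge, samples (default 10 = 0.5 s).
#' @return data.frame with columns `start_idx`, `end_idx`.
#' @export
extract_segments <- function(probabilities, threshold = 0.5, min_len = 40L,
                             gap_tol = 10L) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  mask <- probabilities > threshold
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0))
  if (!any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  runs <- cbind(start = starts[on], end = ends[on])  # 1-based inclusive
  # chain-merge runs whose separating gap is <= gap_tol
  merged <- list()
  cur <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs[i, "start"] - cur["end"] - 1L
    if (gap <= gap_tol) {
      cur["end"] <- runs[i, "end"]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- runs[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  keep <- (m[, "end"] - m[, "start"] + 1L) >= min_len
  m <- m[keep, , drop = FALSE]
  data.frame(start_idx = as.integer(m[, "start"] - 1L),
             end_idx = as.integer(m[, "end"]))
}
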