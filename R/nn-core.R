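# Compact neural-network engine for 1D force time series.
#
# Tensors are numeric arrays of dim (N, L, C): batch, time, channel.
# Convolutions are computed as im2col matrix products so all heavy work
# lands in BLAS; every layer has an explicit hand-derived backward pass
# (verified against numeric gradients in the test suite). Weight layout for
# conv kernels is (C_in, k, C_out) to match im2col column ordering.
#
# Training is fully deterministic for a fixed seed (single-threaded BLAS
# assumed): initialization, batching order and all stochastic draws come
# from the R RNG.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_conv1d <- function(k, cin, cout) {
  pl <- floor((k - 1) / 2)
  list(type = "conv1d", k = k, cin = cin, cout = cout,
       pad_l = pl, pad_r = k - 1 - pl,
       W = he_init(c(cin, k, cout), k * cin),
       b = numeric(cout))
}

# X: (N, L, Cin) -> matrix (N*L, k*Cin); column order = c fastest within
# kernel-offset blocks, matching matrix(W, cin*k, cout).
im2col <- function(X, k, pad_l, pad_r) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Xp <- array(0, c(N, L + pad_l + pad_r, C))
  Xp[, pad_l + seq_len(L), ] <- X
  out <- matrix(0, N * L, k * C)
  for (j in seq_len(k)) {
    out[, (j - 1L) * C + seq_len(C)] <-
      matrix(Xp[, j:(j + L - 1L), , drop = FALSE], N * L, C)
  }
  out
}

conv1d_fwd <- function(layer, X) {
  d <- dim(X)
  Xcol <- im2col(X, layer$k, layer$pad_l, layer$pad_r)
  Y <- Xcol %*% matrix(layer$W, layer$cin * layer$k, layer$cout)
  Y <- sweep(Y, 2, layer$b, `+`)
  list(out = array(Y, c(d[1], d[2], layer$cout)), X = X)
}

conv1d_bwd <- function(layer, cache, dY) {
  d <- dim(cache$X)
  dYm <- matrix(dY, d[1] * d[2], layer$cout)
  Xcol <- im2col(cache$X, layer$k, layer$pad_l, layer$pad_r)
  dW <- array(crossprod(Xcol, dYm), dim(layer$W))
  db <- colSums(dYm)
  # dX is the "full" correlation of dY with the flipped kernel
  Wflip <- array(0, c(layer$cout, layer$k, layer$cin))
  for (j in seq_len(layer$k))
    Wflip[, layer$k + 1L - j, ] <- t(layer$W[, j, ])
  dYcol <- im2col(dY, layer$k, layer$pad_r, layer$pad_l)
  dX <- dYcol %*% matrix(Wflip, layer$cout * layer$k, layer$cin)
  list(dX = array(dX, d), grads = list(W = dW, b = db))
}

new_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

bn_fwd <- function(layer, X, training) {
  d <- dim(X); M <- d[1] * d[2]
  xm <- matrix(X, M, d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  state <- NULL
  if (training) {
    m <- layer$momentum
    state <- list(run_mean = m * layer$run_mean + (1 - m) * mu,
                  run_var = m * layer$run_var + (1 - m) * v)
  }
  list(out = array(y, d), xhat = xhat, invstd = invstd, dims = d,
       state = state)
}

bn_bwd <- function(layer, cache, dY) {
  d <- cache$dims; M <- d[1] * d[2]
  dym <- matrix(dY, M, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, layer$gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$invstd, `*`)
  list(dX = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(X) {
  m <- X > 0
  list(out = X * m, mask = m)
}
relu_bwd <- function(cache, dY) dY * cache$mask

# max-pool width 2, stride 2 (L must be even)
pool2_fwd <- function(X) {
  d <- dim(X)
  io <- seq.int(1L, d[2], 2L); ie <- io + 1L
  Xo <- X[, io, , drop = FALSE]
  Xe <- X[, ie, , drop = FALSE]
  m <- Xo >= Xe
  Y <- Xe; Y[m] <- Xo[m]
  list(out = Y, mask = m, dims = d)
}

pool2_bwd <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  io <- seq.int(1L, d[2], 2L); ie <- io + 1L
  dX[, io, ] <- dY * cache$mask
  dX[, ie, ] <- dY * !cache$mask
  dX
}

# max-pool width 3, stride 1, same length (edges padded with -Inf)
pool3_fwd <- function(X) {
  d <- dim(X); L <- d[2]
  neg <- -Inf
  Xl <- array(neg, d); Xl[, 2:L, ] <- X[, 1:(L - 1), , drop = FALSE]
  Xr <- array(neg, d); Xr[, 1:(L - 1), ] <- X[, 2:L, , drop = FALSE]
  Y <- pmax(Xl, X, Xr)
  list(out = Y, which = (Y == Xl) * 1L + (Y == X & Y != Xl) * 2L +
         (Y == Xr & Y != Xl & Y != X) * 3L, dims = d)
}

pool3_bwd <- function(cache, dY) {
  d <- cache$dims; L <- d[2]
  dX <- array(0, d)
  w <- cache$which
  mid <- dY * (w == 2L)
  dX <- dX + mid
  left_credit <- dY * (w == 1L)      # came from position l-1
  dX[, 1:(L - 1), ] <- dX[, 1:(L - 1), , drop = FALSE] +
    left_credit[, 2:L, , drop = FALSE]
  right_credit <- dY * (w == 3L)     # came from position l+1
  dX[, 2:L, ] <- dX[, 2:L, , drop = FALSE] +
    right_credit[, 1:(L - 1), , drop = FALSE]
  dX
}

# learned x2 upsampling: transposed convolution, kernel 2, stride 2
new_upsample <- function(cin, cout) {
  list(type = "upsample", cin = cin, cout = cout,
       W1 = he_init(c(cin, cout), cin), W2 = he_init(c(cin, cout), cin),
       b = numeric(cout))
}

upsample_fwd <- function(layer, X) {
  d <- dim(X)
  xm <- matrix(X, d[1] * d[2], d[3])
  Y1 <- sweep(xm %*% layer$W1, 2, layer$b, `+`)
  Y2 <- sweep(xm %*% layer$W2, 2, layer$b, `+`)
  Y <- array(0, c(d[1], 2L * d[2], layer$cout))
  Y[, seq.int(1L, 2L * d[2], 2L), ] <- array(Y1, c(d[1], d[2], layer$cout))
  Y[, seq.int(2L, 2L * d[2], 2L), ] <- array(Y2, c(d[1], d[2], layer$cout))
  list(out = Y, X = X, dims = d)
}

upsample_bwd <- function(layer, cache, dY) {
  d <- cache$dims
  dY1 <- matrix(dY[, seq.int(1L, 2L * d[2], 2L), , drop = FALSE],
                d[1] * d[2], layer$cout)
  dY2 <- matrix(dY[, seq.int(2L, 2L * d[2], 2L), , drop = FALSE],
                d[1] * d[2], layer$cout)
  xm <- matrix(cache$X, d[1] * d[2], d[3])
  list(dX = array(dY1 %*% t(layer$W1) + dY2 %*% t(layer$W2), d),
       grads = list(W1 = crossprod(xm, dY1), W2 = crossprod(xm, dY2),
                    b = colSums(dY1) + colSums(dY2)))
}

new_dense <- function(din, dout) {
  list(type = "dense", din = din, dout = dout,
       W = he_init(c(din, dout), din), b = numeric(dout))
}

dense_fwd <- function(layer, X) {
  list(out = sweep(X %*% layer$W, 2, layer$b, `+`), X = X)
}

dense_bwd <- function(layer, cache, dY) {
  list(dX = dY %*% t(layer$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

# global average pooling over time: (N, L, C) -> (N, C)
gap_fwd <- function(X) {
  d <- dim(X)
  list(out = apply(X, c(1, 3), mean), dims = d)
}

gap_bwd <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  for (l in seq_len(d[2])) dX[, l, ] <- dY / d[2]
  dX
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy over rows of logits vs one-hot targets
softmax_ce <- function(logits, targets) {
  p <- softmax_rows(logits)
  loss <- -mean(rowSums(targets * log(pmax(p, 1e-12))))
  list(loss = loss, probs = p, dlogits = (p - targets) / nrow(logits))
}

# ---- LSTM ------------------------------------------------------------------

new_lstm_layer <- function(cin, H) {
  s <- 1 / sqrt(H)
  l <- list(type = "lstm", cin = cin, H = H,
            W = array(stats::rnorm(cin * 4 * H, 0, s), c(cin, 4 * H)),
            U = array(stats::rnorm(H * 4 * H, 0, s), c(H, 4 * H)),
            b = numeric(4 * H))
  l$b[(H + 1):(2 * H)] <- 1   # forget-gate bias
  l
}

sigm <- function(x) 1 / (1 + exp(-x))

# X: (N, L, C); returns hidden sequence (N, L, H) and per-step caches
lstm_fwd <- function(layer, X) {
  d <- dim(X); N <- d[1]; L <- d[2]; H <- layer$H
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Hs <- array(0, c(N, L, H))
  caches <- vector("list", L)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  i4 <- (3 * H + 1):(4 * H)
  for (t in seq_len(L)) {
    xt <- matrix(X[, t, , drop = FALSE], N, d[3])
    a <- xt %*% layer$W + h %*% layer$U
    a <- sweep(a, 2, layer$b, `+`)
    ig <- sigm(a[, i1, drop = FALSE]); fg <- sigm(a[, i2, drop = FALSE])
    gg <- tanh(a[, i3, drop = FALSE]); og <- sigm(a[, i4, drop = FALSE])
    c_prev <- cc
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- og * tc
    Hs[, t, ] <- h
    caches[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                        ig = ig, fg = fg, gg = gg, og = og, tc = tc)
  }
  list(out = Hs, caches = caches, dims = d)
}

# dHs: gradient w.r.t. the full hidden sequence (N, L, H)
lstm_bwd <- function(layer, cache, dHs) {
  d <- cache$dims; N <- d[1]; L <- d[2]; H <- layer$H
  dW <- array(0, dim(layer$W)); dU <- array(0, dim(layer$U))
  db <- numeric(4 * H)
  dX <- array(0, d)
  dh <- matrix(0, N, H); dc <- matrix(0, N, H)
  for (t in rev(seq_len(L))) {
    cs <- cache$caches[[t]]
    dh_t <- dh + matrix(dHs[, t, , drop = FALSE], N, H)
    dog <- dh_t * cs$tc
    dc_t <- dc + dh_t * cs$og * (1 - cs$tc^2)
    dig <- dc_t * cs$gg
    dfg <- dc_t * cs$c_prev
    dgg <- dc_t * cs$ig
    da <- cbind(dig * cs$ig * (1 - cs$ig),
                dfg * cs$fg * (1 - cs$fg),
                dgg * (1 - cs$gg^2),
                dog * cs$og * (1 - cs$og))
    dW <- dW + crossprod(cs$xt, da)
    dU <- dU + crossprod(cs$h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(layer$W)
    dh <- da %*% t(layer$U)
    dc <- dc_t * cs$fg
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db))
}

# ---- parameter plumbing ----------------------------------------------------

PARAM_FIELDS <- c("W", "b", "W1", "W2", "U", "gamma", "beta")

nn_collect_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    for (f in intersect(PARAM_FIELDS, names(ly)))
      out[[paste0(nm, "/", f)]] <- ly[[f]]
  }
  out
}

nn_assign_params <- function(layers, params) {
  for (key in names(params)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    layers[[parts[1]]][[parts[2]]] <- params[[key]]
  }
  layers
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# merge per-layer grads (named list of lists) into flat "layer/field" keys,
# accumulating duplicates (layers used twice in a graph).
flat_grads <- function(...) {
  out <- list()
  for (gl in list(...)) {
    for (key in names(gl)) {
      out[[key]] <- if (is.null(out[[key]])) gl[[key]]
                    else out[[key]] + gl[[key]]
    }
  }
  out
}

prefix_grads <- function(nm, grads) {
  stats::setNames(grads, paste0(nm, "/", names(grads)))
}
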