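# Skill (Expert/Novice) and task (Coagulation/non-Coagulation) recognition.
#
# FTFIT is an InceptionTime-style stack: each module applies a 1-wide
# bottleneck convolution, three parallel convolutions with kernel sizes
# {10, 20, 40}, and a max-pool -> 1-wide-conv branch, concatenates the four
# branches, batch-normalizes and applies ReLU; a residual shortcut joins in
# every third module. Global average pooling yields the learned embedding
# used both by the softmax head and by the hybrid logistic classifier.

#' FTFIT configuration
#'
#' Published defaults: window 200, depth 6 (skill) or 12 (task), learning
#' rate 0.001 (skill) or 0.01 (task), batch size 128, kernels {10, 20, 40}.
#' The bottleneck/branch width defaults to 8 filters per branch, the
#' package's CPU-scale setting (a 32-dimensional embedding after the
#' four-branch concatenation); widen for larger studies.
#'
#' @param L Window length, samples.
#' @param channels Input channels: 2 (force only) or 3 (+ feature channel).
#' @param depth Number of inception modules.
#' @param width Filters per branch (bottleneck width equals it).
#' @param kernels Branch kernel sizes; all must be < L.
#' @param lr,batch_size,max_epochs,patience,seed Training schedule.
#' @export
ftfit_config <- function(L = 200L, channels = 2L, depth = 6L, width = 8L,
                         kernels = c(10L, 20L, 40L), lr = 1e-3,
                         batch_size = 128L, max_epochs = 30L, patience = 5L,
                         seed = 1L) {
  cfg <- list(L = as.integer(L), channels = as.integer(channels),
              depth = as.integer(depth), width = as.integer(width),
              kernels = as.integer(kernels), lr = lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$depth < 1) stop_labeled("config_error", "depth must be >= 1")
  if (any(cfg$kernels >= cfg$L))
    stop_labeled("config_error", "kernel sizes must be < window length L")
  structure(cfg, class = "ftfit_config")
}

#' Build an FTFIT model
#'
#' @param cfg An [ftfit_config()].
#' @return Untrained model of class `ftfit_model`. The pooled embedding has
#'   dimension `4 * width` (four concatenated branches).
#' @export
build_ftfit <- function(cfg = ftfit_config()) {
  with_seed(cfg$seed, {
    nf <- cfg$width
    nk <- length(cfg$kernels)
    cout <- (nk + 1L) * nf
    layers <- list()
    cin <- cfg$channels
    res_cin <- cin
    for (m in seq_len(cfg$depth)) {
      layers[[sprintf("m%d_bottleneck", m)]] <- new_conv1d(1, cin, nf)
      for (j in seq_along(cfg$kernels))
        layers[[sprintf("m%d_conv%d", m, j)]] <-
          new_conv1d(cfg$kernels[j], nf, nf)
      layers[[sprintf("m%d_poolconv", m)]] <- new_conv1d(1, cin, nf)
      layers[[sprintf("m%d_bn", m)]] <- new_bn(cout)
      if (m %% 3L == 0L) {
        layers[[sprintf("m%d_shortcut", m)]] <- new_conv1d(1, res_cin, cout)
        layers[[sprintf("m%d_shortcut_bn", m)]] <- new_bn(cout)
        res_cin <- cout
      }
      cin <- cout
    }
    layers[["head"]] <- new_dense(cout, 2)
    structure(list(arch = "ftfit", loss = "window", cfg = cfg,
                   layers = layers, embed_dim = cout,
                   classes = c("negative", "positive")),
              class = c("ftfit_model", "nn_model"))
  })
}

ftfit_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  if (dim(X)[3] != cfg$channels)
    stop_labeled("shape_error", "model expects %d channels, got %d",
                 cfg$channels, dim(X)[3])
  ly <- model$layers
  nk <- length(cfg$kernels)
  caches <- list()
  bn_states <- list()
  z <- X
  res_in <- X
  for (m in seq_len(cfg$depth)) {
    bt <- conv1d_fwd(ly[[sprintf("m%d_bottleneck", m)]], z)
    branches <- vector("list", nk)
    for (j in seq_len(nk))
      branches[[j]] <- conv1d_fwd(ly[[sprintf("m%d_conv%d", m, j)]], bt$out)
    p3 <- pool3_fwd(z)
    pc <- conv1d_fwd(ly[[sprintf("m%d_poolconv", m)]], p3$out)
    cat_out <- branches[[1]]$out
    for (j in 2:nk) cat_out <- abind3(cat_out, branches[[j]]$out)
    cat_out <- abind3(cat_out, pc$out)
    bn_nm <- sprintf("m%d_bn", m)
    bnr <- bn_fwd(ly[[bn_nm]], cat_out, training)
    if (training) bn_states[[bn_nm]] <- bnr$state
    mc <- list(bt = bt, branches = branches, p3 = p3, pc = pc, bn = bnr)
    if (m %% 3L == 0L) {
      sc <- conv1d_fwd(ly[[sprintf("m%d_shortcut", m)]], res_in)
      sbn_nm <- sprintf("m%d_shortcut_bn", m)
      sbn <- bn_fwd(ly[[sbn_nm]], sc$out, training)
      if (training) bn_states[[sbn_nm]] <- sbn$state
      rl <- relu_fwd(bnr$out + sbn$out)
      mc$shortcut <- sc
      mc$shortcut_bn <- sbn
      res_in <- rl$out
    } else {
      rl <- relu_fwd(bnr$out)
    }
    mc$relu <- rl
    caches[[sprintf("m%d", m)]] <- mc
    z <- rl$out
  }
  gp <- gap_fwd(z)
  hd <- dense_fwd(ly[["head"]], gp$out)
  caches[["gap"]] <- gp
  caches[["head"]] <- hd
  list(logits = hd$out, embedding = gp$out, caches = caches,
       bn_states = if (training) bn_states else NULL)
}

ftfit_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  ly <- model$layers
  nk <- length(cfg$kernels)
  nf <- cfg$width
  caches <- fw$caches
  hb <- dense_bwd(ly[["head"]], caches$head, dlogits)
  grads <- prefix_grads("head", hb$grads)
  dz <- gap_bwd(caches$gap, hb$dX)
  dres <- NULL  # gradient flowing to the stored residual input
  for (m in rev(seq_len(cfg$depth))) {
    mc <- caches[[sprintf("m%d", m)]]
    if (!is.null(dres) && m %% 3L == 0L) {
      # dres was addressed to this module's relu output (it is res_in
      # for later modules); fold it in before differentiating the relu
      dz <- dz + dres
      dres <- NULL
    }
    drelu <- relu_bwd(mc$relu, dz)
    if (m %% 3L == 0L) {
      sbn_nm <- sprintf("m%d_shortcut_bn", m)
      sbb <- bn_bwd(ly[[sbn_nm]], mc$shortcut_bn, drelu)
      scb <- conv1d_bwd(ly[[sprintf("m%d_shortcut", m)]], mc$shortcut,
                        sbb$dX)
      grads <- flat_grads(grads, prefix_grads(sbn_nm, sbb$grads),
                          prefix_grads(sprintf("m%d_shortcut", m), scb$grads))
      dres <- scb$dX
      dbn_out <- drelu
    } else {
      dbn_out <- drelu
    }
    bn_nm <- sprintf("m%d_bn", m)
    bb <- bn_bwd(ly[[bn_nm]], mc$bn, dbn_out)
    grads <- flat_grads(grads, prefix_grads(bn_nm, bb$grads))
    dcat <- bb$dX
    dbt_out <- NULL
    for (j in seq_len(nk)) {
      dj <- dcat[, , (j - 1L) * nf + seq_len(nf), drop = FALSE]
      cb <- conv1d_bwd(ly[[sprintf("m%d_conv%d", m, j)]], mc$branches[[j]],
                       dj)
      grads <- flat_grads(grads,
                          prefix_grads(sprintf("m%d_conv%d", m, j), cb$grads))
      dbt_out <- if (is.null(dbt_out)) cb$dX else dbt_out + cb$dX
    }
    dpc <- dcat[, , nk * nf + seq_len(nf), drop = FALSE]
    pcb <- conv1d_bwd(ly[[sprintf("m%d_poolconv", m)]], mc$pc, dpc)
    grads <- flat_grads(grads, prefix_grads(sprintf("m%d_poolconv", m),
                                            pcb$grads))
    dp3 <- pool3_bwd(mc$p3, pcb$dX)
    btb <- conv1d_bwd(ly[[sprintf("m%d_bottleneck", m)]], mc$bt, dbt_out)
    grads <- flat_grads(grads, prefix_grads(sprintf("m%d_bottleneck", m),
                                            btb$grads))
    dz <- btb$dX + dp3
  }
  if (!is.null(dres)) dz <- dz + dres
  grads
}

#' LSTM configuration and model
#'
#' A stacked recurrent baseline over the same (L, C) windows: the final
#' hidden state of the top layer feeds a dense softmax head. Default
#' topology is 2 layers of 32 units, the package's CPU-scale declared
#' default (the architecture is a free choice; no published topology
#' exists for this baseline).
#'
#' @param L,channels Window shape.
#' @param layers Number of stacked LSTM layers.
#' @param units Hidden units per layer.
#' @param lr,batch_size,max_epochs,patience,seed Training schedule.
#' @export
lstm_config <- function(L = 200L, channels = 2L, layers = 2L, units = 32L,
                        lr = 1e-3, batch_size = 128L, max_epochs = 30L,
                        patience = 5L, seed = 1L) {
  structure(list(L = as.integer(L), channels = as.integer(channels),
                 n_layers = as.integer(layers), units = as.integer(units),
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "lstm_config")
}

#' @rdname lstm_config
#' @param cfg An [lstm_config()].
#' @export
build_lstm <- function(cfg = lstm_config()) {
  with_seed(cfg$seed, {
    layers <- list()
    cin <- cfg$channels
    for (i in seq_len(cfg$n_layers)) {
      layers[[sprintf("lstm%d", i)]] <- new_lstm_layer(cin, cfg$units)
      cin <- cfg$units
    }
    layers[["head"]] <- new_dense(cfg$units, 2)
    structure(list(arch = "lstm", loss = "window", cfg = cfg,
                   layers = layers),
              class = c("lstm_model", "nn_model"))
  })
}

lstm_forward_net <- function(model, X, training = FALSE) {
  ly <- model$layers
  caches <- list()
  z <- X
  for (i in seq_len(model$cfg$n_layers)) {
    r <- lstm_fwd(ly[[sprintf("lstm%d", i)]], z)
    caches[[sprintf("lstm%d", i)]] <- r
    z <- r$out
  }
  L <- dim(z)[2]
  h_last <- matrix(z[, L, , drop = FALSE], dim(z)[1], dim(z)[3])
  hd <- dense_fwd(ly[["head"]], h_last)
  caches[["head"]] <- hd
  list(logits = hd$out, caches = caches, bn_states = NULL)
}

lstm_backward_net <- function(model, fw, dlogits) {
  ly <- model$layers
  caches <- fw$caches
  hb <- dense_bwd(ly[["head"]], caches$head, dlogits)
  grads <- prefix_grads("head", hb$grads)
  top <- caches[[sprintf("lstm%d", model$cfg$n_layers)]]
  d <- top$dims
  dHs <- array(0, c(d[1], d[2], model$layers[[
    sprintf("lstm%d", model$cfg$n_layers)]]$H))
  dHs[, d[2], ] <- hb$dX
  for (i in rev(seq_len(model$cfg$n_layers))) {
    nm <- sprintf("lstm%d", i)
    bk <- lstm_bwd(ly[[nm]], caches[[nm]], dHs)
    grads <- flat_grads(grads, prefix_grads(nm, bk$grads))
    dHs <- bk$dX
  }
  grads
}

#' Train a window classifier (FTFIT or LSTM)
#'
#' Softmax cross-entropy with Adam and early stopping on validation loss
#' (best-epoch weights restored). Both classes must appear in the training
#' set.
#'
#' @param model A built `ftfit_model` or `lstm_model`.
#' @param x,y Training windows (N, L, C) and one-hot labels (N, 2).
#' @param xval,yval Optional validation set.
#' @param cfg Optional config override.
#' @param classes Class names, in one-hot column order.
#' @return Trained model with `$history`.
#' @export
train_classifier <- function(model, x, y, xval = NULL, yval = NULL,
                             cfg = model$cfg, classes = colnames(y)) {
  if (is.null(dim(x)) || dim(x)[1] == 0)
    stop_labeled("empty_batch", "no training windows")
  if (any(colSums(y) == 0))
    stop_labeled("missing_class",
                 "class '%s' missing from the training set",
                 colnames(y)[colSums(y) == 0][1])
  model <- nn_train(model, x, y, xval, yval, lr = cfg$lr,
                    batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
                    patience = cfg$patience, seed = cfg$seed)
  model$classes <- classes %||% c("class0", "class1")
  model
}

#' Predict class probabilities for windows
#' @param model Trained classifier model.
#' @param x Array (N, L, C).
#' @return N x 2 probability matrix (rows sum to 1).
#' @export
predict_proba <- function(model, x) {
  n <- dim(x)[1]
  out <- matrix(0, n, 2)
  for (s in seq.int(1L, n, 256L)) {
    idx <- s:min(n, s + 255L)
    fw <- model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- softmax_rows(fw$logits)
  }
  colnames(out) <- model$classes
  out
}

#' Pooled FTFIT embeddings for windows
#' @param model Trained `ftfit_model`.
#' @param x Array (N, L, C).
#' @return N x embed_dim matrix.
#' @export
ftfit_embedding <- function(model, x) {
  n <- dim(x)[1]
  out <- matrix(0, n, model$embed_dim)
  for (s in seq.int(1L, n, 256L)) {
    idx <- s:min(n, s + 255L)
    fw <- model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$embedding
  }
  out
}

#' XGBoost baseline on the hand-crafted features
#'
#' Gradient-boosted trees on the 29 engineered features only; the deep
#' models are compared against this baseline.
#'
#' @param features Feature table (canonical columns; extra metadata columns
#'   are ignored).
#' @param labels Binary class labels (character or factor).
#' @param seed Integer seed.
#' @param nrounds Boosting rounds.
#' @return Object of class `xgb_baseline` with `$predict(features)`
#'   returning an N x 2 probability matrix.
#' @export
train_xgb_baseline <- function(features, labels, seed = 1L, nrounds = 100L) {
  cols <- intersect(feature_names(), names(features))
  if (length(cols) == 0) cols <- names(features)
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- factor(labels)
  stopifnot(nlevels(y) == 2)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  bst <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 4, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
  obj <- list(model = bst, cols = cols, classes = levels(y))
  obj$predict <- function(newdata) {
    Xn <- as.matrix(newdata[, obj$cols, drop = FALSE])
    p1 <- stats::predict(obj$model, xgboost::xgb.DMatrix(Xn))
    out <- cbind(1 - p1, p1)
    colnames(out) <- obj$classes
    out
  }
  class(obj) <- "xgb_baseline"
  obj
}

#' Hybrid logistic head on learned plus engineered features
#'
#' Concatenates the pooled FTFIT embedding of each window with the
#' standardized engineered features and fits a logistic regression; the
#' published pipeline uses this head for surgeon-experience classification.
#'
#' @param ftfit Trained `ftfit_model`.
#' @param x Windows (N, L, C) aligned with `features`.
#' @param features Feature table (N rows).
#' @param labels Binary labels (N).
#' @param feature_cols Feature columns to use (default all canonical ones
#'   present).
#' @return Object of class `hybrid_logistic` with `$predict(x, features)`.
#' @export
hybrid_logistic <- function(ftfit, x, features, labels,
                            feature_cols = intersect(feature_names(),
                                                     names(features))) {
  if (dim(x)[1] != nrow(features))
    stop_labeled("shape_error", "window count (%d) != feature rows (%d)",
                 dim(x)[1], nrow(features))
  emb <- ftfit_embedding(ftfit, x)
  Fm <- as.matrix(features[, feature_cols, drop = FALSE])
  mu <- colMeans(Fm)
  sdv <- apply(Fm, 2, sd_pop)
  sdv[sdv == 0] <- 1
  Fs <- sweep(sweep(Fm, 2, mu), 2, sdv, `/`)
  y <- factor(labels)
  stopifnot(nlevels(y) == 2)
  df <- data.frame(cbind(emb, Fs))
  names(df) <- c(paste0("e", seq_len(ncol(emb))),
                 paste0("f", seq_len(ncol(Fs))))
  df$.y <- as.integer(y) - 1L
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
  obj <- list(fit = fit, ftfit = ftfit, feature_cols = feature_cols,
              mu = mu, sd = sdv, classes = levels(y))
  obj$predict <- function(x_new, features_new) {
    emb_n <- ftfit_embedding(obj$ftfit, x_new)
    Fn <- as.matrix(features_new[, obj$feature_cols, drop = FALSE])
    Fn <- sweep(sweep(Fn, 2, obj$mu), 2, obj$sd, `/`)
    nd <- data.frame(cbind(emb_n, Fn))
    names(nd) <- c(paste0("e", seq_len(ncol(emb_n))),
                   paste0("f", seq_len(ncol(Fn))))
    p1 <- suppressWarnings(
      stats::predict(obj$fit, newdata = nd, type = "response"))
    out <- cbind(1 - p1, p1)
    colnames(out) <- obj$classes
    out
  }
  class(obj) <- "hybrid_logistic"
  obj
}
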