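test_that("FTFIT construction follows the inception-module contract", {
  cfg <- ftfit_config(L = 200, channels = 2, depth = 6, width = 8, seed = 1)
  m <- build_ftfit(cfg)
  expect_identical(m$embed_dim, 4L * 8L)   # four concatenated branches
  x <- array(rnorm(3 * 200 * 2), c(3, 200, 2))
  fw <- forcepsml:::model_forward(m, x)
  p <- forcepsml:::softmax_rows(fw$logits)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_identical(dim(fw$embedding), c(3L, 32L))

  # channel contract: a 2-channel model rejects feature-augmented windows
  x3 <- array(rnorm(3 * 200 * 3), c(3, 200, 3))
  expect_error(forcepsml:::model_forward(m, x3), class = "shape_error")
  m3 <- build_ftfit(ftfit_config(channels = 3, seed = 1))
  expect_silent(forcepsml:::model_forward(m3, x3))

  expect_error(ftfit_config(L = 30, kernels = c(10, 20, 40)),
               class = "config_error")
  expect_error(ftfit_config(depth = 0), class = "config_error")
})

test_that("full FTFIT gradients agree with numeric differentiation", {
  with_seed_local(12, {
    cfg <- ftfit_config(L = 30, channels = 2, depth = 4, width = 3,
                        kernels = c(3L, 5L, 7L), seed = 4)
    m <- build_ftfit(cfg)
    X <- array(rnorm(5 * 30 * 2), c(5, 30, 2))
    Y <- one_hot(sample(c("a", "b"), 5, TRUE), c("a", "b"))
    fw <- forcepsml:::model_forward(m, X, training = TRUE)
    ce <- forcepsml:::ce_on_batch(m, fw$logits, Y)
    grads <- forcepsml:::model_backward(m, fw, ce$dlogits)
    params <- forcepsml:::nn_collect_params(m$layers)
    for (probe in 1:15) {
      key <- sample(names(grads), 1)
      i <- sample(length(params[[key]]), 1)
      if (abs(grads[[key]][i]) < 1e-8) next  # conv bias under BN: grad 0
      eps <- 1e-5
      loss_at <- function(v) {
        p2 <- params; p2[[key]][i] <- v
        m2 <- m; m2$layers <- forcepsml:::nn_assign_params(m2$layers, p2)
        fw2 <- forcepsml:::model_forward(m2, X, training = TRUE)
        forcepsml:::ce_on_batch(m2, fw2$logits, Y)$loss
      }
      gn <- (loss_at(params[[key]][i] + eps) -
               loss_at(params[[key]][i] - eps)) / (2 * eps)
      expect_lt(abs(grads[[key]][i] - gn) /
                  max(1e-6, abs(gn), abs(grads[[key]][i])), 1e-3,
                label = sprintf("grad of %s[%d]", key, i))
    }
  })
})

test_that("LSTM model meets its shape and determinism contract", {
  cfg <- lstm_config(L = 64, channels = 2, layers = 2, units = 8, seed = 5)
  m <- build_lstm(cfg)
  x <- array(rnorm(4 * 64 * 2), c(4, 64, 2))
  fw <- forcepsml:::model_forward(m, x)
  p <- forcepsml:::softmax_rows(fw$logits)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)

  m3 <- build_lstm(lstm_config(channels = 3, units = 8, seed = 5))
  x3 <- array(rnorm(2 * 200 * 3), c(2, 200, 3))
  expect_identical(dim(forcepsml:::model_forward(m3, x3)$logits), c(2L, 2L))

  # deterministic per seed
  expect_identical(build_lstm(cfg)$layers$lstm1$W, m$layers$lstm1$W)
})

test_that("classifiers learn a separable amplitude toy", {
  tr <- toy_class_windows(120, seed = 2)
  va <- toy_class_windows(40, seed = 3)
  classes <- c("lo", "hi")
  ytr <- one_hot(tr$lab, classes); yva <- one_hot(va$lab, classes)

  cfg <- ftfit_config(L = 64, channels = 2, depth = 3, width = 4,
                      kernels = c(5L, 11L, 21L), max_epochs = 20,
                      batch_size = 32, seed = 2)
  m <- train_classifier(build_ftfit(cfg), tr$x, ytr, va$x, yva, cfg, classes)
  expect_gt(tail(m$history$val_acc, 1), 0.95)
  expect_true(all(diff(m$history$epoch) == 1))

  # same seed reproduces the final weights exactly
  m2 <- train_classifier(build_ftfit(cfg), tr$x, ytr, va$x, yva, cfg,
                         classes)
  expect_identical(
    sum(unlist(forcepsml:::nn_collect_params(m$layers))),
    sum(unlist(forcepsml:::nn_collect_params(m2$layers))))

  lcfg <- lstm_config(L = 64, channels = 2, units = 16, max_epochs = 20,
                      batch_size = 32, seed = 2)
  lm <- train_classifier(build_lstm(lcfg), tr$x, ytr, va$x, yva, lcfg,
                         classes)
  expect_gt(tail(lm$history$val_acc, 1), 0.9)

  y_bad <- ytr; y_bad[, 2] <- 0
  expect_error(train_classifier(build_ftfit(cfg), tr$x, y_bad, va$x, yva,
                                cfg, classes),
               class = "missing_class")
})

test_that("a constant zero third channel reproduces the 2-channel model", {
  tr <- toy_class_windows(80, seed = 4)
  va <- toy_class_windows(30, seed = 5)
  classes <- c("lo", "hi")
  ytr <- one_hot(tr$lab, classes); yva <- one_hot(va$lab, classes)
  zeros <- function(x) {
    out <- array(0, dim(x) + c(0, 0, 1))
    out[, , 1:2] <- x
    out
  }
  cfg2 <- ftfit_config(L = 64, channels = 2, depth = 2, width = 4,
                       kernels = c(5L, 11L, 21L), max_epochs = 20,
                       patience = 10L, batch_size = 32, seed = 3)
  cfg3 <- ftfit_config(L = 64, channels = 3, depth = 2, width = 4,
                       kernels = c(5L, 11L, 21L), max_epochs = 20,
                       patience = 10L, batch_size = 32, seed = 3)
  m2c <- train_classifier(build_ftfit(cfg2), tr$x, ytr, va$x, yva, cfg2,
                          classes)
  m3c <- train_classifier(build_ftfit(cfg3), zeros(tr$x), ytr, zeros(va$x),
                          yva, cfg3, classes)
  a2 <- tail(m2c$history$val_acc, 1)
  a3 <- tail(m3c$history$val_acc, 1)
  expect_lt(abs(a2 - a3), 0.1)   # seed-level equivalence of accuracy
})

test_that("XGBoost baseline behaves on separable and null features", {
  with_seed_local(6, {
    n <- 200
    tab <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
    y <- rep(c("a", "b"), each = n / 2)
    tab$f1 <- ifelse(y == "a", 0, 3) + rnorm(n, 0, 0.1)
    fit <- train_xgb_baseline(tab, y, seed = 1)
    p <- fit$predict(tab)
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-6)
    expect_gt(mean(colnames(p)[max.col(p)] == y), 0.99)

    # pure-noise features hover near chance under cross-validation
    tabn <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
    cv <- crossvalidate(function(xx, yy) {
      fit <- train_xgb_baseline(xx, yy, seed = 2)
      list(predict = fit$predict)
    }, tabn, y, k = 5, seed = 3, positive = "a")
    expect_lt(abs(cv$mean_accuracy - 0.5), 0.15)
  })
})

test_that("the hybrid logistic head uses embeddings plus features", {
  tr <- toy_class_windows(120, seed = 7)
  classes <- c("lo", "hi")
  cfg <- ftfit_config(L = 64, channels = 2, depth = 2, width = 4,
                      kernels = c(5L, 11L, 21L), max_epochs = 10,
                      batch_size = 32, seed = 1)
  net <- train_classifier(build_ftfit(cfg), tr$x,
                          one_hot(tr$lab, classes), cfg = cfg,
                          classes = classes)
  feats <- data.frame(g1 = apply(tr$x[, , 1], 1, max),
                      g2 = apply(tr$x[, , 1], 1, sd))
  hyb <- hybrid_logistic(net, tr$x, feats, tr$lab,
                         feature_cols = c("g1", "g2"))
  te <- toy_class_windows(40, seed = 8)
  feats_te <- data.frame(g1 = apply(te$x[, , 1], 1, max),
                         g2 = apply(te$x[, , 1], 1, sd))
  p <- hyb$predict(te$x, feats_te)
  acc_hyb <- mean(colnames(p)[max.col(p)] == te$lab)
  acc_net <- mean(colnames(predict_proba(net, te$x))[
    max.col(predict_proba(net, te$x))] == te$lab)
  expect_gte(acc_hyb, acc_net - 0.05)

  # ablation: with embeddings constant (zeroed windows) the head reduces
  # to logistic regression on the engineered features alone
  hyb0 <- hybrid_logistic(net, tr$x * 0, feats, tr$lab,
                          feature_cols = c("g1", "g2"))
  scale_pop <- function(x) (x - mean(x)) / forcepsml:::sd_pop(x)
  refdf <- data.frame(y = as.integer(factor(tr$lab)) - 1L,
                      g1 = scale_pop(feats$g1), g2 = scale_pop(feats$g2))
  ref <- suppressWarnings(stats::glm(y ~ g1 + g2, data = refdf,
                                     family = stats::binomial()))
  mu <- c(mean(feats$g1), mean(feats$g2))
  sdv <- c(forcepsml:::sd_pop(feats$g1), forcepsml:::sd_pop(feats$g2))
  nd <- data.frame(g1 = (feats_te$g1 - mu[1]) / sdv[1],
                   g2 = (feats_te$g2 - mu[2]) / sdv[2])
  p_ref <- suppressWarnings(stats::predict(ref, nd, type = "response"))
  p0 <- hyb0$predict(te$x * 0, feats_te)
  expect_equal(unname(p0[, 2]), unname(p_ref), tolerance = 1e-6)

  expect_error(hybrid_logistic(net, tr$x, feats[1:10, ], tr$lab),
               class = "shape_error")
})
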