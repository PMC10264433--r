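test_that("T-U-Net construction honours its shape contract", {
  cfg <- tunet_config(L = 224, filters = 16, depth = 3, seed = 1)
  m <- build_tunet(cfg)
  x <- array(rnorm(2 * 224 * 2), c(2, 224, 2))
  fw <- forcepsml:::model_forward(m, x)
  expect_identical(dim(fw$logits), c(2L, 224L, 2L))
  p <- forcepsml:::softmax_rows(matrix(fw$logits, 2 * 224, 2))
  expect_equal(rowSums(p), rep(1, 448), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))

  # parameter count grows with the base filter size
  n8 <- n_params(build_tunet(tunet_config(filters = 8, seed = 1)))
  n16 <- n_params(build_tunet(tunet_config(filters = 16, seed = 1)))
  expect_gt(n16, n8)

  expect_error(tunet_config(L = 225), class = "config_error")
  expect_error(tunet_config(filters = 2), class = "config_error")
})

test_that("full T-U-Net gradients agree with numeric differentiation", {
  with_seed_local(11, {
    cfg <- tunet_config(L = 16, filters = 4, depth = 2, seed = 3)
    m <- build_tunet(cfg)
    X <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
    Y <- matrix(rbinom(4 * 16, 1, 0.5), 4, 16)
    fw <- forcepsml:::model_forward(m, X, training = TRUE)
    ce <- forcepsml:::ce_on_batch(m, fw$logits, Y)
    grads <- forcepsml:::model_backward(m, fw, ce$dlogits)
    params <- forcepsml:::nn_collect_params(m$layers)
    for (probe in 1:15) {
      key <- sample(names(grads), 1)
      i <- sample(length(params[[key]]), 1)
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

test_that("the segmenter learns a separable plateau toy to >0.99", {
  tr <- toy_plateau_windows(80, seed = 7)
  va <- toy_plateau_windows(30, seed = 8)
  cfg <- tunet_config(L = 32, filters = 8, depth = 2, max_epochs = 10,
                      batch_size = 32, lr = 1e-2, seed = 1)
  m <- train_segmenter(build_tunet(cfg), tr, va, cfg)
  expect_gt(tail(m$history$val_acc, 1), 0.99)
  expect_lte(nrow(m$history), 10)

  # determinism: same config and seed give the identical final loss
  m2 <- train_segmenter(build_tunet(cfg), tr, va, cfg)
  expect_identical(tail(m$history$val_loss, 1),
                   tail(m2$history$val_loss, 1))

  expect_error(train_segmenter(build_tunet(cfg),
                               list(x = tr$x[0, , , drop = FALSE],
                                    y = tr$y[0, , drop = FALSE]), va, cfg),
               class = "empty_batch")
})

test_that("point-wise prediction covers recordings of any length", {
  cfg <- tunet_config(L = 32, filters = 8, depth = 2, max_epochs = 8,
                      batch_size = 32, lr = 1e-2, seed = 1)
  tr <- toy_plateau_windows(60, seed = 7)
  m <- train_segmenter(build_tunet(cfg), tr, NULL, cfg)
  x500 <- matrix(rnorm(1000), 500, 2)
  p <- predict_pointwise(m, x500)
  expect_length(p, 500L)
  expect_true(all(p >= 0 & p <= 1))

  # thresholded predictions recover the toy mask
  te <- toy_plateau_windows(20, seed = 9)
  flat <- matrix(aperm(te$x, c(2, 1, 3)), ncol = 2)
  pt <- predict_pointwise(m, flat)
  acc <- mean((pt > 0.5) == as.logical(as.vector(t(te$y))))
  expect_gt(acc, 0.99)
})

test_that("grid search selects the minimum-validation-loss configuration", {
  tr <- toy_plateau_windows(40, seed = 3)
  va <- toy_plateau_windows(15, seed = 4)
  base <- tunet_config(L = 32, filters = 4, depth = 2, max_epochs = 2,
                       batch_size = 32, seed = 1)
  gs1 <- grid_search(list(filters = 4L), tr, va, base)
  expect_identical(nrow(gs1$leaderboard), 1L)
  expect_identical(gs1$best_cfg$filters, 4L)

  gs <- grid_search(list(filters = c(4L, 8L), lr = c(1e-3, 1e-2)), tr, va,
                    base)
  expect_identical(nrow(gs$leaderboard), 4L)
  expect_true(all(gs$leaderboard$val_loss[1] <= gs$leaderboard$val_loss))
  expect_equal(gs$best$best_val_loss, gs$leaderboard$val_loss[1])
})

# independent run-length reference written as an explicit scan
oracle_blocks <- function(mask, min_len, gap_tol) {
  blocks <- list()
  i <- 1; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      start <- i
      end <- i
      j <- i + 1
      gap <- 0
      while (j <= n) {
        if (mask[j]) {
          end <- j; gap <- 0
        } else {
          gap <- gap + 1
          if (gap > gap_tol) break
        }
        j <- j + 1
      }
      if (end - start + 1 >= min_len)
        blocks[[length(blocks) + 1]] <- c(start - 1, end)
      i <- end + gap + 1
    } else i <- i + 1
  }
  if (!length(blocks))
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  m <- do.call(rbind, blocks)
  data.frame(start_idx = as.integer(m[, 1]), end_idx = as.integer(m[, 2]))
}

test_that("block extraction handles the documented cases", {
  expect_identical(extract_segments(c(0, 0, 1, 1, 1, 0, 0), min_len = 2,
                                    gap_tol = 0),
                   data.frame(start_idx = 2L, end_idx = 5L))
  expect_identical(extract_segments(c(1, 1, 0, 1, 1), min_len = 1,
                                    gap_tol = 1),
                   data.frame(start_idx = 0L, end_idx = 5L))
  expect_identical(extract_segments(c(1, 1, 0, 1, 1), min_len = 1,
                                    gap_tol = 0),
                   data.frame(start_idx = c(0L, 3L), end_idx = c(2L, 5L)))
  expect_identical(nrow(extract_segments(rep(0, 10))), 0L)
})

test_that("block extraction equals the run-length oracle exhaustively", {
  n_bits <- 12
  for (gap_tol in 0:2) {
    for (min_len in 1:3) {
      for (code in 0:(2^n_bits - 1)) {
        mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(n_bits - 1)), 1L))
        got <- extract_segments(as.numeric(mask), min_len = min_len,
                                gap_tol = gap_tol)
        want <- oracle_blocks(mask, min_len, gap_tol)
        if (!isTRUE(all.equal(got, want, check.attributes = FALSE)))
          fail(sprintf("mismatch at code %d, gap_tol %d, min_len %d",
                       code, gap_tol, min_len))
      }
    }
  }
  succeed()
})
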