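# Generic minibatch trainer: Adam, cross-entropy, early stopping on
# validation loss with best-epoch weight restore. Works for any model
# exposing model_forward / model_backward via its `arch` field.

model_forward <- function(model, X, training = FALSE) {
  switch(model$arch,
         tunet = tunet_forward(model, X, training),
         ftfit = ftfit_forward(model, X, training),
         lstm = lstm_forward_net(model, X, training),
         stop_labeled("value_error", "unknown architecture '%s'", model$arch))
}

model_backward <- function(model, fw, dlogits) {
  switch(model$arch,
         tunet = tunet_backward(model, fw, dlogits),
         ftfit = ftfit_backward(model, fw, dlogits),
         lstm = lstm_backward_net(model, fw, dlogits))
}

ce_on_batch <- function(model, logits, Y) {
  if (model$loss == "pointwise") {
    d <- dim(logits)                      # (N, L, 2)
    lm <- matrix(logits, d[1] * d[2], d[3])
    t2 <- cbind(1 - as.numeric(Y), as.numeric(Y))  # cols: OFF, ON
    sc <- softmax_ce(lm, t2)
    acc <- mean((sc$probs[, 2] > 0.5) == (as.numeric(Y) == 1))
    list(loss = sc$loss, acc = acc,
         dlogits = array(sc$dlogits, d))
  } else {
    sc <- softmax_ce(logits, Y)
    acc <- mean(max.col(sc$probs) == max.col(Y))
    list(loss = sc$loss, acc = acc, dlogits = sc$dlogits)
  }
}

slice_batch <- function(X, idx) X[idx, , , drop = FALSE]
slice_y <- function(model, Y, idx) {
  if (model$loss == "pointwise") Y[idx, , drop = FALSE]
  else Y[idx, , drop = FALSE]
}

# evaluate loss/accuracy over a set in chunks (inference mode)
nn_evaluate <- function(model, X, Y, chunk = 256L) {
  n <- dim(X)[1]
  tot_loss <- 0; tot_acc <- 0
  for (s in seq.int(1L, n, chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    fw <- model_forward(model, slice_batch(X, idx), training = FALSE)
    ce <- ce_on_batch(model, fw$logits, slice_y(model, Y, idx))
    w <- length(idx) / n
    tot_loss <- tot_loss + ce$loss * w
    tot_acc <- tot_acc + ce$acc * w
  }
  list(loss = tot_loss, acc = tot_acc)
}

#' @keywords internal
nn_train <- function(model, X, Y, Xval = NULL, Yval = NULL,
                     lr = 1e-3, batch_size = 128L, max_epochs = 30L,
                     patience = 10L, seed = 1L, verbose = FALSE) {
  n <- dim(X)[1]
  if (n == 0) stop_labeled("empty_batch", "no training windows")
  params <- nn_collect_params(model$layers)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(seed + epoch, sample.int(n))
    ep_loss <- 0; ep_acc <- 0
    for (s in seq.int(1L, n, batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      fw <- model_forward(model, slice_batch(X, idx), training = TRUE)
      if (!is.null(fw$bn_states))
        for (nm in names(fw$bn_states)) {
          model$layers[[nm]]$run_mean <- fw$bn_states[[nm]]$run_mean
          model$layers[[nm]]$run_var <- fw$bn_states[[nm]]$run_var
        }
      ce <- ce_on_batch(model, fw$logits, slice_y(model, Y, idx))
      grads <- model_backward(model, fw, ce$dlogits)
      st <- adam_step(params, grads, opt, lr)
      params <- st$params; opt <- st$state
      model$layers <- nn_assign_params(model$layers, params)
      w <- length(idx) / n
      ep_loss <- ep_loss + ce$loss * w
      ep_acc <- ep_acc + ce$acc * w
    }
    if (!is.null(Xval) && dim(Xval)[1] > 0) {
      ev <- nn_evaluate(model, Xval, Yval)
    } else ev <- list(loss = ep_loss, acc = ep_acc)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss, train_acc = ep_acc,
      val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, ep_loss, ep_acc, ev$loss, ev$acc))
    if (ev$loss < best$loss - 1e-6) {
      best <- list(loss = ev$loss, params = params, epoch = epoch,
                   bn = lapply(model$layers, function(l)
                     if (identical(l$type, "bn"))
                       list(run_mean = l$run_mean, run_var = l$run_var)))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$layers <- nn_assign_params(model$layers, best$params)
  if (!is.null(best$bn))
    for (nm in names(best$bn)) {
      if (!is.null(best$bn[[nm]])) {
        model$layers[[nm]]$run_mean <- best$bn[[nm]]$run_mean
        model$layers[[nm]]$run_var <- best$bn[[nm]]$run_var
      }
    }
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model
}
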