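# Desk-scale benchmark workflows on synthetic data. These are the package's
# reference experiments: segmentation of default recordings with the
# T-U-Net, and Coagulation-vs-non-Coagulation recognition with FTFIT (with
# the subset-1 feature channel) or the LSTM baseline. Both return the
# metric bundle computed on a held-out 20% test split.

#' Segmentation benchmark on synthetic recordings
#'
#' Generates default synthetic recordings, trims long idle runs, windows
#' the standardized traces into 224-point windows with point labels, makes
#' a nested 64/16/20 split, trains the T-U-Net and reports point-wise test
#' metrics.
#'
#' @param n_windows Number of 224-point windows to use (default 400).
#' @param seed Integer seed driving generation, split and training.
#' @param filters,lr,max_epochs T-U-Net hyperparameters (published
#'   defaults: filters 16, learning rate 0.001).
#' @return List: `weighted_f1`, `report` (full [compute_metrics()] bundle),
#'   `model`, `n_windows`.
#' @export
benchmark_segmentation <- function(n_windows = 400L, seed = 7L,
                                   filters = 16L, lr = 1e-3,
                                   max_epochs = 30L) {
  minutes <- ceiling(n_windows * 224 / 20 / 60 * 1.35) + 5
  scfg <- synth_config(recording_minutes = minutes)
  gen <- generate_recording(scfg, seed = seed)
  rec <- balance_idle(gen$recording)
  std <- fit_standardizer(rec)
  recs <- apply_standardizer(std, rec)
  wb <- make_windows(recs, 224L)
  n <- min(n_windows, dim(wb$x)[1])
  x <- wb$x[seq_len(n), , , drop = FALSE]
  y <- wb$y[seq_len(n), , drop = FALSE]
  sp <- split_nested(n, seed = seed)
  cfg <- tunet_config(filters = filters, lr = lr, max_epochs = max_epochs,
                      patience = 10L, seed = seed)
  model <- build_tunet(cfg)
  model <- train_segmenter(model,
                           list(x = x[sp$train, , , drop = FALSE],
                                y = y[sp$train, , drop = FALSE]),
                           list(x = x[sp$validation, , , drop = FALSE],
                                y = y[sp$validation, , drop = FALSE]), cfg)
  fw <- model_forward(model, x[sp$test, , , drop = FALSE], training = FALSE)
  d <- dim(fw$logits)
  p <- matrix(softmax_rows(matrix(fw$logits, d[1] * d[2], d[3]))[, 2],
              d[1], d[2])
  truth <- as.logical(y[sp$test, , drop = FALSE])
  rep <- compute_metrics(ifelse(truth, "ON", "OFF"), as.numeric(p),
                         positive = "ON")
  list(weighted_f1 = rep$weighted_f1, report = rep, model = model,
       n_windows = n)
}

#' Task-recognition benchmark on synthetic segments
#'
#' Generates labeled segments with the default task signatures, subsamples
#' Coagulation at 0.5 for balance (before splitting), builds 200-point
#' standardized windows -- with the subset-1 engineered-feature channel for
#' FTFIT -- and trains the requested classifier. Reports held-out test
#' metrics with Coagulation as the positive class.
#'
#' @param n_segments Segments to generate (default 1000).
#' @param seed Integer seed.
#' @param model `"ftfit"` (depth 6, subset-1 feature channel, lr 0.01) or
#'   `"lstm"` (force channels only).
#' @param depth FTFIT depth (default 6).
#' @param max_epochs Training epochs cap.
#' @return List: `macro_auc`, `report`, `model`, `n_segments`.
#' @export
benchmark_task_recognition <- function(n_segments = 1000L, seed = 11L,
                                       model = c("ftfit", "lstm"),
                                       depth = 6L, max_epochs = 30L) {
  model <- match.arg(model)
  scfg <- synth_config()
  ds <- generate_dataset(scfg, n_segments, seed = seed)
  segs <- subsample_class(ds$segments, "Coagulation", 0.5, seed = seed)
  labels <- ifelse(vapply(segs, `[[`, "", "task") == "Coagulation",
                   "Coagulation", "nonCoagulation")
  classes <- c("nonCoagulation", "Coagulation")
  sp <- split_nested(length(segs), seed = seed)
  train_segs <- segs[sp$train]
  std <- fit_standardizer(lapply(train_segs, function(s)
    force_recording(s$left, s$right, fs = s$fs)))
  fstats <- if (model == "ftfit") fit_feature_stats(train_segs) else NULL
  batch_of <- function(idx)
    segments_to_batch(segs[idx], std, feature_stats = fstats)
  xtr <- batch_of(sp$train)
  xva <- batch_of(sp$validation)
  xte <- batch_of(sp$test)
  ytr <- one_hot(labels[sp$train], classes)
  yva <- one_hot(labels[sp$validation], classes)
  if (model == "ftfit") {
    cfg <- ftfit_config(channels = 3L, depth = depth, lr = 1e-2,
                        max_epochs = max_epochs, patience = 5L, seed = seed)
    net <- build_ftfit(cfg)
  } else {
    cfg <- lstm_config(channels = 2L, max_epochs = max_epochs,
                       patience = 5L, seed = seed)
    net <- build_lstm(cfg)
  }
  net <- train_classifier(net, xtr, ytr, xva, yva, cfg, classes)
  probs <- predict_proba(net, xte)
  rep <- compute_metrics(labels[sp$test], probs, positive = "Coagulation")
  list(macro_auc = rep$macro_auc, report = rep, model = net,
       n_segments = length(segs))
}

#' Generator calibration statistics
#'
#' Recomputes the duration statistics the generator is calibrated to:
#' the Coagulation duration mean/SD, the relative excess of Coagulation
#' over the other tasks, and the Novice-vs-Expert Coagulation duration gap
#' (which must vanish, since skill effects never touch durations).
#'
#' @param n_durations Draws for the moment check.
#' @param n_segments Segments for the mix-weighted task gap.
#' @param seed Integer seed.
#' @return List: `coag_mean_s`, `coag_sd_s`, `task_gap_pct`,
#'   `skill_gap_pct`.
#' @export
calibration_statistics <- function(n_durations = 50000L,
                                   n_segments = 10000L, seed = 1L) {
  cfg <- synth_config()
  d <- sample_segment_duration("Coagulation", n_durations, cfg, seed = seed)
  ds <- generate_dataset(cfg, n_segments, seed = seed + 3L)
  task <- vapply(ds$segments, `[[`, "", "task")
  dur <- vapply(ds$segments, function(s) length(s$left), 0) /
    cfg$sampling_rate
  gap <- 100 * (mean(dur[task == "Coagulation"]) /
                  mean(dur[task != "Coagulation"]) - 1)
  coag <- generate_dataset(cfg, n_segments, seed = seed + 5L,
                           tasks = "Coagulation")
  skl <- vapply(coag$segments, `[[`, "", "skill")
  cdur <- vapply(coag$segments, function(s) length(s$left), 0) /
    cfg$sampling_rate
  skill_gap <- 100 * abs(mean(cdur[skl == "Novice"]) -
                           mean(cdur[skl == "Expert"])) /
    mean(cdur[skl == "Expert"])
  list(coag_mean_s = mean(d), coag_sd_s = stats::sd(d),
       task_gap_pct = gap, skill_gap_pct = skill_gap)
}
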