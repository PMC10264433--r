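# Hand-crafted time-series features of a force segment.
#
# 29 named scalars per segment, computed on the mean of the two prong
# channels except the two explicit inter-prong descriptors. Definitions of
# the irregularity features (stability, lumpiness, spikiness, ARCH
# heterogeneity, first-ACF-zero) follow the standard time-series-features
# canon; moment/extremum features are elementary and oracle-checked in the
# test suite.

#' Canonical feature names, in fixed order
#'
#' @return Character vector of the 29 feature names. Units: Duration Force
#'   in seconds; Mean/Median/Max/Minimum/Range/SD/IQR/RMS Force and Prong
#'   Asymmetry in newtons; Dominant Frequency and Spectral Centroid in Hz;
#'   the rest dimensionless.
#' @export
feature_names <- function() c(
  "Duration Force", "Mean Force", "Median Force", "Max Force",
  "Minimum Force", "Range Force", "SD", "IQR", "RMS",
  "Skewness", "Kurtosis", "Coefficient of Variance",
  "Entropy", "Stability", "Lumpiness", "Heterogeneity", "Spikiness",
  "Trend Strength", "Linearity", "Curvature",
  "ACF1", "First Autocorrelation Zero",
  "Flat Spots", "Crossing Points", "Peak Count",
  "Dominant Frequency", "Spectral Centroid",
  "Prong Correlation", "Prong Asymmetry")

#' The canonical 4-feature dashboard subset
#'
#' Duration Force, Range Force, Entropy and Heterogeneity: the four
#' performance indices surfaced on the surgeon dashboard and used as the
#' engineered-feature augmentation channel for task recognition.
#' @return Character vector of length 4.
#' @export
subset1 <- function() c("Duration Force", "Range Force", "Entropy",
                        "Heterogeneity")

# Shannon entropy of the normalized periodogram, scaled to [0, 1] by the
# log bin count. A pure tone gives ~0; white noise ~1.
spectral_entropy <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  if (all(xc == 0)) return(0)
  nb <- floor(n / 2)
  p <- Mod(stats::fft(xc))[2:(nb + 1)]^2
  tot <- sum(p)
  if (tot <= 0 || nb < 2) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(nb)
}

periodogram <- function(x, fs) {
  n <- length(x)
  nb <- floor(n / 2)
  xc <- x - mean(x)
  list(freq = (1:nb) * fs / n, power = Mod(stats::fft(xc))[2:(nb + 1)]^2)
}

# variance of means / variances over non-overlapping tiles
tiled_stat <- function(x, width, stat) {
  n <- length(x)
  k <- floor(n / width)
  if (k < 2) return(0)
  tiles <- matrix(x[seq_len(k * width)], width, k)
  v <- apply(tiles, 2, stat)
  stats::var(v)
}

# ARCH effect: R^2 of regressing squared demeaned values on their lags
arch_r2 <- function(x, lags = 12L) {
  e2 <- (x - mean(x))^2
  n <- length(e2)
  lags <- min(lags, max(1L, floor(n / 5)))
  if (n <= lags + 1) return(0)
  y <- e2[(lags + 1):n]
  X <- sapply(seq_len(lags), function(l) e2[(lags + 1 - l):(n - l)])
  fit <- stats::lm.fit(cbind(1, X), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(0)
  max(0, 1 - ss_res / ss_tot)
}

# variance of leave-one-out variances of the detrended series
spikiness <- function(resid) {
  n <- length(resid)
  if (n < 3) return(0)
  loo <- vapply(seq_len(n), function(i) stats::var(resid[-i]), 0)
  stats::var(loo)
}

first_acf_zero <- function(x, max_lag = length(x) - 1L) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[-1]
  hit <- which(a <= 0)
  if (length(hit)) hit[1] else length(x)
}

flat_spots <- function(x, bins = 10L) {
  if (max(x) == min(x)) return(length(x))
  cuts <- cut(x, breaks = bins, include.lowest = TRUE, labels = FALSE)
  max(rle(cuts)$lengths)
}

#' Extract the 29 hand-crafted features of one force segment
#'
#' Single-channel features are computed on the mean of the two prongs.
#' Stability is the variance of tiled-window means and Lumpiness the
#' variance of tiled-window variances (20-sample tiles); Entropy is the
#' Shannon entropy of the normalized periodogram scaled by log bin count;
#' Spikiness is the variance of leave-one-out variances of the detrended
#' series; Heterogeneity is the ARCH-effect statistic (R-squared of a
#' squared-residual autoregression); Trend Strength, Linearity and
#' Curvature come from orthogonal-polynomial regression on time.
#'
#' @param segment A `force_segment` (>= 20 samples), or an n x 2 matrix.
#' @param fs Sampling rate, Hz.
#' @return Named list of 29 finite scalars in canonical order.
#' @export
extract_features <- function(segment, fs = 20) {
  if (inherits(segment, "force_segment")) {
    left <- segment$left; right <- segment$right; fs <- segment$fs
  } else {
    left <- segment[, 1]; right <- segment[, 2]
  }
  n <- length(left)
  if (n < 20)
    stop_labeled("segment_too_short",
                 "segment has %d samples; need >= 20", n)
  x <- (left + right) / 2
  mu <- mean(x)
  sdv <- sd_pop(x)
  med <- stats::median(x)
  mx <- max(x); mn <- min(x)
  iqr <- stats::IQR(x)
  rms <- sqrt(mean(x^2))
  skew <- if (sdv > 0) mean((x - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((x - mu)^4) / sdv^4 - 3 else 0
  cv <- if (abs(mu) > 1e-12) sdv / abs(mu) else 0

  # trend structure via orthogonal polynomials of time
  tt <- seq_len(n)
  P <- stats::poly(tt, 2)
  fit <- stats::lm.fit(cbind(1, P), x)
  resid <- fit$residuals
  vx <- stats::var(x)
  trend <- if (vx > 0) max(0, 1 - stats::var(resid) / vx) else 0
  linearity <- unname(fit$coefficients[2])
  curvature <- unname(fit$coefficients[3])

  acf1 <- if (sdv > 0)
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2] else 0

  pg <- periodogram(x, fs)
  tot <- sum(pg$power)
  domf <- if (tot > 0) pg$freq[which.max(pg$power)] else 0
  centroid <- if (tot > 0) sum(pg$freq * pg$power) / tot else 0

  d <- diff(sign(x - mu))
  crossings <- sum(d != 0 & !is.na(d))
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  peaks <- sum(x[interior] > x[interior - 1] & x[interior] > x[interior + 1])

  pc <- if (sd_pop(left) > 0 && sd_pop(right) > 0)
    stats::cor(left, right) else 0

  out <- list(
    `Duration Force` = n / fs,
    `Mean Force` = mu,
    `Median Force` = med,
    `Max Force` = mx,
    `Minimum Force` = mn,
    `Range Force` = mx - mn,
    `SD` = sdv,
    `IQR` = iqr,
    `RMS` = rms,
    `Skewness` = skew,
    `Kurtosis` = kurt,
    `Coefficient of Variance` = cv,
    `Entropy` = spectral_entropy(x),
    `Stability` = tiled_stat(x, 20L, mean),
    `Lumpiness` = tiled_stat(x, 20L, stats::var),
    `Heterogeneity` = arch_r2(x),
    `Spikiness` = spikiness(resid),
    `Trend Strength` = trend,
    `Linearity` = linearity,
    `Curvature` = curvature,
    `ACF1` = acf1,
    `First Autocorrelation Zero` = first_acf_zero(x),
    `Flat Spots` = flat_spots(x),
    `Crossing Points` = crossings,
    `Peak Count` = peaks,
    `Dominant Frequency` = domf,
    `Spectral Centroid` = centroid,
    `Prong Correlation` = pc,
    `Prong Asymmetry` = mean(abs(left - right)))
  bad <- names(out)[!vapply(out, is.finite, TRUE)]
  if (length(bad))
    stop_labeled("feature_error", "non-finite feature(s): %s",
                 paste(bad, collapse = ", "))
  out[feature_names()]
}

#' Feature table for a list of segments
#'
#' @param segments List of `force_segment` objects.
#' @param fs Sampling rate, Hz.
#' @return data.frame with `segment_id`, `task`, `skill`, `surgeon_id`
#'   columns followed by the 29 canonical feature columns; row order equals
#'   segment order. Per-segment failures propagate with the segment id.
#' @export
feature_matrix <- function(segments, fs = 20) {
  nm <- feature_names()
  if (length(segments) == 0) {
    empty <- stats::setNames(
      as.data.frame(matrix(numeric(0), 0, length(nm))), nm)
    return(cbind(data.frame(segment_id = integer(0), task = character(0),
                            skill = character(0), surgeon_id = character(0)),
                 empty))
  }
  rows <- lapply(seq_along(segments), function(i) {
    fv <- tryCatch(extract_features(segments[[i]], fs),
                   error = function(e) stop_labeled(
                     "feature_error", "segment %d: %s", i, conditionMessage(e)))
    as.data.frame(fv, check.names = FALSE)
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    segment_id = seq_along(segments),
    task = vapply(segments, function(s) s$task %||% NA_character_, ""),
    skill = vapply(segments, function(s) s$skill %||% NA_character_, ""),
    surgeon_id = vapply(segments, function(s) s$surgeon_id %||% NA_character_, ""))
  out <- cbind(meta, feats)
  rownames(out) <- NULL
  out
}

#' Remove feature-table rows that are outliers by z-score
#'
#' Z-scores are computed once per column on the input table (not
#' iteratively); a row is dropped when any feature column has |z| >= z.
#' Zero-variance columns are skipped.
#'
#' @param table Feature table (data.frame containing the canonical columns).
#' @param z Threshold (default 3); `Inf` is the identity.
#' @return Filtered table.
#' @export
remove_outliers_z <- function(table, z = 3) {
  cols <- intersect(feature_names(), names(table))
  keep <- rep(TRUE, nrow(table))
  for (col in cols) {
    v <- table[[col]]
    s <- sd_pop(v)
    if (s <= 0) next
    keep <- keep & (abs((v - mean(v)) / s) < z)
  }
  table[keep, , drop = FALSE]
}

# leave-one-out 5-NN accuracy given feature matrix X (already scaled)
knn_loo_accuracy <- function(X, y, k = 5L) {
  pred <- class::knn.cv(X, y, k = k)
  mean(pred == y)
}

#' Rank features by KNN permutation importance and boosted-tree gain
#'
#' KNN importance is the drop in leave-one-out 5-NN accuracy when a feature
#' column is permuted (mean over 10 seeded permutations, on column-scaled
#' data). Tree importance is the gain from a gradient-boosted classifier on
#' the raw columns. The consensus ranking is by rank sum of the two.
#'
#' @param X Feature data.frame/matrix (canonical 29 columns or any subset).
#' @param y Class labels (>= 2 classes).
#' @param n_perm Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return data.frame (one row per feature) with `knn_importance`,
#'   `xgb_gain`, per-method ranks and `consensus_rank`, sorted by consensus.
#' @export
rank_features <- function(X, y, n_perm = 10L, seed = 1L) {
  X <- as.data.frame(X)
  y <- factor(y)
  if (nlevels(y) < 2)
    stop_labeled("value_error", "need at least 2 classes to rank features")
  Xs <- scale(as.matrix(X))
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  base_acc <- with_seed(seed, knn_loo_accuracy(Xs, y))
  knn_imp <- with_seed(seed + 1L, vapply(seq_len(ncol(Xs)), function(j) {
    drops <- vapply(seq_len(n_perm), function(p) {
      Xp <- Xs
      Xp[, j] <- sample(Xp[, j])
      base_acc - knn_loo_accuracy(Xp, y)
    }, 0)
    mean(drops)
  }, 0))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                 label = as.integer(y) - 1L)
  nc <- nlevels(y)
  params <- if (nc == 2) list(objective = "binary:logistic")
            else list(objective = "multi:softprob", num_class = nc)
  bst <- with_seed(seed + 2L, xgboost::xgb.train(
    params = c(params, list(max_depth = 3, eta = 0.3, nthread = 1,
                            seed = seed)),
    data = dtrain, nrounds = 50, verbose = 0))
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  gain[imp$Feature] <- imp$Gain
  knn_rank <- rank(-knn_imp, ties.method = "average")
  xgb_rank <- rank(-gain, ties.method = "average")
  out <- data.frame(feature = colnames(X),
                    knn_importance = knn_imp,
                    xgb_gain = as.numeric(gain),
                    knn_rank = knn_rank,
                    xgb_rank = xgb_rank,
                    consensus_rank = rank(knn_rank + xgb_rank,
                                          ties.method = "first"))
  out[order(out$consensus_rank), ]
}
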