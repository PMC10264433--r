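# Standardization, windowing, idle balancing, label encoding, nested
# splitting, and feature-channel construction.
#
# Statistics are always fitted on the training partition only and reused to
# transform validation/test data, so no information leaks across the split.

#' Fit a per-channel standardizer on training recordings
#'
#' Computes the per-channel mean and population SD of the left and right
#' prong forces over the training data; [apply_standardizer()] removes the
#' mean and scales to unit variance with those statistics.
#'
#' @param recordings A `force_recording` or list of them.
#' @return Object of class `standardizer` with fields `mean` and `sd`
#'   (length-2, left/right).
#' @export
fit_standardizer <- function(recordings) {
  if (inherits(recordings, "force_recording")) recordings <- list(recordings)
  left <- unlist(lapply(recordings, `[[`, "left_force_n"))
  right <- unlist(lapply(recordings, `[[`, "right_force_n"))
  if (length(left) < 2)
    stop_labeled("value_error", "need at least 2 samples per channel")
  mu <- c(left = mean(left), right = mean(right))
  sdv <- c(left = sd_pop(left), right = sd_pop(right))
  if (any(sdv <= 0))
    stop_labeled("zero_variance",
                 "channel '%s' has zero variance; cannot standardize",
                 names(sdv)[sdv <= 0][1])
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @param rec Recording (or n x 2 matrix) to transform with the training
#'   statistics.
#' @export
apply_standardizer <- function(std, rec) {
  if (inherits(rec, "force_recording")) {
    rec$left_force_n <- (rec$left_force_n - std$mean["left"]) / std$sd["left"]
    rec$right_force_n <- (rec$right_force_n - std$mean["right"]) / std$sd["right"]
    rec
  } else {
    cbind((rec[, 1] - std$mean["left"]) / std$sd["left"],
          (rec[, 2] - std$mean["right"]) / std$sd["right"])
  }
}

#' Standardize a numeric vector to zero mean, unit variance
#'
#' Uses the population SD (divide by n), so e.g. `c(1, 2, 3)` maps to
#' `c(-1.2247, 0, 1.2247)`.
#' @param x Numeric vector.
#' @param mean,sd Optional pre-fitted statistics (training values).
#' @export
standardize_vec <- function(x, mean = NULL, sd = NULL) {
  m <- mean %||% base::mean(x)
  s <- sd %||% sd_pop(x)
  if (s <= 0) stop_labeled("zero_variance", "zero-variance input")
  (x - m) / s
}

#' Slice a recording into fixed-length windows
#'
#' Windows start at offsets 0, stride, 2*stride, ...; a trailing partial
#' window is dropped. Point labels, when present, are carried per sample.
#'
#' @param rec A `force_recording` (standardized or raw).
#' @param L Window length in samples (224 for segmentation).
#' @param stride Offset between window starts; defaults to `L`
#'   (non-overlapping).
#' @return List of class `window_batch`: `x` array (n_windows, L, 2) and,
#'   if the recording is labeled, `y` integer matrix (n_windows, L) with
#'   1 = ON, 0 = OFF.
#' @export
make_windows <- function(rec, L, stride = L) {
  stopifnot(is_count(L, 2L), is_count(stride, 1L))
  n <- nrow(rec)
  if (n < L)
    stop_labeled("recording_too_short",
                 "recording of %d samples is shorter than window L=%d", n, L)
  starts <- seq.int(1L, n - L + 1L, by = stride)
  nw <- length(starts)
  x <- array(0, c(nw, L, 2L))
  y <- NULL
  has_lab <- "label" %in% names(rec)
  if (has_lab) y <- matrix(0L, nw, L)
  for (i in seq_len(nw)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    x[i, , 1] <- rec$left_force_n[idx]
    x[i, , 2] <- rec$right_force_n[idx]
    if (has_lab) y[i, ] <- as.integer(rec$label[idx] == "ON")
  }
  structure(list(x = x, y = y, L = L, stride = stride, starts = starts - 1L),
            class = "window_batch")
}

#' Trim long idle runs from a labeled recording
#'
#' Every maximal OFF run longer than `max_off_run` samples is trimmed to
#' `max_off_run` by deleting its central portion, preserving the OFF context
#' on both sides of the neighbouring ON segments. ON samples are never
#' removed and segment order is preserved. The time column is rebuilt as a
#' fresh uniform grid.
#'
#' @param rec A labeled `force_recording`.
#' @param max_off_run Maximum OFF run length to keep, samples (default 224).
#' @return The trimmed `force_recording`.
#' @export
balance_idle <- function(rec, max_off_run = 224L) {
  if (!"label" %in% names(rec))
    stop_labeled("value_error", "balance_idle requires point labels")
  r <- rle(rec$label == "OFF")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, nrow(rec))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] > max_off_run) {
      head_n <- ceiling(max_off_run / 2)
      tail_n <- max_off_run - head_n
      drop <- (starts[i] + head_n):(ends[i] - tail_n)
      keep[drop] <- FALSE
    }
  }
  out <- rec[keep, , drop = FALSE]
  force_recording(out$left_force_n, out$right_force_n, fs = attr(rec, "fs"),
                  label = out$label)
}

#' Nested train/validation/test split
#'
#' First holds out 20% of items as the test set, then 20% of the remainder
#' as validation, giving 64% / 16% / 20% of the full set. The partition is
#' disjoint, covering, and reproducible per seed.
#'
#' @param items Vector or list to split (>= 5 items), or an integer count.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` index vectors into
#'   `items`.
#' @export
split_nested <- function(items, seed = 1L) {
  n <- if (length(items) == 1L && is.numeric(items)) as.integer(items)
       else length(items)
  if (n < 5) stop_labeled("value_error", "need at least 5 items to split")
  with_seed(seed, {
    perm <- sample.int(n)
    n_test <- round(0.2 * n)
    n_val <- round(0.2 * (n - n_test))
    list(test = sort(perm[seq_len(n_test)]),
         validation = sort(perm[n_test + seq_len(n_val)]),
         train = sort(perm[(n_test + n_val + 1L):n]))
  })
}

#' Randomly subsample one class of segments
#'
#' Retains `floor(fraction * count)` randomly chosen members of the given
#' class (by task label); members of other classes are untouched. Original
#' ordering is preserved.
#'
#' @param segments List of `force_segment` objects.
#' @param label Class (task label) to subsample.
#' @param fraction Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @return Filtered list of segments.
#' @export
subsample_class <- function(segments, label, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  task <- vapply(segments, `[[`, "", "task")
  if (!label %in% task)
    stop_labeled("value_error", "label '%s' not present in data", label)
  if (fraction == 1) return(segments)
  in_class <- which(task == label)
  n_keep <- floor(fraction * length(in_class))
  keep_class <- with_seed(seed, sort(sample(in_class, n_keep)))
  keep <- sort(c(keep_class, which(task != label)))
  segments[keep]
}

#' Fit a force segment into a fixed-length window
#'
#' Segments longer than `L` are center-cropped; shorter segments are
#' edge-padded (boundary sample repeated) symmetrically to length `L`.
#'
#' @param segment A `force_segment`.
#' @param L Window length, samples (default 200).
#' @return `L` x 2 force matrix.
#' @export
segment_to_window <- function(segment, L = 200L) {
  n <- length(segment$left)
  if (n < 20) stop_labeled("segment_too_short", "segment shorter than 20 samples")
  m <- cbind(segment$left, segment$right)
  if (n == L) return(m)
  if (n > L) {
    off <- floor((n - L) / 2)
    return(m[(off + 1):(off + L), , drop = FALSE])
  }
  pad_l <- floor((L - n) / 2)
  pad_r <- L - n - pad_l
  rbind(m[rep(1L, pad_l), , drop = FALSE], m,
        m[rep(n, pad_r), , drop = FALSE])
}

#' Resample standardized feature values into a window-length channel
#'
#' The K standardized feature scalars are placed at equally spaced abscissae
#' spanning the window and interpolated by a spline of the configured order
#' to L points (order 0 = step, 1 = linear, >= 2 = cubic spline), with
#' edge-mode boundaries (endpoint values held). The result is the
#' engineered-feature channel appended to the two force channels as the
#' third signal.
#'
#' @param values K standardized feature values (K >= 1).
#' @param L Output length (default 200).
#' @param order Interpolation order (default 3, cubic).
#' @return Numeric vector of length `L`.
#' @export
feature_channel <- function(values, L = 200L, order = 3L) {
  K <- length(values)
  if (K < 1) stop_labeled("value_error", "need at least one feature value")
  if (K > L)
    stop_labeled("value_error", "more feature values (%d) than points (%d)",
                 K, L)
  if (K == 1) return(rep(values, L))
  if (K == L) return(as.numeric(values))
  x <- seq(1, L, length.out = K)
  xout <- seq_len(L)
  if (order == 0) {
    stats::approx(x, values, xout, method = "constant", rule = 2)$y
  } else if (order == 1) {
    stats::approx(x, values, xout, method = "linear", rule = 2)$y
  } else {
    stats::splinefun(x, values, method = "natural")(xout)
  }
}

#' One-hot encode labels over a fixed vocabulary
#'
#' @param labels Character vector of labels.
#' @param vocabulary Label vocabulary fixing column order.
#' @return n x length(vocabulary) 0/1 matrix; every row sums to 1.
#' @export
one_hot <- function(labels, vocabulary) {
  idx <- match(labels, vocabulary)
  if (anyNA(idx))
    stop_labeled("unknown_label", "label '%s' not in vocabulary",
                 labels[which(is.na(idx))[1]])
  m <- matrix(0, length(labels), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Build classifier windows (with optional feature channel) from segments
#'
#' Standardizes each segment window with the supplied training statistics,
#' and optionally appends a third channel carrying the subset-1 engineered
#' features resampled to the window length.
#'
#' @param segments List of `force_segment`.
#' @param std A fitted `standardizer` (training statistics).
#' @param L Window length (default 200).
#' @param feature_stats Optional list(mean, sd) per feature (training
#'   statistics) enabling the feature channel; `NULL` gives 2 channels.
#' @param feature_subset Character vector of feature names for the channel
#'   (default [subset1()]).
#' @param order Spline order for [feature_channel()].
#' @return Array (n, L, C) with C = 2 or 3.
#' @export
segments_to_batch <- function(segments, std, L = 200L, feature_stats = NULL,
                              feature_subset = subset1(), order = 3L) {
  n <- length(segments)
  C <- if (is.null(feature_stats)) 2L else 3L
  x <- array(0, c(n, L, C))
  for (i in seq_len(n)) {
    w <- segment_to_window(segments[[i]], L)
    w <- apply_standardizer(std, w)
    x[i, , 1:2] <- w
    if (C == 3L) {
      fv <- extract_features(segments[[i]])
      vals <- (unlist(fv[feature_subset]) - feature_stats$mean[feature_subset]) /
        feature_stats$sd[feature_subset]
      x[i, , 3] <- feature_channel(vals, L, order)
    }
  }
  x
}

#' Fit per-feature standardization statistics on training segments
#' @param segments Training `force_segment` list.
#' @param feature_subset Features to fit (default [subset1()]).
#' @return List with named `mean` and `sd` vectors (population SD).
#' @export
fit_feature_stats <- function(segments, feature_subset = subset1()) {
  tab <- feature_matrix(segments)
  m <- vapply(feature_subset, function(f) mean(tab[[f]]), 0)
  s <- vapply(feature_subset, function(f) sd_pop(tab[[f]]), 0)
  s[s <= 0] <- 1
  list(mean = m, sd = s)
}
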