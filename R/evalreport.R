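# Metric bundles, cross-validation, feature statistics and the
# surgeon-vs-expert gauge report.

# ROC points with tied scores grouped, so trapezoidal integration equals
# the pairwise-concordance (Mann-Whitney, ties = 0.5) definition exactly.
roc_points <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- y[o]; score <- score[o]
  ths <- unique(score)
  n_pos <- sum(y); n_neg <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- !duplicated(score, fromLast = TRUE)  # last index of each tie group
  data.frame(threshold = c(Inf, score[keep]),
             tpr = c(0, tp[keep] / n_pos),
             fpr = c(0, fp[keep] / n_neg))
}

auc_trapezoid <- function(y, score) {
  r <- roc_points(y, score)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

average_precision <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- y[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Compute a full evaluation report
#'
#' Hard labels are taken at probability 0.5. Sensitivity is the recall of
#' the positive class and specificity the recall of the negative class.
#' AUC is computed by trapezoidal integration of the ROC curve with tied
#' scores grouped (equivalent to pairwise concordance with ties counting
#' one half); macro-AUC is the unweighted mean of the one-vs-rest AUCs.
#' Weighted F1 is the support-weighted mean of per-class F1.
#'
#' @param y_true Class labels.
#' @param probabilities N x 2 matrix with columns named by class (rows sum
#'   to 1), or a numeric vector of positive-class probabilities.
#' @param positive Name of the positive class.
#' @return List of class `eval_report`.
#' @export
compute_metrics <- function(y_true, probabilities, positive) {
  y_true <- as.character(y_true)
  classes <- sort(unique(y_true))
  if (is.matrix(probabilities)) {
    stopifnot(max(abs(rowSums(probabilities) - 1)) < 1e-6)
    p_pos <- probabilities[, positive]
  } else p_pos <- probabilities
  negative <- setdiff(classes, positive)
  single_class <- length(classes) < 2
  if (length(negative) > 1)
    stop_labeled("value_error", "compute_metrics is binary; got %d classes",
                 length(classes))
  pred <- ifelse(p_pos > 0.5, positive,
                 if (single_class) paste0("not_", positive) else negative)
  lev <- if (single_class) c(positive, paste0("not_", positive))
         else c(positive, negative)
  cm <- table(factor(y_true, lev), factor(pred, lev))
  tp <- cm[1, 1]; fn <- sum(cm[1, ]) - tp
  fp <- sum(cm[, 1]) - tp; tn <- sum(cm) - tp - fn - fp
  accuracy <- (tp + tn) / sum(cm)
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1_of <- function(tp, fp, fn) {
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }
  f1 <- c(f1_of(tp, fp, fn), f1_of(tn, fn, fp))
  names(f1) <- lev
  support <- c(sum(cm[1, ]), sum(cm[2, ]))
  weighted_f1 <- sum(f1 * support) / sum(support)
  if (single_class) {
    auc <- NA_real_; macro_auc <- NA_real_; ap <- NA_real_
    roc <- NULL; pr <- NULL
  } else {
    ybin <- y_true == positive
    auc <- auc_trapezoid(ybin, p_pos)
    macro_auc <- mean(c(auc, auc_trapezoid(!ybin, 1 - p_pos)))
    ap <- average_precision(ybin, p_pos)
    roc <- roc_points(ybin, p_pos)
    o <- order(p_pos, decreasing = TRUE)
    tp_cum <- cumsum(ybin[o])
    pr <- data.frame(recall = tp_cum / sum(ybin),
                     precision = tp_cum / seq_along(o))
  }
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, f1 = f1,
                 weighted_f1 = weighted_f1, auc = auc,
                 macro_auc = macro_auc, average_precision = ap,
                 confusion = cm, roc = roc, pr = pr,
                 positive = positive, n = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d  acc %.3f  sens %.3f  spec %.3f  ",
                     "wF1 %.3f  AUC %.3f  AP %.3f\n"),
              x$n, x$accuracy, x$sensitivity, x$specificity, x$weighted_f1,
              x$auc, x$average_precision))
  invisible(x)
}

#' Point-wise weighted F1 for a segmentation mask
#'
#' Convenience wrapper treating each time point as one observation with
#' classes ON/OFF.
#' @param truth,pred Logical or 0/1 vectors (TRUE = ON).
#' @export
pointwise_weighted_f1 <- function(truth, pred) {
  y <- ifelse(as.logical(truth), "ON", "OFF")
  p <- as.numeric(as.logical(pred))
  compute_metrics(y, p, positive = "ON")$weighted_f1
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and seeded; every sample is tested exactly
#' once. `builder(train_x, train_y)` must return an object whose
#' `$predict(x)` gives an N x 2 probability matrix.
#'
#' @param builder Model-fitting closure.
#' @param x Feature table / matrix (rows = samples).
#' @param y Class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param positive Positive class (default first level).
#' @return List with `mean_accuracy`, `sd_accuracy`, `folds` (per-fold
#'   `eval_report`s) and `fold_assignment`.
#' @export
crossvalidate <- function(builder, x, y, k = 5L, seed = 1L,
                          positive = NULL) {
  y <- as.character(y)
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  if (min(table(y)) < k)
    stop_labeled("value_error", "a class has fewer members than k = %d", k)
  positive <- positive %||% sort(unique(y))[1]
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  reports <- vector("list", k)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    model <- builder(x[tr, , drop = FALSE], y[tr])
    probs <- model$predict(x[te, , drop = FALSE])
    reports[[f]] <- compute_metrics(y[te], probs, positive)
    accs[f] <- reports[[f]]$accuracy
  }
  list(mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
       folds = reports, fold_assignment = fold)
}

#' Two-way ANOVA of a feature across task and skill
#'
#' Additive model (no interaction): `value ~ task + skill`. F and p values
#' for each factor are adjusted for the other (drop-one F tests), matching
#' the analysis used to contrast duration structure across tasks versus
#' skill levels.
#'
#' @param values Numeric feature values.
#' @param task,skill Factor labels (>= 2 levels each; >= 3 observations per
#'   crossed cell).
#' @return List with `task` and `skill`, each `c(F, p)`.
#' @export
feature_anova <- function(values, task, skill) {
  task <- factor(task); skill <- factor(skill)
  if (nlevels(task) < 2 || nlevels(skill) < 2)
    stop_labeled("value_error", "both factors need >= 2 levels")
  cells <- table(task, skill)
  if (any(cells < 3))
    stop_labeled("empty_cell",
                 "every task x skill cell needs >= 3 observations")
  fit <- stats::lm(values ~ task + skill)
  dr <- stats::drop1(fit, test = "F")
  list(task = c(F = dr["task", "F value"], p = dr["task", "Pr(>F)"]),
       skill = c(F = dr["skill", "F value"], p = dr["skill", "Pr(>F)"]))
}

GAUGE_METRICS <- c(`Average Force Duration` = "Duration Force",
                   `Range of Forces` = "Range Force",
                   `Force Variability` = "SD",
                   `Force Uncertainty` = "Entropy")

#' Surgeon-vs-expert gauge report
#'
#' For each dashboard index (Average Force Duration, Range of Forces,
#' Force Variability, Force Uncertainty) reports the surgeon's mean, the
#' expert reference mean and SD, and the signed delta (surgeon minus
#' expert). Force Variability maps to the segment SD feature and Force
#' Uncertainty to spectral Entropy.
#'
#' @param surgeon Feature table of the surgeon's segments.
#' @param expert Feature table of the expert reference segments.
#' @return data.frame of class `gauge_report` with one row per index.
#' @export
gauge_report <- function(surgeon, expert) {
  if (nrow(surgeon) == 0 || nrow(expert) == 0)
    stop_labeled("value_error", "both tables must be non-empty")
  need <- unname(GAUGE_METRICS)
  for (tbl_nm in c("surgeon", "expert")) {
    tbl <- if (tbl_nm == "surgeon") surgeon else expert
    miss <- setdiff(need, names(tbl))
    if (length(miss))
      stop_labeled("schema_error", "%s table missing column(s): %s",
                   tbl_nm, paste(miss, collapse = ", "))
  }
  out <- data.frame(
    metric = names(GAUGE_METRICS),
    feature = unname(GAUGE_METRICS),
    surgeon_mean = vapply(GAUGE_METRICS, function(f) mean(surgeon[[f]]), 0),
    expert_mean = vapply(GAUGE_METRICS, function(f) mean(expert[[f]]), 0),
    expert_sd = vapply(GAUGE_METRICS, function(f)
      stats::sd(expert[[f]]) %||% 0, 0),
    row.names = NULL)
  out$expert_sd[is.na(out$expert_sd)] <- 0
  out$delta <- out$surgeon_mean - out$expert_mean
  class(out) <- c("gauge_report", "data.frame")
  out
}

#' Serialize an evaluation or gauge report to JSON
#' @param report An `eval_report` or `gauge_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "eval_report")) {
    obj <- report[c("accuracy", "sensitivity", "specificity",
                    "weighted_f1", "auc", "macro_auc",
                    "average_precision", "n", "positive")]
    obj$f1 <- as.list(report$f1)
    obj$confusion <- as.data.frame.matrix(report$confusion)
  } else obj <- report
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
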