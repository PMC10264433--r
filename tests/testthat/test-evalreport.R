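# exhaustive pairwise-concordance AUC (Mann-Whitney, ties count one half)
oracle_auc <- function(y_pos, score) {
  pos <- score[y_pos]; neg <- score[!y_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

test_that("metrics match hand computation on a fixed confusion matrix", {
  # 7 TP, 3 FN, 2 FP, 8 TN
  y <- c(rep("pos", 10), rep("neg", 10))
  p <- c(rep(0.9, 7), rep(0.1, 3), rep(0.9, 2), rep(0.1, 8))
  r <- compute_metrics(y, p, positive = "pos")
  expect_equal(r$sensitivity, 0.7)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$accuracy, 0.75)
  expect_identical(sum(r$confusion), 20L)
  # weighted F1 recomputed from the confusion matrix
  f1_pos <- 2 * 7 / (2 * 7 + 2 + 3)
  f1_neg <- 2 * 8 / (2 * 8 + 3 + 2)
  expect_equal(r$weighted_f1, (10 * f1_pos + 10 * f1_neg) / 20,
               tolerance = 1e-9)
})

test_that("perfect and uninformative predictions bound the metrics", {
  y <- rep(c("a", "b"), 25)
  p_perf <- ifelse(y == "a", 0.99, 0.01)
  r <- compute_metrics(y, p_perf, positive = "a")
  expect_equal(r$accuracy, 1)
  expect_equal(r$weighted_f1, 1)
  expect_equal(r$auc, 1)
  expect_equal(r$average_precision, 1)

  r0 <- compute_metrics(y, rep(0.5, 50), positive = "a")
  expect_equal(r0$auc, 0.5)   # all tied: concordance one half
})

test_that("trapezoidal AUC equals the exhaustive concordance oracle", {
  with_seed_local(9, {
    for (rep_i in 1:20) {
      n <- sample(10:200, 1)
      y <- sample(c(TRUE, FALSE), n, TRUE)
      if (length(unique(y)) < 2) next
      score <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
      yl <- ifelse(y, "pos", "neg")
      r <- compute_metrics(yl, score, positive = "pos")
      expect_equal(r$auc, oracle_auc(y, score), tolerance = 1e-12)
    }
  })
})

test_that("macro-AUC averages the one-vs-rest AUCs", {
  with_seed_local(10, {
    y <- sample(c("on", "off"), 100, TRUE)
    p <- runif(100)
    r <- compute_metrics(y, p, positive = "on")
    a_on <- oracle_auc(y == "on", p)
    a_off <- oracle_auc(y == "off", 1 - p)
    expect_equal(r$macro_auc, mean(c(a_on, a_off)), tolerance = 1e-12)
  })
})

test_that("cross-validation folds partition the data with stratification", {
  with_seed_local(11, {
    x <- data.frame(f = rnorm(103))
    y <- sample(c("a", "b"), 103, TRUE, prob = c(0.6, 0.4))
    const_model <- function(xx, yy)
      list(predict = function(nx)
        matrix(0.5, nrow(nx), 2, dimnames = list(NULL, c("a", "b"))))
    cv <- crossvalidate(const_model, x, y, k = 5, seed = 2, positive = "a")
    expect_identical(sort(unique(cv$fold_assignment)), 1:5)
    expect_lte(diff(range(table(cv$fold_assignment))), 2)
    # every sample tested exactly once
    expect_identical(sum(table(cv$fold_assignment)), 103L)
    # constant predictions on unbalanced labels: accuracy = majority rate
    expect_equal(cv$mean_accuracy, mean(
      vapply(1:5, function(f) mean(y[cv$fold_assignment == f] != "a"), 0)))

    expect_error(crossvalidate(const_model, x[1:6, , drop = FALSE],
                               c("a", "a", "a", "a", "a", "b"), k = 5,
                               seed = 1),
                 class = "value_error")
  })
})

test_that("two-way ANOVA recovers injected effects", {
  with_seed_local(12, {
    n <- 240
    task <- sample(c("Coagulation", "Pulling"), n, TRUE)
    skill <- sample(c("Expert", "Novice"), n, TRUE)
    # identical group means: p near 1 is not guaranteed, but large
    v0 <- rnorm(n)
    a0 <- feature_anova(v0, task, skill)
    expect_gt(a0$task[["p"]], 0.01)

    v1 <- rnorm(n) + ifelse(task == "Coagulation", 3, 0)
    a1 <- feature_anova(v1, task, skill)
    expect_lt(a1$task[["p"]], 0.001)
    expect_gt(a1$skill[["p"]], 0.05)
  })
})

test_that("balanced two-way ANOVA matches textbook sums of squares", {
  # 2x2 balanced, 3 replicates per cell
  task <- rep(c("A", "A", "B", "B"), each = 3)
  skill <- rep(c("E", "N", "E", "N"), each = 3)
  v <- c(10, 11, 12, 13, 14, 15, 20, 21, 22, 23, 24, 25)
  a <- feature_anova(v, task, skill)
  # hand computation: SS_task = 12*( (11? ) ) — use direct formulas
  gm <- mean(v)
  ss_task <- sum(tapply(v, task, function(g) length(g) * (mean(g) - gm)^2))
  ss_skill <- sum(tapply(v, skill, function(g) length(g) * (mean(g) - gm)^2))
  fit <- lm(v ~ factor(task) + factor(skill))
  ss_res <- sum(residuals(fit)^2)
  f_task <- (ss_task / 1) / (ss_res / (12 - 3))
  f_skill <- (ss_skill / 1) / (ss_res / (12 - 3))
  expect_equal(a$task[["F"]], f_task, tolerance = 1e-9)
  expect_equal(a$skill[["F"]], f_skill, tolerance = 1e-9)

  expect_error(feature_anova(v[1:11], task[1:11], skill[1:11]),
               class = "empty_cell")
})

test_that("gauge report compares surgeon to the expert reference", {
  segs <- generate_dataset(synth_config(), 60, seed = 13)$segments
  tab <- feature_matrix(segs)
  expert <- tab[tab$skill == "Expert", ]
  g_same <- gauge_report(expert, expert)
  expect_equal(g_same$delta, rep(0, 4))
  expect_true(all(g_same$expert_sd >= 0))
  expect_identical(g_same$metric,
                   c("Average Force Duration", "Range of Forces",
                     "Force Variability", "Force Uncertainty"))

  surgeon <- expert
  surgeon$`Duration Force` <- surgeon$`Duration Force` + 2.19
  g <- gauge_report(surgeon, expert)
  expect_equal(g$delta[g$metric == "Average Force Duration"], 2.19,
               tolerance = 1e-9)

  expect_error(gauge_report(expert[, 1:5], expert), class = "schema_error")
  expect_error(gauge_report(expert[0, ], expert), class = "value_error")
})

test_that("reports serialize to JSON", {
  y <- rep(c("a", "b"), 10)
  r <- compute_metrics(y, ifelse(y == "a", 0.8, 0.2), positive = "a")
  f <- withr::local_tempfile(fileext = ".json")
  write_report(r, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$accuracy, 1)
  expect_equal(back$weighted_f1, 1)
})
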