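# Independent brute-force oracles for the moment/extremum/counting
# features, written with explicit loops so they share no code with the
# implementation.
oracle_moments <- function(seg) {
  x <- numeric(length(seg$left))
  for (i in seq_along(x)) x[i] <- (seg$left[i] + seg$right[i]) / 2
  n <- length(x)
  m <- sum(x) / n
  ss <- 0; s3 <- 0; s4 <- 0; sq <- 0
  for (v in x) {
    ss <- ss + (v - m)^2; s3 <- s3 + (v - m)^3; s4 <- s4 + (v - m)^4
    sq <- sq + v * v
  }
  sdp <- sqrt(ss / n)
  xs <- sort(x)
  mx <- xs[n]; mn <- xs[1]
  cross <- 0
  for (i in 2:n)
    if ((x[i] > m) != (x[i - 1] > m) || (x[i] == m) != (x[i - 1] == m))
      cross <- cross + 1
  peaks <- 0
  for (i in 2:(n - 1))
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) peaks <- peaks + 1
  asym <- 0
  for (i in seq_len(n)) asym <- asym + abs(seg$left[i] - seg$right[i])
  list(`Duration Force` = n / 20, `Mean Force` = m,
       `Median Force` = stats::median(x), `Max Force` = mx,
       `Minimum Force` = mn, `Range Force` = mx - mn, SD = sdp,
       RMS = sqrt(sq / n),
       Skewness = if (sdp > 0) (s3 / n) / sdp^3 else 0,
       Kurtosis = if (sdp > 0) (s4 / n) / sdp^4 - 3 else 0,
       `Coefficient of Variance` = if (abs(m) > 1e-12) sdp / abs(m) else 0,
       `Crossing Points` = cross, `Peak Count` = peaks,
       `Prong Asymmetry` = asym / n)
}

test_that("feature vector has exactly 29 canonical entries", {
  fv <- extract_features(toy_segment(200))
  expect_identical(names(fv), feature_names())
  expect_length(fv, 29L)
  expect_true(all(vapply(fv, is.finite, TRUE)))
  m <- cbind(abs(rnorm(50)) + 1, abs(rnorm(50)) + 1)
  expect_length(extract_features(m), 29L)
  expect_error(extract_features(m[1:10, ]), class = "segment_too_short")
})

test_that("moment, extremum and counting features match brute force", {
  for (s in 1:100) {
    seg <- random_segment(seed = s)
    fv <- extract_features(seg)
    orc <- oracle_moments(seg)
    for (nm in names(orc))
      expect_equal(fv[[nm]], orc[[nm]], tolerance = 1e-9, label = nm,
                   expected.label = sprintf("oracle %s (seed %d)", nm, s))
  }
})

test_that("duration reflects the 20 Hz sampling rate", {
  expect_equal(extract_features(toy_segment(200))$`Duration Force`, 10)
  expect_equal(extract_features(toy_segment(242))$`Duration Force`, 12.1)
})

test_that("degenerate and pure-tone segments give analytic features", {
  const <- forcepsml:::new_force_segment(cbind(rep(1, 100), rep(1, 100)),
                                         "Retracting", "Expert", "S01")
  fv <- extract_features(const)
  expect_identical(fv$`Range Force`, 0)
  expect_identical(fv$SD, 0)
  expect_identical(fv$`Coefficient of Variance`, 0)
  expect_identical(fv$`Crossing Points`, 0L)
  expect_identical(fv$Entropy, 0)

  # 5 Hz tone at 20 Hz sampling: dominant frequency 5 Hz, near-zero entropy
  t_s <- (0:199) / 20
  tone <- 1 + 0.5 * sin(2 * pi * 5 * t_s)
  seg <- forcepsml:::new_force_segment(cbind(tone, tone), "Coagulation",
                                       "Expert", "S01")
  fv2 <- extract_features(seg)
  expect_equal(fv2$`Dominant Frequency`, 5)
  expect_lt(fv2$Entropy, 0.05)
  expect_gt(extract_features(random_segment(200, seed = 1))$Entropy,
            fv2$Entropy)
})

test_that("features scale as designed under force rescaling", {
  for (s in 1:20) {
    seg <- random_segment(seed = s)
    k <- 3.7
    seg2 <- seg
    seg2$left <- k * seg$left; seg2$right <- k * seg$right
    a <- extract_features(seg); b <- extract_features(seg2)
    for (nm in c("Coefficient of Variance", "Entropy", "Skewness",
                 "Prong Correlation"))
      expect_equal(b[[nm]], a[[nm]], tolerance = 1e-8, label = nm)
    expect_equal(b$`Range Force`, k * a$`Range Force`, tolerance = 1e-9)
    expect_equal(b$SD, k * a$SD, tolerance = 1e-9)
  }
})

test_that("feature matrix preserves order and matches recomputation", {
  expect_identical(nrow(feature_matrix(list())), 0L)
  segs <- lapply(1:100, function(s) random_segment(seed = s))
  tab <- feature_matrix(segs)
  expect_identical(dim(tab), c(100L, 4L + 29L))
  rng <- vapply(segs, function(s) {
    x <- (s$left + s$right) / 2
    max(x) - min(x)
  }, 0)
  expect_equal(tab$`Range Force`, rng, tolerance = 1e-12)
})

test_that("z-score outlier removal drops only extreme rows", {
  segs <- lapply(1:100, function(s) random_segment(n = 100, seed = s))
  tab <- feature_matrix(segs)
  expect_identical(remove_outliers_z(tab, z = Inf), tab)

  spiked <- tab
  spiked$`Mean Force`[7] <- mean(tab$`Mean Force`) +
    10 * forcepsml:::sd_pop(tab$`Mean Force`)
  out <- remove_outliers_z(spiked, z = 3)
  expect_false(7 %in% out$segment_id)

  same <- tab[rep(1, 10), ]
  expect_identical(nrow(remove_outliers_z(same)), 10L)  # zero-variance cols
})

test_that("feature ranking finds separating features and handles nulls", {
  with_seed_local(5, {
    n <- 120
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("f", 1:6))))
    y <- rep(c("a", "b"), each = n / 2)
    X$f3 <- ifelse(y == "a", 0, 5) + rnorm(n, 0, 0.1)  # perfect separator
    rk <- rank_features(X, y, seed = 1)
    expect_identical(rk$feature[1], "f3")
    expect_identical(nrow(rk), 6L)

    Xnull <- as.data.frame(matrix(rnorm(n * 5), n))
    rknull <- rank_features(Xnull, y, seed = 2)
    expect_lt(max(abs(rknull$knn_importance)), 0.15)
  })
  expect_error(rank_features(data.frame(a = 1:10), rep("a", 10)),
               class = "value_error")
})

test_that("the dashboard subset is fixed and canonical", {
  expect_identical(subset1(), c("Duration Force", "Range Force", "Entropy",
                                "Heterogeneity"))
  expect_identical(subset1(), subset1())
  expect_true(all(subset1() %in% feature_names()))
})
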