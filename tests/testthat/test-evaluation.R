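test_that("confusion metrics follow their standard definitions", {
  m <- confusion_metrics(tp = 44, fp = 11, tn = 27, fn = 9)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$accuracy, 71 / 91)
  m2 <- confusion_metrics(tp = 44, fp = 11, tn = 9, fn = 27)
  expect_equal(m2$f1, 2 * 44 / (2 * 44 + 11 + 27))

  perfect <- confusion_metrics(tp = 10, fp = 0, tn = 5, fn = 0)
  for (v in c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1"))
    expect_equal(perfect[[v]], 1)

  # undefined ratios come back missing, not zero
  m3 <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_true(is.na(m3$ppv))
  expect_equal(m3$specificity, 1)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("accuracy decomposes over prevalence exactly", {
  set.seed(9)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    if (counts[1] + counts[4] == 0 || counts[2] + counts[3] == 0) next
    m <- confusion_metrics(counts[1], counts[2], counts[3], counts[4])
    prev <- (m$tp + m$fn) / m$n
    expect_equal(m$accuracy,
                 m$sensitivity * prev + m$specificity * (1 - prev))
  }
})

test_that("AUROC equals the all-pairs concordance oracle", {
  expect_equal(auroc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  expect_equal(auroc(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(c(-25, -7), c(TRUE, FALSE), direction = "lower"), 1)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    scores <- sample(-5:5, n, replace = TRUE)  # heavy ties on purpose
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auroc(scores, labels),
                 auroc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("label-independent scores give a null AUROC near one half", {
  set.seed(5)
  expect_equal(auroc(rnorm(10000), runif(10000) < 0.5), 0.5,
               tolerance = 0.02)
})

test_that("the ROC sweep and Youden cutoff behave on known geometries", {
  # fully separated classes: cutoff lies in the separating gap
  r <- roc_curve(c(-30, -25, -10, -2), c(TRUE, TRUE, FALSE, FALSE),
                 direction = "lower")
  expect_equal(r$auroc, 1)
  expect_gte(r$youden_cutoff, -25)
  expect_lt(r$youden_cutoff, -10)
  i <- match(r$youden_cutoff, r$thresholds)
  expect_equal(r$se[i] + r$sp[i] - 1, 1)

  # a single threshold grid point is returned as the cutoff
  r1 <- roc_curve(c(3, 3, 3), c(TRUE, FALSE, TRUE))
  expect_equal(youden_cutoff(r1), 3)

  # sensitivity is monotone along the threshold sweep
  set.seed(2)
  scores <- rnorm(60); labels <- runif(60) < 0.4
  r2 <- roc_curve(scores, labels, direction = "lower")
  expect_true(all(diff(r2$se) >= 0))   # looser threshold, higher Se
  expect_true(all(diff(r2$sp) <= 0))
  expect_equal(r2$auroc, auroc_bruteforce(-scores, labels),
               tolerance = 1e-12)
})

test_that("the Youden cutoff tracks the equal-density boundary", {
  # two Gaussians as configured for the lesion classes; the Youden-optimal
  # threshold converges on the point where the class densities cross
  m1 <- -25.08; s1 <- 37.98; m2 <- -7.08; s2 <- 42.6
  boundary <- uniroot(function(x) {
    dnorm(x, m1, s1) - dnorm(x, m2, s2)
  }, interval = c(m1 - 5, m2 + 5))$root
  set.seed(3)
  n <- 10000
  scores <- c(rnorm(n / 2, m1, s1), rnorm(n / 2, m2, s2))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  r <- roc_curve(scores, labels, direction = "lower")
  expect_lt(abs(r$youden_cutoff - boundary), 3)
})

test_that("the group comparison gates between t and rank tests", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$test, "mann-whitney")   # n = 3: Shapiro gate refuses t
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, wilcox_enum_p(c(1, 2, 3), c(4, 5, 6)))

  big <- compare_groups(rnorm(50), rnorm(50, 5))
  expect_lt(big$p_value, 1e-6)
})

test_that("class-sized AREA draws separate significantly in most runs", {
  hits <- 0L
  for (seed in 1:500) {
    set.seed(seed)
    mal <- rnorm(51, -25.08, 37.98)
    ben <- rnorm(40, -7.08, 42.6)
    if (compare_groups(mal, ben)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, 250)   # majority of seeds
})

test_that("the proportion test reproduces pooled-z arithmetic", {
  expect_equal(round(two_proportion_test(66, 91, 71, 91), 2), 0.39)
  expect_equal(two_proportion_test(10, 40, 10, 40), 1)
  expect_equal(two_proportion_test(7, 91, 7, 91), 1)

  p_f <- two_proportion_test(0, 10, 10, 10, method = "fisher")
  expect_lt(p_f, 1e-4)
  # hypergeometric enumeration oracle for the Fisher branch
  probs <- dhyper(0:10, 10, 10, 10)
  expect_equal(p_f, sum(probs[probs <= dhyper(0, 10, 10, 10) + 1e-12]))
})

test_that("the AREA regression recovers hand-computed fits", {
  r <- suppressWarnings(area_regression(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$slope, 1, tolerance = 1e-12)

  r2 <- area_regression(c(0, 2), c(1, 5))
  expect_equal(r2$intercept, 1)
  expect_equal(r2$slope, 2)

  expect_error(area_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("regression intervals achieve near-nominal coverage", {
  cover_i <- 0L; cover_s <- 0L
  n_rep <- 500L
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    x <- rnorm(30, 0, 2)
    y <- -12.21 + 0.16 * x + rnorm(30)
    r <- area_regression(x, y)
    tq <- qt(0.975, 28)
    if (abs(r$intercept + 12.21) <= tq * r$se_intercept)
      cover_i <- cover_i + 1L
    if (abs(r$slope - 0.16) <= tq * r$se_slope) cover_s <- cover_s + 1L
  }
  expect_gt(cover_i / n_rep, 0.91); expect_lt(cover_i / n_rep, 0.98)
  expect_gt(cover_s / n_rep, 0.91); expect_lt(cover_s / n_rep, 0.98)
})

test_that("detection rate arithmetic and guards", {
  expect_equal(detection_rate(20, 71)$percent, 28)
  expect_equal(detection_rate(0, 71)$percent, 0)
  expect_equal(detection_rate(71, 71)$percent, 100)
  expect_error(detection_rate(5, 0), "denominator")
  expect_error(detection_rate(10, 5), "more correct types")
})
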