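# ROC/AUC, threshold reports, cross-validated performance, comparison
# statistics and output histograms.

test_that("ROC curve endpoints, monotonicity and separable AUC", {
  rc <- rocAndAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(rc@auc, 1.0)
  expect_equal(rc@tpr[1], 0); expect_equal(rc@fpr[1], 0)
  expect_equal(rc@tpr[length(rc@tpr)], 1)
  expect_equal(rc@fpr[length(rc@fpr)], 1)
  expect_true(all(diff(rc@tpr) >= 0) && all(diff(rc@fpr) >= 0))
  expect_error(rocAndAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("trapezoidal AUC equals the pair-counting statistic", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(rocAndAuc(scores, labels)@auc, bruteAuc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- rocAndAuc(scores, labels)@auc
  expect_equal(rocAndAuc(qlogis(scores), labels)@auc, a)
  expect_equal(rocAndAuc(scores^3, labels)@auc, a)
})

test_that("threshold reports count calls with ties positive", {
  r <- thresholdReport(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(r$tpr, 100); expect_equal(r$fpr, 0)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(2, 0, 2, 0))
  r0 <- thresholdReport(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0)
  expect_equal(r0$tpr, 100); expect_equal(r0$fpr, 100)
  # tie at the cutoff counts as positive
  rt <- thresholdReport(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(rt$tp, 1); expect_equal(rt$fp, 0)
  # sweep: TPR and FPR non-increasing in tau; corner reproduces (100, 100)
  set.seed(47)
  scores <- runif(50); labels <- rbinom(50, 1, 0.5); labels[1:2] <- 0:1
  taus <- seq(0, 1, 0.05)
  reps <- lapply(taus, function(tau) thresholdReport(scores, labels, tau))
  expect_true(all(diff(vapply(reps, `[[`, 0, "tpr")) <= 0))
  expect_true(all(diff(vapply(reps, `[[`, 0, "fpr")) <= 0))
  expect_equal(reps[[1]]$sensitivity, 100)
  expect_equal(reps[[1]]$specificity, 0)
})

test_that("proportions test reproduces the exact conditional law and is symmetric", {
  # identical proportions
  expect_equal(propEqualityTest(5, 10, 5, 10)$p.value, 1)
  # symmetry in group order
  a <- propEqualityTest(10, 40, 20, 40)
  b <- propEqualityTest(20, 40, 10, 40)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, b$statistic)
  # degenerate margins
  expect_true(propEqualityTest(0, 8, 0, 9)$degenerate)
  expect_equal(propEqualityTest(0, 8, 0, 9)$p.value, 1)
  expect_equal(propEqualityTest(8, 8, 9, 9)$p.value, 1)
  # the continuity-corrected chi-square approximates the exact
  # margin-conditioned two-sided p on well-filled tables
  for (tb in list(c(10, 40, 20, 40), c(15, 60, 30, 60), c(8, 30, 18, 30))) {
    expect_equal(propEqualityTest(tb[1], tb[2], tb[3], tb[4])$p.value,
                 exactPropP(tb[1], tb[2], tb[3], tb[4]), tolerance = 0.03)
  }
})

test_that("pooled t test matches a hand computation", {
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_lt(twoSampleT(c(0, 0.01, 0, 0.01), c(1, 1.01, 1, 0.99))$p.value,
            0.001)
  expect_true(twoSampleT(c(2, 2), c(5, 5))$degenerate)
  # worked example, recomputed from the pooled-variance formula
  a <- c(12.1, 14.3, 13.5, 12.9, 13.8)
  b <- c(15.2, 14.8, 16.1, 15.5)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pHand <- 2 * pt(-abs(tHand), length(a) + length(b) - 2)
  res <- twoSampleT(a, b)
  expect_equal(res$statistic, tHand)
  expect_equal(res$p.value, pHand)
})

test_that("output histograms conserve mass on the log-spaced bins", {
  h <- outputHistogram(rep(0.3, 12))
  expect_equal(h$percent[h$lower == 0.2], 100)
  expect_equal(sum(h$percent), 100)
  set.seed(53)
  h2 <- outputHistogram(runif(20000), edges = seq(0, 1, 0.1))
  expect_equal(sum(h2$percent), 100, tolerance = 1e-9)
  expect_true(all(abs(h2$percent - 10) < 1.5))
  expect_error(outputHistogram(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(outputHistogram(0.5, edges = c(0, 0.5, 0.4, 1)), "edges")
  # endpoint scores land in the extreme bins
  h3 <- outputHistogram(c(0, 1, 1e-5))
  expect_equal(h3$count[1], 2)
  expect_equal(h3$count[nrow(h3)], 1)
})

test_that("cross-validated AUC recovers separation and the permutation null", {
  # strongly separated classes (clear orientation and length differences)
  cfg <- synthConfig(nPos = 24, nNeg = 48, pSensePos = 0.95,
                     pSenseNeg = 0.05,
                     intronLog10Mean = c(pos = 3.0, neg = 5.0),
                     distanceLog10Mean = c(pos = 2.0, neg = 4.3),
                     seed = 5)
  enc <- encodeInsertions(generateTrainingLike(cfg))
  plan <- buildCvPlan(24, 48, permutations = 2, seed = 5)
  ens <- trainEnsemble(plan, enc$x, enc$target, nReinits = 5)
  cvp <- cvPerformance(ens, enc$x, enc$target)
  expect_gt(cvp$meanAuc, 0.95)
  expect_length(cvp$aucs, 6)
  # shuffled targets: chance-level discrimination (the plan convention is
  # kept by shuffling the encoded rows within each class block instead)
  encNull <- enc
  set.seed(99)
  encNull$x <- enc$x[sample(nrow(enc$x)), ]
  ensNull <- trainEnsemble(plan, encNull$x, enc$target, nReinits = 5)
  cvpNull <- cvPerformance(ensNull, encNull$x, enc$target)
  expect_lt(abs(cvpNull$meanAuc - 0.5), 0.18)
})
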