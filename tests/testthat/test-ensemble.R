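# Cross-validation plan, ensemble training, consolidation, prediction.

test_that("stratified splitting reproduces the curated-set geometry", {
  plan <- buildCvPlan(33, 117, permutations = 1, seed = 4)
  expect_length(plan@splits, 3)
  for (s in plan@splits) {
    expect_length(s$test, 50)
    expect_length(s$train, 100)
    expect_equal(sum(s$test <= 33), 11)   # 11 positives per test subgroup
    expect_equal(sum(s$test > 33), 39)    # 39 negatives
  }
  tests <- lapply(plan@splits, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:150)     # disjoint cover
})

test_that("minimal and remainder class sizes split correctly", {
  plan <- buildCvPlan(3, 3, permutations = 1, seed = 1)
  for (s in plan@splits) {
    expect_equal(sum(s$test <= 3), 1)
    expect_equal(sum(s$test > 3), 1)
  }
  plan2 <- buildCvPlan(34, 118, permutations = 1, seed = 1)
  posSizes <- sort(vapply(plan2@splits, function(s) sum(s$test <= 34), 0L))
  negSizes <- sort(vapply(plan2@splits, function(s) sum(s$test > 34), 0L))
  expect_equal(posSizes, c(11L, 11L, 12L))
  expect_equal(negSizes, c(39L, 39L, 40L))
  allTest <- unlist(lapply(plan2@splits, `[[`, "test"))
  expect_equal(sort(allTest), 1:152)
  expect_false(anyDuplicated(allTest) > 0)
  expect_error(buildCvPlan(2, 10), "at least")
})

test_that("permutations differ while each remains a stratified partition", {
  plan <- buildCvPlan(12, 24, permutations = 4, seed = 9)
  expect_length(plan@splits, 12)
  byPerm <- split(plan@splits,
                  vapply(plan@splits, `[[`, 0L, "permutation"))
  expect_length(byPerm, 4)
  partitions <- lapply(byPerm, function(ss)
    lapply(ss, `[[`, "test"))
  for (ss in partitions) {
    expect_equal(sort(unlist(ss)), 1:36)
  }
  expect_false(identical(partitions[[1]], partitions[[2]]))
})

test_that("ensemble bookkeeping, leakage-freedom and reproducibility", {
  fx <- smallEnsembleFixture()
  ens <- fx$ens
  expect_length(ens@members, 3 * 5)
  expect_equal(ens@splitId, rep(1:3, each = 5))
  expect_equal(ens@reinitId, rep(1:5, 3))
  # leakage audit: no member was trained on its split's held-out cases
  for (m in seq_along(ens@members)) {
    s <- ens@plan@splits[[ens@splitId[m]]]
    expect_length(intersect(s$train, s$test), 0)
  }
  # bit-identical replay from the same seeds
  ens2 <- trainEnsemble(fx$plan, fx$enc$x, fx$enc$target, nReinits = 5)
  expect_identical(lapply(ens@members, ervImpact:::mlpToPar),
                   lapply(ens2@members, ervImpact:::mlpToPar))
  expect_identical(consolidate(ens, fx$enc$x), consolidate(ens2, fx$enc$x))
})

test_that("ensemble training validates the plan/data pairing", {
  fx <- smallEnsembleFixture()
  expect_error(trainEnsemble(fx$plan, fx$enc$x[1:10, ], fx$enc$target[1:10]),
               "case count")
  expect_error(trainEnsemble(fx$plan, fx$enc$x, rev(fx$enc$target)),
               "positives first")
})

test_that("consolidation is the arithmetic mean of member outputs", {
  set.seed(31)
  members <- lapply(1:7, function(i) initMlp(i))
  X <- matrix(runif(32), ncol = 4)
  each <- vapply(members, function(m) mlpForward(m, X), numeric(8))
  expect_equal(consolidate(members, X), rowMeans(each), tolerance = 1e-12)
  # identical members collapse to the single-member output
  expect_equal(consolidate(members[c(1, 1, 1)], X),
               mlpForward(members[[1]], X))
  # convex hull
  cons <- consolidate(members, X)
  expect_true(all(cons >= apply(each, 1, min) - 1e-12))
  expect_true(all(cons <= apply(each, 1, max) + 1e-12))
  expect_error(consolidate(list(), X), "empty")
})

test_that("prediction thresholds, ordering and per-record failures", {
  fx <- smallEnsembleFixture()
  poly <- generatePolymorphicLike(fx$cfg)
  pr <- predict(fx$ens, poly)
  expect_equal(nrow(pr), 134)
  expect_true(all(pr$likelihood > 0 & pr$likelihood < 1))
  expect_true(all(predict(fx$ens, poly, threshold = 0)$call == "positive"))
  expect_true(all(predict(fx$ens, poly, threshold = 1)$call == "negative"))
  # order equivariance
  idx <- rev(seq_len(134))
  pr2 <- predict(fx$ens, poly[idx])
  expect_equal(pr2$likelihood, pr$likelihood[idx])
  expect_equal(pr2$id, pr$id[idx])
  # a record that cannot be encoded yields an NA entry, not an abort
  tab <- as.data.frame(poly)
  tab$family[3] <- "LINE"
  expect_warning(pr3 <- predict(fx$ens, tab), "could not be encoded")
  expect_true(is.na(pr3$likelihood[3]))
  expect_equal(pr3$likelihood[-3], pr$likelihood[-3])
  # a strong positive-like record scores above threshold
  strong <- ErvSet(id = "s", family = "ETnMusD", orientation = "sense",
                   intron_size_bp = 300, exon_distance_bp = 20)
  expect_gt(predict(fx$ens, strong)$likelihood, 0.5)
})
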