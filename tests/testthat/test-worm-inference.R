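# Frequency estimation, group tests, fold changes and map distances.

test_that("frequencies reproduce the scored marker-exchange counts", {
  wt <- estimateFrequency(2, nTotal = 3175)
  expect_equal(frequencyPct(wt), 0.06)
  mut <- estimateFrequency(43, nTotal = 2625)
  expect_equal(frequencyPct(mut), 1.64)
  zero <- estimateFrequency(0, nTotal = 500)
  expect_equal(frequencyPct(zero), 0)
  expect_equal(zero@ci95[1L], 0)
  expect_true(wt@ci95[1L] <= frequencyPct(wt) &&
                frequencyPct(wt) <= wt@ci95[2L])
  expect_error(estimateFrequency(1, nTotal = 0), "positive")
})

test_that("tallies are scored through the cross design", {
  cross <- defaultCross()
  tally <- simulateProgeny(cross, r = 0.02, n = 2e4, seed = 11)
  est <- estimateFrequency(tally, cross)
  rec <- phenotypeClasses(cross)
  k <- sum(tally[names(tally) %in% rec$phenotype[rec$recombinant]])
  expect_equal(est@nRecombinant, k)
  expect_equal(est@nTotal, 2e4)
  bad <- c(tally, mystery = 5L)
  expect_error(estimateFrequency(bad, cross), "not in the cross design")
})

test_that("frequency estimates recover the model expectation", {
  cross <- defaultCross()
  ep <- expectedProgeny(cross, r = 0.01)
  expected <- 100 * sum(ep$probability[ep$recombinant])
  ests <- vapply(1:100, function(s)
    frequencyPct(estimateFrequency(
      simulateProgeny(cross, r = 0.01, n = 1e5, seed = s), cross)),
    numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - expected), 3 * se)
  # estimator consistency at large n
  big <- estimateFrequency(simulateProgeny(cross, r = 0.01, n = 1e6,
                                           seed = 1), cross)
  seBig <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 1e6)
  expect_lt(abs(frequencyPct(big) - expected), 3 * seBig + 0.005)
})

test_that("the test-selection rule switches on group totals at 1000", {
  small <- compareFrequencies(c(1, 10), c(9, 10))
  expect_equal(small$test, "fisher")
  # exact hypergeometric two-sided p for the 1/9 vs 9/1 table
  expect_equal(small$p.value, 202 / 184756, tolerance = 1e-12)
  big <- compareFrequencies(c(2, 3175), c(43, 2625))
  expect_equal(big$test, "chisq")
  edge <- compareFrequencies(c(1, 1000), c(50, 5000))
  expect_equal(edge$test, "fisher")
  just <- compareFrequencies(c(1, 1001), c(50, 5000))
  expect_equal(just$test, "chisq")
  ident <- compareFrequencies(c(5, 100), c(5, 100))
  expect_equal(ident$p.value, 1)
  expect_error(compareFrequencies(c(0, 0), c(0, 0)), "positive")
})

test_that("fold changes follow the round/truncate conventions", {
  wt <- estimateFrequency(2, nTotal = 3175)     # 0.06%
  rt <- estimateFrequency(43, nTotal = 2625)    # 1.64%
  hm <- estimateFrequency(166, nTotal = 2500)   # 6.64%
  f1 <- foldChange(rt, wt)
  expect_equal(f1$foldRound, 27)
  expect_equal(f1$foldTrunc, 27)
  expect_false(f1$conventionsDiffer)
  f2 <- foldChange(hm, wt)
  expect_equal(f2$foldTrunc, 110)
  expect_true(f2$conventionsDiffer)
  same <- foldChange(rt, rt)
  expect_equal(same$foldRound, 1)
  zero <- foldChange(rt, estimateFrequency(0, nTotal = 100))
  expect_true(is.na(zero$foldRound))
  expect_match(zero$note, "denominator")
})

test_that("map distance estimators behave on closed-form inputs", {
  d <- twoMarkerCross("dpy-17", "unc-36")
  est <- mapDistance(c(95, 1000), d)
  expect_equal(est@distanceCM, 100 * (1 - sqrt(1 - 2 * 0.095)))
  expect_equal(est@distanceCM, 10, tolerance = 1e-3)
  zero <- mapDistance(c(0, 1000), d)
  expect_equal(zero@distanceCM, 0)
  direct <- mapDistance(c(95, 1000), d, estimator = "direct")
  expect_equal(direct@distanceCM, 9.5)
  expect_error(mapDistance(c(600, 1000), d), "0.5")
  expect_true(est@ci95CM[1L] < est@distanceCM &&
                est@distanceCM < est@ci95CM[2L])
})

test_that("the corrected estimator recovers the true crossover rate", {
  d <- twoMarkerCross("dpy-17", "unc-36")
  ests <- vapply(1:100, function(s) {
    tally <- simulateTwoMarkerProgeny(0.05, 5000, d, seed = s)
    mapDistance(tally, d)@distanceCM
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 5), 3 * se)
  # the direct estimator is biased low in expectation (R < p)
  directs <- vapply(1:40, function(s) {
    tally <- simulateTwoMarkerProgeny(0.05, 5000, d, seed = s)
    mapDistance(tally, d, estimator = "direct")@distanceCM
  }, numeric(1))
  expect_lt(mean(directs), 5)
})

test_that("two-marker class probabilities match first principles", {
  d <- twoMarkerCross("a", "b")
  p <- 0.1
  probs <- expectedTwoMarkerClasses(p, d)
  expect_equal(sum(probs), 1)
  expect_equal(unname(probs["a only"]), p / 2 - p^2 / 4)
  expect_equal(unname(probs["a b"]), ((1 - p) / 2)^2)
  expect_equal(unname(probs["a only"] + probs["b only"]), p - p^2 / 2)
})
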