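test_that("fitted anchors are the requested quantiles of positive means", {
  set.seed(31)
  vals <- matrix(runif(600, 0, 4), 300, 2)
  vals[sample(600, 30)] <- 0  # zeros must be excluded from anchoring
  prof <- profileFromMeans(vals)
  spec <- fitFuzzySpec(prof, nLevels = 4, quantiles = c(0.25, 0.5, 0.9))
  pos <- vals[vals > 0]
  expect_equal(anchors(spec),
               c(0, unname(quantile(pos, c(0.25, 0.5, 0.9)))))
  expect_identical(levelLabels(spec),
                   c("NotExpressed", "Low", "Medium", "High"))
  # uniform on (0, 4]: anchors land near (0, 1, 2, 3.6)
  expect_equal(anchors(spec), c(0, 1, 2, 3.6), tolerance = 0.15)
})

test_that("two levels anchor at the median; degenerate input is rejected", {
  vals <- matrix(c(1, 2, 3, 4, 0, 5), 3, 2)
  prof <- profileFromMeans(vals)
  spec <- fitFuzzySpec(prof, nLevels = 2)
  expect_equal(anchors(spec), c(0, median(vals[vals > 0])))

  zero <- profileFromMeans(matrix(0, 3, 2))
  expect_error(fitFuzzySpec(zero), "fewer distinct positive")
  expect_error(fitFuzzySpec(prof, nLevels = 4, quantiles = c(0.5, 0.25, 0.9)),
               "strictly increasing")
})

test_that("triangular memberships interpolate, clamp, and are crisp at anchors", {
  spec <- FuzzySpec(c(0, 1, 2, 4))
  mu <- fuzzifyValues(c(0, 1, 1.5, 2, 3, 4, 9), spec)
  expect_equal(unname(mu[1, ]), c(1, 0, 0, 0))     # at a_0
  expect_equal(unname(mu[2, ]), c(0, 1, 0, 0))     # at a_1
  expect_equal(unname(mu[3, ]), c(0, 0.5, 0.5, 0)) # midway a_1..a_2
  expect_equal(unname(mu[4, ]), c(0, 0, 1, 0))
  expect_equal(unname(mu[5, ]), c(0, 0, 0.5, 0.5)) # midway a_2..a_4
  expect_equal(unname(mu[6, ]), c(0, 0, 0, 1))     # at a_3
  expect_equal(unname(mu[7, ]), c(0, 0, 0, 1))     # beyond the last anchor
  expect_error(fuzzifyValues(-0.1, spec), "nonnegative")
  expect_error(FuzzySpec(c(0, 2, 1)), "strictly increasing")
  expect_error(FuzzySpec(c(1, 2, 3)), "first anchor")
})

test_that("memberships form a partition of unity on random inputs", {
  set.seed(17)
  for (anch in list(c(0, 1, 2, 4), c(0, 0.3, 5), c(0, 1, 1.1, 2, 10))) {
    spec <- FuzzySpec(anch)
    x <- c(0, anch, runif(1000, 0, 1.5 * max(anch)))
    mu <- fuzzifyValues(x, spec)
    expect_lt(max(abs(rowSums(mu) - 1)), 1e-12)
    expect_true(all(mu >= 0 & mu <= 1))
  }
})

test_that("larger inputs shift the membership-weighted mean level upward", {
  spec <- FuzzySpec(c(0, 1, 2, 4))
  x <- sort(runif(500, 0, 6))
  mu <- fuzzifyValues(x, spec)
  meanLevel <- mu %*% seq_len(4)
  expect_true(all(diff(meanLevel) >= -1e-12))
})

test_that("fuzzify gates undetected genes and preserves group structure", {
  sce <- smallCohort(seed = 13)
  prof <- pseudobulkProfile(sce, verbose = FALSE)
  spec <- fitFuzzySpec(prof)
  tens <- suppressMessages(fuzzify(prof, spec, detectionGate = 0.05))
  mu <- memberships(tens)
  expect_lte(dim(mu)[1], nrow(profileMeans(prof)))
  s <- apply(mu, c(1, 2), sum)
  expect_lt(max(abs(s - 1)), 1e-12)
  # gate off keeps everything
  tens0 <- fuzzify(prof, spec, detectionGate = 0)
  expect_identical(dim(memberships(tens0))[1], nrow(profileMeans(prof)))
  expect_identical(conditionSeries(tens), levels(sce$condition))
})
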