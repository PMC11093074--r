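test_that("crisp thresholding is inclusive and monotone in the threshold", {
  M <- c(A = 0.6, B = 0.5, C = 0.49)
  expect_setequal(crispOverlap(M, 0.5), c("A", "B"))
  expect_identical(crispOverlap(c(A = 1, B = 0.999), 1.0), "A")
  expect_error(crispOverlap(M, 0), "threshold")

  set.seed(3)
  M <- setNames(runif(200), paste0("g", 1:200))
  sizes <- vapply(seq(0.05, 0.95, by = 0.05),
                  function(th) length(crispOverlap(M, th)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("hypergeometric p matches the combinatorial oracle", {
  # the worked case: universe 20, set 5, hits 6, overlap 4
  gsc <- GeneSetCollection(list(S = paste0("g", 1:5)),
                           universe = paste0("g", 1:20))
  hits <- paste0("g", c(1:4, 10, 11))
  res <- hypergeomEnrichment(hits, gsc)
  expect_identical(res$overlap, 4L)
  expect_equal(res$p, hyperTailOracle(20, 5, 6, 4), tolerance = 1e-14)

  # sweep all configurations at a few universe sizes
  for (N in c(5, 9, 12)) {
    for (K in 1:N) for (n in 1:N) for (k in 0:min(K, n)) {
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(p, hyperTailOracle(N, K, n, k), tolerance = 1e-12)
    }
  }
})

test_that("degenerate hit sets behave exactly", {
  uni <- paste0("g", 1:12)
  gsc <- GeneSetCollection(list(S1 = uni[1:4], S2 = uni[5:6]),
                           universe = uni)
  res <- hypergeomEnrichment(uni, gsc)         # hits = universe
  expect_equal(res$overlap, res$size)
  expect_equal(res$p, c(1, 1))

  tiny <- hypergeomEnrichment(uni[7:8], gsc)   # no overlap with S1
  expect_true(all(tiny$p >= 0 & tiny$p <= 1))
  expect_gt(tiny$p[tiny$set == "S1"], 0.5)

  expect_error(hypergeomEnrichment(character(0), gsc), "empty hit")
  expect_error(hypergeomEnrichment("absent", gsc), "outside the universe")
  expect_warning(
    hypergeomEnrichment(uni[1:2],
                        GeneSetCollection(list(S1 = uni[1:3], SX = "zz"),
                                          universe = uni)),
    "dropped")
})

test_that("results do not depend on input ordering and BH is monotone", {
  uni <- paste0("g", 1:50)
  sets <- list(A = uni[1:10], B = uni[5:20], C = uni[30:34])
  hits <- uni[c(1:8, 30, 31)]
  r1 <- hypergeomEnrichment(hits, GeneSetCollection(sets, uni))
  r2 <- hypergeomEnrichment(rev(hits),
                            GeneSetCollection(sets[c(2, 3, 1)], rev(uni)))
  m <- match(r1$set, r2$set)
  expect_equal(r1$p, r2$p[m])
  expect_equal(r1$q, r2$q[m])
  ord <- order(r1$p)
  expect_true(all(diff(r1$q[ord]) >= -1e-15))
  expect_equal(r1$q, p.adjust(r1$p, "BH"))
})

test_that("weighted scores are exact and seeds make permutation p reproducible", {
  uni <- paste0("g", 1:40)
  sets <- list(S1 = uni[1:5], S2 = uni[6:15])
  gsc <- GeneSetCollection(sets, uni)

  # identical memberships: score is |S| * m exactly; permutations tie
  M <- setNames(rep(0.3, 40), uni)
  res <- weightedEnrichment(M, gsc, nPerm = 199, seed = 4)
  expect_equal(res$score, c(5, 10) * 0.3)
  expect_equal(res$p, c(1, 1))  # every permutation ties the observed score

  set.seed(9)
  M <- setNames(runif(40), uni)
  a <- weightedEnrichment(M, gsc, nPerm = 199, seed = 7)
  b <- weightedEnrichment(M, gsc, nPerm = 199, seed = 7)
  d <- weightedEnrichment(M, gsc, nPerm = 199, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$p, d$p))
  expect_error(weightedEnrichment(M, gsc, nPerm = 50, seed = 1), "at least 100")
})

test_that("a strongly planted set is detected by the permutation test", {
  uni <- sprintf("g%03d", 1:500)
  planted <- uni[1:20]
  M <- setNames(c(rep(0.9, 20), rep(0.1, 480)), uni)
  gsc <- GeneSetCollection(list(planted = planted,
                                background = uni[100:119]), uni)
  res <- weightedEnrichment(M, gsc, nPerm = 999, seed = 21)
  expect_lte(res$p[res$set == "planted"], 1 / 1000 + 1e-12)
  expect_gt(res$p[res$set == "background"], 0.05)
})

test_that("crisp memberships give permutation p consistent with the exact test", {
  uni <- sprintf("g%03d", 1:80)
  hits <- uni[c(1:12, 40:47)]           # 20 hits
  M <- setNames(as.numeric(uni %in% hits), uni)
  gsc <- GeneSetCollection(list(S = uni[1:16]), uni)
  exact <- hypergeomEnrichment(hits, gsc)$p
  nPerm <- 4999
  perm <- weightedEnrichment(M, gsc, nPerm = nPerm, seed = 12)$p
  se <- sqrt(exact * (1 - exact) / nPerm)
  expect_lt(abs(perm - exact), 3 * se + 2 / nPerm)
})
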