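lv4 <- c("NotExpressed", "Low", "Medium", "High")

test_that("path enumeration is complete, lexicographic, and capped", {
  expect_identical(nrow(enumeratePaths(4, 3)), 64L)
  p22 <- enumeratePaths(2, 2)
  expect_equal(unname(p22),
               rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L)))
  expect_error(enumeratePaths(4, 11, cap = 1e6), "cap")  # 4^11 > 1e6
  expect_identical(nrow(enumeratePaths(2, 10)), 1024L)   # under the cap
})

test_that("path membership multiplies per-condition memberships", {
  muA <- rbind(g1 = c(0.2, 0.8, 0, 0))       # t1: NE 0.2, Low 0.8
  muB <- rbind(g1 = c(0, 0, 0.3, 0.7))       # t2: Med 0.3, High 0.7
  tens <- tensorFromMemberships(list(k = list(t1 = muA, t2 = muB)),
                                c("t1", "t2"), lv4)
  expect_equal(pathMembership(tens, "g1", "k", c(2L, 4L)), 0.8 * 0.7)
  expect_equal(pathMembership(tens, "g1", "k", c(2L, 4L), combiner = "min"),
               0.7)
  # a zero membership annihilates the path under both combiners
  expect_equal(pathMembership(tens, "g1", "k", c(1L, 1L)), 0)
  expect_equal(pathMembership(tens, "g1", "k", c(1L, 1L), combiner = "min"), 0)
  expect_error(pathMembership(tens, "nope", "k", c(1L, 1L)), "unknown gene")
  expect_error(pathMembership(tens, "g1", "zz", c(1L, 1L)), "unknown cluster")
})

test_that("crisp genes concentrate all weight on their single path", {
  crisp <- function(l) { m <- matrix(0, 2, 4); m[, l] <- 1
                         rownames(m) <- c("g1", "g2"); m }
  tens <- tensorFromMemberships(
    list(k = list(t1 = crisp(1), t2 = crisp(2), t3 = crisp(4))),
    c("t1", "t2", "t3"), lv4)
  w <- flowWeights(tens, "k")
  expect_equal(unname(w["NotExpressed-Low-High"]), 2)
  expect_equal(sum(w), 2)  # everything else is zero
  # per gene: membership 1 for exactly one path, 0 for all others
  pm <- vapply(seq_len(nrow(enumeratePaths(4, 3))), function(i)
    pathMembership(tens, "g1", "k", enumeratePaths(4, 3)[i, ]), 0)
  expect_identical(sum(pm == 1), 1L)
  expect_identical(sum(pm == 0), 63L)
})

test_that("factorized flow weights equal brute-force path enumeration", {
  tens <- randomTensor(G = 200, C = 3, T = 3, L = 3, seed = 8)
  paths <- enumeratePaths(3, 3)
  for (cl in clusterNames(tens)) {
    for (comb in c("product", "min")) {
      fast <- unname(flowWeights(tens, cl, comb, paths))
      slow <- bruteForceWeights(tens, cl, paths, comb)
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  }
})

test_that("flow weights conserve the gene count under the product combiner", {
  tens <- randomTensor(G = 200, C = 3, T = 3, L = 4, seed = 15)
  G <- dim(memberships(tens))[1]
  for (cl in clusterNames(tens))
    expect_lt(abs(sum(flowWeights(tens, cl)) - G), 1e-9 * G)
})

test_that("pattern selection matches an explicit predicate oracle", {
  pat <- FlowPattern("final_above_all_prior", minFinalLevel = "Medium")
  sel <- selectFlows(pat, lv4, 3)
  paths <- enumeratePaths(4, 3)
  oracle <- apply(paths, 1, function(p)
    p[3] > max(p[1:2]) && p[3] >= 3)
  expect_identical(nrow(sel), 13L)           # 2*2 (final Med) + 3*3 (final High)
  expect_equal(unname(sel), unname(paths[oracle, , drop = FALSE]))

  expect_identical(nrow(selectFlows(FlowPattern("constant"), lv4, 3)), 4L)
  sel2 <- selectFlows(FlowPattern("final_above_all_prior",
                                  minFinalLevel = "High"), lv4, 2)
  expect_identical(nrow(sel2), 3L)
  expect_error(selectFlows(FlowPattern("any", minFinalLevel = "Huge"), lv4, 3),
               "not a valid level")

  down <- selectFlows(FlowPattern("final_below_all_prior"), lv4, 2)
  expect_true(all(down[, 2] < down[, 1]))
  nd <- selectFlows(FlowPattern("nondecreasing"), lv4, 3)
  expect_true(all(apply(nd, 1, function(p) all(diff(p) >= 0))))
  expect_identical(nrow(nd), 20L)  # C(4+3-1, 3) multisets ordered
})

test_that("selected-set membership plus complement membership is 1 per gene", {
  tens <- randomTensor(G = 50, C = 2, T = 3, L = 4, seed = 23)
  pat <- FlowPattern("final_above_all_prior", minFinalLevel = "L2")
  sel <- selectFlows(pat, levelLabels(tens), 3)
  paths <- enumeratePaths(4, 3)
  selKey <- apply(sel, 1, paste, collapse = ".")
  comp <- paths[!apply(paths, 1, paste, collapse = ".") %in% selKey, ]
  inSel <- clusterMembershipMatrix(tens, sel)
  inComp <- clusterMembershipMatrix(tens, comp)
  expect_equal(unname(inSel + inComp),
               matrix(1, 50, 2), tolerance = 1e-12)
  expect_true(all(inSel >= 0 & inSel <= 1 + 1e-12))
})

test_that("cluster scoping combines memberships by min/max/single", {
  tens <- randomTensor(G = 30, C = 3, T = 3, L = 4, seed = 29)
  pat <- FlowPattern("final_above_all_prior", minFinalLevel = "L2")
  sel <- selectFlows(pat, levelLabels(tens), 3)
  per <- clusterMembershipMatrix(tens, sel)
  allM <- combinedMembership(tens, sel, "all_clusters")
  anyM <- combinedMembership(tens, sel, "any_cluster")
  oneM <- combinedMembership(tens, sel, "single", cluster = "c2")
  expect_equal(allM, apply(per, 1, min))
  expect_equal(anyM, apply(per, 1, max))
  expect_equal(unname(oneM), unname(per[, "c2"]))
  expect_true(all(anyM >= allM))
  expect_error(combinedMembership(tens, sel[0, , drop = FALSE], "all_clusters"),
               "empty")
})

test_that("gene ranking is descending with deterministic lexicographic ties", {
  M <- c(A = 0.9, B = 0.1, C = 0.9)
  tg <- topGenes(M, 2)
  expect_identical(tg$gene, c("A", "C"))
  expect_identical(topGenes(M, 10)$gene, c("A", "C", "B"))
  expect_error(topGenes(M, 0), "at least 1")
})

test_that("raising final-condition expression never lowers increased-flow membership", {
  spec <- FuzzySpec(c(0, 1, 2, 4))
  pat <- FlowPattern("final_above_all_prior", minFinalLevel = "Medium")
  sel <- selectFlows(pat, levelLabels(spec), 3)
  base <- c(0.6, 0.8)  # fixed prior-condition expression
  grid <- seq(0, 6, by = 0.1)
  m <- vapply(grid, function(xf) {
    mus <- fuzzifyValues(c(base, xf), spec)
    tens <- tensorFromMemberships(
      list(k = list(t1 = rbind(g = mus[1, ]), t2 = rbind(g = mus[2, ]),
                    t3 = rbind(g = mus[3, ]))),
      c("t1", "t2", "t3"), levelLabels(spec))
    unname(combinedMembership(tens, sel, "single", cluster = "k"))
  }, 0)
  expect_true(all(diff(m) >= -1e-12))
})

test_that("flowAnalysis assembles weights, selection and ranking consistently", {
  sce <- smallCohort(seed = 19)
  prof <- pseudobulkProfile(sce, verbose = FALSE)
  tens <- fuzzify(prof, fitFuzzySpec(prof), detectionGate = 0)
  pat <- FlowPattern("final_above_all_prior", minFinalLevel = "Medium")
  res <- flowAnalysis(tens, pat)
  G <- dim(memberships(tens))[1]
  expect_identical(nrow(res@paths), 64L)
  expect_identical(sum(res@selected), 13L)
  expect_lt(max(abs(colSums(res@weights) - G)), 1e-9 * G)
  expect_equal(memberships(res),
               apply(res@clusterMembership, 1, min))
  tab <- flowWeightTable(res)
  expect_identical(nrow(tab), 64L)
  expect_identical(sum(tab$selected), 13L)
})
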