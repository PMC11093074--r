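test_that("the generator is seed-deterministic and produces valid counts", {
  a <- smallCohort(seed = 100)
  b <- smallCohort(seed = 100)
  d <- smallCohort(seed = 101)
  expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_identical(
    SummarizedExperiment::assay(SingleCellExperiment::altExp(a, "ADT")),
    SummarizedExperiment::assay(SingleCellExperiment::altExp(b, "ADT")))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(d)))

  m <- SummarizedExperiment::assay(a)
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  expect_identical(ncol(a), 2L * 3L * 2L * 40L)  # C x T x S x cells
  expect_identical(nrow(S4Vectors::metadata(a)$ground_truth), 10L)
})

test_that("planted genes are refused when they exceed the eligible pool", {
  expect_error(
    simulateCiteSeq(syntheticSpec(nGenes = 20, plantedGenes = 50, seed = 1)),
    "planted subset larger")
})

test_that("without planted genes, condition differences center at zero", {
  sce <- smallCohort(seed = 7, plantedGenes = 0L, nGenes = 500L)
  prof <- pseudobulkProfile(sce, verbose = FALSE)
  m <- profileMeans(prof)
  first <- rowMeans(m[, prof@condition == "healthy", drop = FALSE])
  last <- rowMeans(m[, prof@condition == "infection", drop = FALSE])
  diffs <- last - first
  tstat <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
  expect_lt(abs(tstat), 4)
})

test_that("planted fold changes appear in the raw pseudobulk means", {
  sce <- smallCohort(seed = 77, nGenes = 500L, nClusters = 2L,
                     cellsPerSample = 100L, plantedGenes = 25L)
  counts <- SummarizedExperiment::assay(sce)
  truth <- S4Vectors::metadata(sce)$ground_truth$gene
  inFinal <- sce$condition == "infection"
  inFirst <- sce$condition == "healthy"
  ratio <- rowMeans(counts[truth, inFinal]) / rowMeans(counts[truth, inFirst])
  # >= 200 cells per group: the planted moment ratio sits within 20% of 4
  expect_lt(abs(median(ratio) / 4 - 1), 0.2)
  expect_true(all(ratio > 2))
  bg <- setdiff(rownames(sce), truth)[1:100]
  bgRatio <- rowMeans(counts[bg, inFinal]) / rowMeans(counts[bg, inFirst])
  expect_lt(abs(median(bgRatio, na.rm = TRUE) - 1), 0.2)
})

test_that("empirical dispersion is consistent with the NB parameter", {
  spec <- syntheticSpec(nGenes = 200L, nClusters = 1L,
                        conditions = c("a", "b"), samplesPerCondition = 1L,
                        cellsPerSample = 1000L, plantedGenes = 0L,
                        dispersion = 0.3, seed = 55)
  sce <- simulateCiteSeq(spec)
  m <- SummarizedExperiment::assay(sce)[, sce$condition == "a"]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 0.5
  thetaHat <- median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_gt(thetaHat, 0.2)
  expect_lt(thetaHat, 0.4)
})

test_that("recovery evaluation matches its definition and null expectation", {
  expect_equal(truthEval(c("g1", "g9", "g2"), c("g1", "g2"), 3), 1)
  expect_equal(truthEval(c("g1", "g9", "g2"), c("g1", "g2"), 1), 0.5)
  expect_equal(truthEval(c("g1"), c("g1", "g2"), 0), 0)
  expect_equal(truthEval(data.frame(gene = c("a", "b")),
                         data.frame(gene = "b"), 2), 1)

  # random ranking: expected fraction at k = n*K/N / K = k/N
  set.seed(61)
  genes <- sprintf("g%04d", 1:5000)
  planted <- sample(genes, 50)
  fr <- replicate(300, truthEval(sample(genes), planted, 60))
  expect_lt(abs(mean(fr) - 60 / 5000), 0.004)
})
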