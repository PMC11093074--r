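test_that("no cell passes positive thresholds on an all-zero ADT matrix", {
  adt <- matrix(0L, 2, 5, dimnames = list(c("CD45", "MHC1"), paste0("c", 1:5)))
  mask <- callCells(adt, c("CD45", "MHC1"),
                    thresholds = c(CD45 = 1, MHC1 = 1), verbose = FALSE)
  expect_false(any(mask))
})

test_that("a cell must reach the threshold for every required antibody", {
  adt <- rbind(CD45 = c(50, 50, 1), MHC1 = c(30, 1, 30))
  colnames(adt) <- paste0("c", 1:3)
  mask <- callCells(adt, c("CD45", "MHC1"),
                    thresholds = c(CD45 = 10, MHC1 = 10), verbose = FALSE)
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  expect_error(callCells(adt, c("CD45", "CD15"),
                         thresholds = c(CD45 = 1, CD15 = 1)),
               "absent")
})

test_that("raising any threshold never adds a cell (monotonicity)", {
  set.seed(42)
  adt <- matrix(rpois(2 * 300, 20), 2,
                dimnames = list(c("A", "B"), paste0("c", 1:300)))
  base <- callCells(adt, c("A", "B"), thresholds = c(A = 10, B = 10),
                    verbose = FALSE)
  for (bump in list(c(A = 15, B = 10), c(A = 10, B = 25), c(A = 30, B = 30))) {
    higher <- callCells(adt, c("A", "B"), thresholds = bump, verbose = FALSE)
    expect_true(all(!higher | base))  # higher => base
  }
})

test_that("background-quantile thresholds separate a bimodal stain", {
  sce <- smallCohort(seed = 5, adtStainedFraction = 0.5, nGenes = 50L,
                     cellsPerSample = 100L)
  adt <- SingleCellExperiment::altExp(sce, "ADT")
  stained <- adt$stained
  mask <- callCells(adt, c("CD45", "MHC1"),
                    background = !stained, backgroundQuantile = 0.99,
                    verbose = FALSE)
  expect_lte(mean(mask != stained), 0.01)
})

test_that("antibody calling keeps low-RNA cells that a UMI filter drops", {
  # a genuine cell with only 50 transcripts but clear surface staining
  rna <- matrix(0L, 10, 3,
                dimnames = list(paste0("g", 1:10), c("lowRNA", "b", "c")))
  rna["g1", "lowRNA"] <- 50L
  rna[, "b"] <- 20L   # 200 UMIs
  rna[, "c"] <- 15L   # 150 UMIs
  adt <- rbind(CD45 = c(120, 110, 1), MHC1 = c(90, 100, 2))
  colnames(adt) <- colnames(rna)
  called <- callCells(adt, c("CD45", "MHC1"),
                      thresholds = c(CD45 = 10, MHC1 = 10), verbose = FALSE)
  kept <- umiFilter(rna, 100)
  expect_true(called["lowRNA"])
  expect_false(kept["lowRNA"])
  expect_true(called["b"] && kept["b"])
})

test_that("the UMI cutoff is inclusive and matches an explicit recount", {
  m <- matrix(0L, 3, 3, dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  m[1, ] <- c(99L, 100L, 101L)
  expect_identical(sum(umiFilter(m, 100)), 2L)
  expect_error(umiFilter(m, 0), "positive integer")

  set.seed(7)
  big <- matrix(rpois(50 * 200, 1), 50,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:200)))
  expect_true(all(umiFilter(big, 1)))  # no all-zero columns here
  mask <- umiFilter(big, 60)
  recount <- vapply(seq_len(ncol(big)), function(j) sum(big[, j]) >= 60, TRUE)
  expect_identical(unname(mask), recount)
})
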