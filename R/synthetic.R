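#' Construct a SyntheticSpec
#'
#' Defaults emulate a modest CITE-seq cohort: 5,000 genes over 5 clusters x
#' an ordered three-condition series (healthy, sterile inflammation,
#' infection), 2 samples per condition and 100 cells per (cluster,
#' condition, sample) — 200 cells per pseudobulk group.  RNA counts are
#' negative binomial (dispersion 0.3) around log-normal baseline gene
#' means; 50 planted genes receive a 4-fold increase in the final condition
#' in all clusters.  Planted genes are drawn from the 25th-75th percentile
#' band of baseline means: a fold change on an essentially unexpressed gene
#' is undetectable and one on an already maximal gene is not a level shift,
#' so moderately expressed genes are where a planted pattern is
#' biologically meaningful.  Antibody captures are a two-component negative
#' binomial mixture (stained mean 100 vs background mean 2, dispersion
#' 0.1).
#'
#' @param nGenes,nClusters,conditions,samplesPerCondition,cellsPerSample
#'   cohort dimensions; see [SyntheticSpec-class].
#' @param baselineLogMean,baselineLogSd log-normal parameters of baseline
#'   mean counts per cell.
#' @param dispersion NB dispersion of RNA counts.
#' @param plantedGenes,plantedFoldChange,plantedConditions,plantedClusters,plantedBaselineQuantiles
#'   the planted pattern; \code{plantedConditions} defaults to the final
#'   condition and \code{plantedClusters} (character(0)) to all clusters.
#' @param antibodies,adtStainedMean,adtBackgroundMean,adtStainedFraction,adtDispersion
#'   antibody capture model.
#' @param seed mandatory integer seed.
#' @return A [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nGenes = 100, nClusters = 2, cellsPerSample = 20, seed = 1)
#' @export
syntheticSpec <- function(nGenes = 5000L, nClusters = 5L,
                          conditions = c("healthy", "stroke", "infection"),
                          samplesPerCondition = 2L, cellsPerSample = 100L,
                          baselineLogMean = -1, baselineLogSd = 1,
                          dispersion = 0.3,
                          plantedGenes = 50L, plantedFoldChange = 4,
                          plantedConditions = NULL, plantedClusters = NULL,
                          plantedBaselineQuantiles = c(0.25, 0.75),
                          antibodies = c("CD45", "MHC1"),
                          adtStainedMean = 100, adtBackgroundMean = 2,
                          adtStainedFraction = 1, adtDispersion = 0.1,
                          seed) {
  if (missing(seed)) stop("an explicit seed is mandatory", call. = FALSE)
  if (is.null(plantedConditions))
    plantedConditions <- conditions[length(conditions)]
  new("SyntheticSpec",
      nGenes = as.integer(nGenes), nClusters = as.integer(nClusters),
      conditions = as.character(conditions),
      samplesPerCondition = as.integer(samplesPerCondition),
      cellsPerSample = as.integer(cellsPerSample),
      baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
      dispersion = dispersion,
      plantedGenes = as.integer(plantedGenes),
      plantedFoldChange = plantedFoldChange,
      plantedConditions = as.character(plantedConditions),
      plantedClusters = if (is.null(plantedClusters)) character(0)
                        else as.character(plantedClusters),
      plantedBaselineQuantiles = plantedBaselineQuantiles,
      antibodies = as.character(antibodies),
      adtStainedMean = adtStainedMean,
      adtBackgroundMean = adtBackgroundMean,
      adtStainedFraction = adtStainedFraction,
      adtDispersion = adtDispersion,
      seed = as.integer(seed))
}

#' Simulate a CITE-seq style cohort with planted flow patterns
#'
#' Generates RNA counts (negative binomial around log-normal baseline gene
#' means, with the planted fold changes applied in the target (cluster,
#' condition) blocks), antibody capture counts (stained/background NB
#' mixture), and per-cell annotation.  All randomness derives from the
#' spec's seed; the same spec is byte-identical across runs.
#'
#' @param spec a [SyntheticSpec-class] from [syntheticSpec()].
#' @return A \link[SingleCellExperiment]{SingleCellExperiment}: RNA counts
#'   in \code{counts}, antibody counts in \code{altExp(, "ADT")} (with a
#'   logical \code{stained} column in its colData), cell annotation
#'   (\code{sample_id}, \code{condition}, \code{cluster}) in
#'   \code{colData}, planted flags in \code{rowData}, and the ground-truth
#'   table in \code{metadata()$ground_truth}.
#' @export
simulateCiteSeq <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  with_local_seed(spec@seed, {
    G <- spec@nGenes
    geneIds <- sprintf("gene%05d", seq_len(G))
    baseline <- rlnorm(G, spec@baselineLogMean, spec@baselineLogSd)

    qs <- quantile(baseline, spec@plantedBaselineQuantiles, names = FALSE)
    eligible <- which(baseline >= qs[1L] & baseline <= qs[2L])
    if (spec@plantedGenes > length(eligible))
      stop("planted subset larger than the eligible gene pool", call. = FALSE)
    planted <- sort(sample(eligible, spec@plantedGenes))

    clusters <- paste0("c", seq_len(spec@nClusters) - 1L)
    targetClusters <- if (length(spec@plantedClusters)) spec@plantedClusters
                      else clusters
    bad <- setdiff(spec@plantedConditions, spec@conditions)
    if (length(bad))
      stop("planted condition(s) not in the series: ",
           paste(bad, collapse = ", "), call. = FALSE)

    blocks <- expand.grid(cluster = clusters, condition = spec@conditions,
                          sample = seq_len(spec@samplesPerCondition),
                          stringsAsFactors = FALSE)
    nCells <- nrow(blocks) * spec@cellsPerSample
    counts <- matrix(0L, G, nCells)
    cellCluster <- character(nCells)
    cellCondition <- character(nCells)
    cellSample <- character(nCells)
    size <- 1 / spec@dispersion
    col <- 0L
    for (b in seq_len(nrow(blocks))) {
      mu <- baseline
      if (blocks$condition[b] %in% spec@plantedConditions &&
          blocks$cluster[b] %in% targetClusters)
        mu[planted] <- mu[planted] * spec@plantedFoldChange
      n <- spec@cellsPerSample
      counts[, col + seq_len(n)] <-
        rnbinom(G * n, size = size, mu = mu)  # mu recycles down each column
      cellCluster[col + seq_len(n)] <- blocks$cluster[b]
      cellCondition[col + seq_len(n)] <- blocks$condition[b]
      cellSample[col + seq_len(n)] <-
        paste0(blocks$condition[b], "_s", blocks$sample[b])
      col <- col + n
    }
    cellIds <- sprintf("cell%06d", seq_len(nCells))
    dimnames(counts) <- list(geneIds, cellIds)

    stained <- as.logical(rbinom(nCells, 1L, spec@adtStainedFraction))
    adtSize <- 1 / spec@adtDispersion
    adt <- t(vapply(spec@antibodies, function(ab) {
      mu <- ifelse(stained, spec@adtStainedMean, spec@adtBackgroundMean)
      rnbinom(nCells, size = adtSize, mu = mu)
    }, numeric(nCells)))
    dimnames(adt) <- list(spec@antibodies, cellIds)

    nP <- length(planted)
    truth <- data.frame(
      gene = geneIds[planted],
      baseline_mean = baseline[planted],
      fold_change = rep(spec@plantedFoldChange, nP),
      conditions = rep(paste(spec@plantedConditions, collapse = ","), nP),
      clusters = rep(paste(targetClusters, collapse = ","), nP))

    adtSE <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = adt),
      colData = S4Vectors::DataFrame(stained = stained, row.names = cellIds))
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        sample_id = cellSample,
        condition = factor(cellCondition, levels = spec@conditions),
        cluster = cellCluster, row.names = cellIds),
      rowData = S4Vectors::DataFrame(
        baseline_mean = baseline, planted = seq_len(G) %in% planted,
        row.names = geneIds))
    SingleCellExperiment::altExp(sce, "ADT") <- adtSE
    S4Vectors::metadata(sce)$ground_truth <- truth
    S4Vectors::metadata(sce)$spec <- spec
    sce
  })
}

#' Recovery of planted genes in a ranked list
#'
#' @param ranked character vector of gene ids ranked best first, or the
#'   data.frame returned by [topGenes()].
#' @param truth character vector of planted gene ids, or the ground-truth
#'   table from [simulateCiteSeq()].
#' @param k depth of the ranked list to examine.
#' @return Fraction of planted genes among the top \code{k}, in [0, 1].
#' @examples
#' truthEval(c("g1", "g9", "g2"), c("g1", "g2"), k = 3)
#' @export
truthEval <- function(ranked, truth, k) {
  if (is.data.frame(ranked)) ranked <- ranked$gene
  if (is.data.frame(truth)) truth <- truth$gene
  if (k <= 0) return(0)
  mean(truth %in% head(ranked, k))
}
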