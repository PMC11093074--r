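#' Per-cell module score against expression-matched controls
#'
#' Scores a gene set in every cell as the mean normalized expression of the
#' set genes minus the mean normalized expression of control genes.
#' Controls are matched on average expression: genes are binned into
#' \code{nBins} equal-frequency bins of their across-cell mean, and each set
#' gene draws \code{nCtrl} control genes (excluding the set itself) from its
#' own bin; the control draws are pooled with multiplicity so that control
#' bins carry exactly the set's bin weighting.  The subtraction removes the
#' expression-magnitude component, so under a null (no coordinated signal in
#' the set) scores center near 0.
#'
#' @param x gene x cell matrix of \emph{normalized} expression (same
#'   normalization as [pseudobulkProfile()], e.g. from
#'   [normalizeCounts()]), or a SingleCellExperiment with a
#'   \code{logcounts} assay.
#' @param geneSet character vector; must intersect the matrix genes (an
#'   error lists missing symbols otherwise).
#' @param nBins number of average-expression bins (default 24; reduced when
#'   there are fewer genes than bins).
#' @param nCtrl control genes drawn per set gene (default 100; draws are
#'   without replacement within a bin when possible).
#' @param seed integer seed; identical seeds give identical scores.
#' @param cells optional subset of cells to score; binning, control
#'   selection and scores are computed from these cells only, so the result
#'   does not depend on cells outside the subset.
#' @return Named numeric vector, one score per scored cell.
#' @export
moduleScore <- function(x, geneSet, nBins = 24L, nCtrl = 100L, seed = 1L,
                        cells = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    an <- SummarizedExperiment::assayNames(x)
    x <- SummarizedExperiment::assay(x,
      if ("logcounts" %in% an) "logcounts" else an[[1L]])
  }
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  genes <- rownames(x)
  found <- intersect(geneSet, genes)
  if (!length(found))
    stop("gene set disjoint from the matrix; missing: ",
         paste(head(setdiff(geneSet, genes), 5L), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(geneSet, genes)
  if (length(missing))
    message(sprintf("moduleScore: %d set gene(s) not in the matrix, ignored",
                    length(missing)))
  gm <- Matrix::rowMeans(x)
  nBins <- min(as.integer(nBins), length(gm))
  # equal-frequency bins on the gene-mean distribution (ranks, ties split
  # deterministically), used for control matching
  bin <- ceiling(rank(gm, ties.method = "first") * nBins / length(gm))
  setIdx <- match(found, genes)
  # controls are non-set genes from each set gene's bin, kept as a multiset
  # (nCtrl draws per set gene) so control bins are weighted exactly like the
  # set's; a bin made up entirely of set genes falls back to including them
  ctrl <- with_local_seed(seed, {
    unlist(lapply(setIdx, function(i) {
      pool <- setdiff(which(bin == bin[i]), setIdx)
      if (!length(pool)) pool <- which(bin == bin[i])
      if (length(pool) >= nCtrl) sample(pool, nCtrl)
      else sample(pool, nCtrl, replace = TRUE)
    }), use.names = FALSE)
  })
  setMean <- Matrix::colMeans(x[setIdx, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(x[ctrl, , drop = FALSE])
  score <- setMean - ctrlMean
  names(score) <- colnames(x)
  score
}
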