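#' Call cells from antibody capture counts
#'
#' Marks a cell as called when its capture count reaches the threshold for
#' \emph{every} required antibody.  Intended for CITE-seq experiments where
#' cell populations with very low RNA content (e.g. neutrophils) would be
#' lost by transcript-based filtering: surface staining (such as CD45 plus
#' MHC class I) identifies genuine cells independently of their RNA yield.
#'
#' Thresholds are either given explicitly per antibody, or derived from a
#' declared background population as an upper quantile of its counts
#' (default the 99th percentile), in which case \code{background} is
#' required.
#'
#' @param adt antibody x cell count matrix (matrix, Matrix, or a
#'   SingleCellExperiment whose \code{counts} assay holds the captures).
#' @param requiredAntibodies character; must all be present in
#'   \code{rownames(adt)}.
#' @param thresholds named numeric, explicit threshold per required
#'   antibody; \code{NULL} to use the background-quantile rule.
#' @param background logical mask or indices of background cells (empty
#'   droplets or a negative population), required when \code{thresholds} is
#'   \code{NULL}.
#' @param backgroundQuantile quantile of the background counts used as
#'   threshold (default 0.99).
#' @param verbose report the thresholds used and the number of cells called.
#' @return Named logical vector over cells, \code{TRUE} = called.
#' @examples
#' adt <- rbind(CD45 = c(50, 1, 40), MHC1 = c(30, 0, 2))
#' colnames(adt) <- paste0("c", 1:3)
#' callCells(adt, c("CD45", "MHC1"), thresholds = c(CD45 = 10, MHC1 = 10))
#' @export
callCells <- function(adt, requiredAntibodies, thresholds = NULL,
                      background = NULL, backgroundQuantile = 0.99,
                      verbose = TRUE) {
  m <- .as_counts(adt)
  missing <- setdiff(requiredAntibodies, rownames(m))
  if (length(missing))
    stop("required antibody absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(thresholds)) {
    if (is.null(background))
      stop("either explicit 'thresholds' or a declared 'background' population is required",
           call. = FALSE)
    bg <- m[requiredAntibodies, background, drop = FALSE]
    thresholds <- apply(as.matrix(bg), 1L, quantile,
                        probs = backgroundQuantile, names = FALSE)
    names(thresholds) <- requiredAntibodies
  } else {
    if (is.null(names(thresholds)) && length(thresholds) == length(requiredAntibodies))
      names(thresholds) <- requiredAntibodies
    missing <- setdiff(requiredAntibodies, names(thresholds))
    if (length(missing))
      stop("no threshold supplied for: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  sub <- as.matrix(m[requiredAntibodies, , drop = FALSE])
  mask <- colSums(sub >= thresholds[requiredAntibodies]) == length(requiredAntibodies)
  names(mask) <- colnames(m)
  if (verbose)
    message(sprintf("callCells: %d / %d cells called (thresholds: %s)",
                    sum(mask), length(mask),
                    paste(sprintf("%s>=%.3g", requiredAntibodies,
                                  thresholds[requiredAntibodies]),
                          collapse = ", ")))
  mask
}

#' Filter cells by total transcript count
#'
#' Keeps cells whose per-cell UMI total reaches \code{cutoff}; the boundary
#' is inclusive (total == cutoff is kept).
#'
#' @param rna gene x cell counts (matrix, Matrix or SingleCellExperiment).
#' @param cutoff positive integer minimum UMI total (default 100).
#' @return Named logical vector over cells.
#' @examples
#' m <- matrix(c(99, 0, 100, 0, 0, 101), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' umiFilter(m, 100)
#' @export
umiFilter <- function(rna, cutoff = 100) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff != floor(cutoff))
    stop("'cutoff' must be a positive integer", call. = FALSE)
  m <- .as_counts(rna)
  totals <- Matrix::colSums(m)
  mask <- totals >= cutoff
  names(mask) <- colnames(m)
  mask
}

#' Downsample per-sample cell tables and pool them
#'
#' Each sample contributes at most \code{nPerSample} rows, chosen uniformly
#' without replacement under the given seed; samples smaller than the cap
#' keep all their rows (with a warning).  The per-sample identity of each
#' row is preserved in the pooled table.
#'
#' @param tables list of data.frames, one per sample; each must carry a
#'   \code{sample_id} column (constant within a table).
#' @param nPerSample positive integer cap per sample (e.g. 20000 cells per
#'   individual before pooling a cohort).
#' @param seed integer seed; identical seeds give identical selections.
#' @return Pooled data.frame with \code{sum(pmin(nPerSample, sizes))} rows.
#' @export
downsampleAndPool <- function(tables, nPerSample, seed) {
  if (!is.list(tables) || !length(tables))
    stop("'tables' must be a nonempty list of per-sample tables", call. = FALSE)
  if (!is.numeric(nPerSample) || nPerSample < 1)
    stop("'nPerSample' must be positive", call. = FALSE)
  picks <- with_local_seed(seed, {
    lapply(tables, function(tab) {
      n <- nrow(tab)
      if (n <= nPerSample) {
        if (n < nPerSample)
          warning(sprintf("sample '%s' has only %d rows (< cap %d); keeping all",
                          as.character(tab$sample_id[1L]), n, nPerSample))
        tab
      } else {
        tab[sort(sample.int(n, nPerSample)), , drop = FALSE]
      }
    })
  })
  pooled <- do.call(rbind, c(picks, list(make.row.names = FALSE)))
  rownames(pooled) <- NULL
  pooled
}
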