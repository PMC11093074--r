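#' Library-size normalize counts
#'
#' Scales every cell to a fixed total (default 10,000 counts) and applies
#' \code{log1p} — the conventional single-cell normalization.  Cells with a
#' zero total are left at zero.
#'
#' @param x gene x cell counts (matrix, Matrix or SingleCellExperiment).
#' @param scaleFactor per-cell target total (default 1e4).
#' @return Dense or sparse numeric matrix of normalized values, same
#'   dimnames as the input.
#' @examples
#' normalizeCounts(matrix(c(4L, 0L, 6L, 10L), 2,
#'                        dimnames = list(c("g1", "g2"), c("a", "b"))))
#' @export
normalizeCounts <- function(x, scaleFactor = 1e4) {
  m <- .as_counts(x)
  totals <- Matrix::colSums(m)
  scale <- ifelse(totals > 0, scaleFactor / totals, 0)
  if (methods::is(m, "sparseMatrix")) {
    norm <- m %*% Matrix::Diagonal(x = scale)
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(m)
  } else {
    norm <- log1p(sweep(m, 2L, scale, "*"))
  }
  norm
}

#' Aggregate single cells into a grouped pseudobulk profile
#'
#' For every (gene, cluster, condition) group: the mean of the normalized
#' (per-cell scaled, log1p) expression over member cells, the fraction of
#' member cells with a raw count > 0, and the cell count.  Groups with zero
#' cells are omitted and reported.  These per-group summaries are the input
#' to fuzzification and flow analysis.
#'
#' @param x gene x cell counts (matrix, Matrix or SingleCellExperiment; for
#'   an annotated SingleCellExperiment \code{cluster}/\code{condition}
#'   default to the same-named \code{colData} columns).
#' @param cluster cluster label per cell.
#' @param condition condition label per cell; a factor's level order (or
#'   \code{conditions}) declares the ordered condition series.
#' @param conditions optional explicit ordered condition series.
#' @param scaleFactor normalization target total (default 1e4).
#' @param verbose report omitted empty groups.
#' @return A [GroupedProfile-class].
#' @export
pseudobulkProfile <- function(x, cluster = NULL, condition = NULL,
                              conditions = NULL, scaleFactor = 1e4,
                              verbose = TRUE) {
  m <- .as_counts(x)
  if (methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(cluster) && "cluster" %in% colnames(cd)) cluster <- cd$cluster
    if (is.null(condition) && "condition" %in% colnames(cd)) condition <- cd$condition
  }
  if (is.null(cluster) || is.null(condition))
    stop("every cell needs a cluster and a condition label", call. = FALSE)
  if (length(cluster) != ncol(m) || length(condition) != ncol(m))
    stop("'cluster' and 'condition' must have one entry per cell", call. = FALSE)
  if (anyNA(cluster) || anyNA(condition))
    stop("cluster/condition labels must not contain NA", call. = FALSE)
  if (is.null(conditions))
    conditions <- if (is.factor(condition)) levels(condition) else unique(as.character(condition))
  bad <- setdiff(unique(as.character(condition)), conditions)
  if (length(bad))
    stop("condition label(s) absent from the declared series: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cluster <- factor(as.character(cluster))
  condition <- factor(as.character(condition), levels = conditions)

  norm <- normalizeCounts(m, scaleFactor)
  grid <- expand.grid(cluster = levels(cluster), condition = conditions,
                      stringsAsFactors = FALSE)
  keep <- logical(nrow(grid))
  means <- dets <- matrix(0, nrow(m), nrow(grid))
  ncells <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cells <- which(cluster == grid$cluster[i] & condition == grid$condition[i])
    ncells[i] <- length(cells)
    if (!length(cells)) next
    keep[i] <- TRUE
    means[, i] <- Matrix::rowMeans(norm[, cells, drop = FALSE])
    dets[, i] <- Matrix::rowMeans(m[, cells, drop = FALSE] > 0)
  }
  if (verbose && any(!keep))
    message("pseudobulkProfile: omitting empty group(s): ",
            paste(paste(grid$cluster[!keep], grid$condition[!keep], sep = ":"),
                  collapse = ", "))
  grid <- grid[keep, , drop = FALSE]
  means <- means[, keep, drop = FALSE]
  dets <- dets[, keep, drop = FALSE]
  gnames <- paste(grid$cluster, grid$condition, sep = ":")
  dimnames(means) <- dimnames(dets) <- list(rownames(m), gnames)
  new("GroupedProfile", mean = means, detection = dets,
      nCells = ncells[keep],
      cluster = factor(grid$cluster),
      condition = factor(grid$condition, levels = conditions))
}
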