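#' Read a gene x cell count matrix
#'
#' Reads either a Matrix Market triplet directory (\code{matrix.mtx} with
#' \code{features.tsv} / \code{barcodes.tsv} companions, the 10x convention)
#' or a dense CSV with a header row and gene ids in the first column.
#' Orientation is genes x cells internally; an MTX matrix stored cells x
#' genes (detected from the companion id files) is transposed and the
#' decision reported via \code{message()}.
#'
#' @param path directory (MTX) or file (CSV).
#' @param format \code{"auto"} (by path type), \code{"mtx"} or \code{"csv"}.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{counts} assay (sparse), gene ids as rownames, cell ids as
#'   colnames.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gene = c("g1", "g2"), c1 = c(5L, 0L), c2 = c(0L, 3L)),
#'           tmp, row.names = FALSE)
#' readExpressionMatrix(tmp)
#' @export
readExpressionMatrix <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx" else "csv"
  if (!file.exists(path))
    stop("path does not exist: ", path, call. = FALSE)
  if (format == "mtx") {
    mfile <- file.path(path, "matrix.mtx")
    ffile <- file.path(path, "features.tsv")
    bfile <- file.path(path, "barcodes.tsv")
    for (f in c(mfile, ffile, bfile))
      if (!file.exists(f)) stop("missing companion file: ", f, call. = FALSE)
    m <- Matrix::readMM(mfile)
    genes <- read.delim(ffile, header = FALSE)[[1L]]
    cells <- read.delim(bfile, header = FALSE)[[1L]]
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      # stored genes x cells
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      message("matrix stored cells x genes; transposing to genes x cells")
      m <- Matrix::t(m)
    } else {
      stop(sprintf(
        "matrix dimensions %d x %d match neither %d features nor %d barcodes",
        nrow(m), ncol(m), length(genes), length(cells)), call. = FALSE)
    }
    dimnames(m) <- list(as.character(genes), as.character(cells))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2L)
      stop("dense CSV needs a gene-id column plus at least one cell column",
           call. = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1L], is.numeric, TRUE))[1L]
      stop("non-numeric counts in column '", colnames(df)[-1L][bad], "'",
           call. = FALSE)
    }
    rownames(m) <- genes
  }
  .validate_counts(m)
  .check_ids(rownames(m), "gene ids")
  .check_ids(colnames(m), "cell ids")
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")))
}

.validate_counts <- function(m) {
  v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(v < 0)) {
    i <- which(v < 0)[1L]
    stop("negative count encountered (value ", v[i],
         "); counts must be nonnegative integers", call. = FALSE)
  }
  if (any(v != floor(v)))
    stop("non-integer count encountered; counts must be nonnegative integers",
         call. = FALSE)
  invisible(m)
}

#' Write a count matrix in a supported exchange format
#'
#' Inverse of [readExpressionMatrix()]; reading back reproduces the counts,
#' gene ids and cell ids exactly.
#'
#' @param x matrix, Matrix or SingleCellExperiment (counts assay).
#' @param path target directory (MTX) or file (CSV).
#' @param format \code{"mtx"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  m <- .as_counts(x)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a per-cell annotation table
#'
#' Tab- or comma-separated table with columns \code{cell_id},
#' \code{sample_id}, \code{condition} and \code{cluster}.
#'
#' @param path file path; the separator is taken from the extension
#'   (\code{.csv} = comma, otherwise tab).
#' @return data.frame with the four required columns.
#' @export
readCellAnnotation <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "sample_id", "condition", "cluster")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_ids(df$cell_id, "cell ids in annotation")
  df
}

#' Attach cell annotation to an experiment
#'
#' Matches annotation rows to the experiment's cells (every cell must be
#' annotated exactly once), declares the ordered condition series, and stores
#' everything in \code{colData}.
#'
#' @param x SingleCellExperiment.
#' @param annotation data.frame as returned by [readCellAnnotation()].
#' @param conditions ordered condition series (default: order of first
#'   appearance in the annotation).
#' @return \code{x} with populated \code{colData}.
#' @export
attachCellAnnotation <- function(x, annotation, conditions = NULL) {
  idx <- match(colnames(x), annotation$cell_id)
  if (anyNA(idx))
    stop("cells without annotation: ",
         paste(head(colnames(x)[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  ann <- annotation[idx, , drop = FALSE]
  if (is.null(conditions)) conditions <- unique(ann$condition)
  bad <- setdiff(unique(ann$condition), conditions)
  if (length(bad))
    stop("condition label(s) not in the declared series: ",
         paste(bad, collapse = ", "), call. = FALSE)
  SummarizedExperiment::colData(x)$sample_id <- ann$sample_id
  SummarizedExperiment::colData(x)$condition <-
    factor(ann$condition, levels = conditions)
  SummarizedExperiment::colData(x)$cluster <- as.character(ann$cluster)
  x
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member symbols.  Lines with
#' fewer than three fields are a parse error (reported with the line
#' number); duplicate members within a set are removed with a warning.
#'
#' @param path GMT file.
#' @param universe optional gene universe for the collection.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: %d field(s), need name, description and at least one member",
                   i, length(fields)), call. = FALSE)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT parse error at line %d: set '%s' has no members",
                   i, fields[1L]), call. = FALSE)
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' removed", fields[1L]))
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  new("GeneSetCollection", sets = sets,
      universe = if (is.null(universe))
        unique(unlist(sets, use.names = FALSE)) else as.character(universe))
}

#' Write a GeneSetCollection as GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path target file.
#' @param descriptions optional per-set description column (default "na").
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(x, path, descriptions = NULL) {
  sets <- geneSets(x)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
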