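## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards.  All stochastic operations in the package
## take an explicit seed and go through this helper, so no function mutates
## global random state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Extract a counts matrix (genes x cells) from the containers the package
## accepts: a base matrix, a Matrix sparse matrix, or a
## SummarizedExperiment/SingleCellExperiment with a "counts" assay.
.as_counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, "counts")
  }
  if (!(is.matrix(x) || methods::is(x, "Matrix")))
    stop("expected a matrix, Matrix, or SummarizedExperiment with a 'counts' assay",
         call. = FALSE)
  x
}

.check_ids <- function(ids, what) {
  if (anyDuplicated(ids))
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(ids[duplicated(ids)])[seq_len(min(3, sum(duplicated(ids))))],
                       collapse = ", ")), call. = FALSE)
  invisible(ids)
}
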