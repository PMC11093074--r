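#' Fit a fuzzy level specification from a grouped profile
#'
#' Places the level anchors on the data scale: the first anchor is 0
#' (NotExpressed) and the remaining \code{nLevels - 1} anchors are empirical
#' quantiles of the \emph{positive} mean expression values pooled over all
#' groups.  One specification is fitted per dataset so that levels are
#' comparable across clusters and conditions — a shared scale is what makes
#' cross-cluster flow comparison meaningful.
#'
#' @param profile a [GroupedProfile-class].
#' @param nLevels number of levels (>= 2; default 4).
#' @param quantiles strictly increasing values in (0, 1), length
#'   \code{nLevels - 1}.  Default for 4 levels: \code{c(0.25, 0.5, 0.9)}
#'   (the top anchor at the 90th percentile so that full High membership
#'   marks the strongly expressed tail); otherwise equally spaced
#'   \code{(1:(nLevels-1))/nLevels}.
#' @param levels optional level labels (default NotExpressed/Low/Medium/High
#'   for 4 levels).
#' @return A [FuzzySpec-class].
#' @export
fitFuzzySpec <- function(profile, nLevels = 4L, quantiles = NULL,
                         levels = NULL) {
  stopifnot(is(profile, "GroupedProfile"))
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("'nLevels' must be at least 2", call. = FALSE)
  if (is.null(quantiles))
    quantiles <- if (nLevels == 4L) c(0.25, 0.5, 0.9)
                 else seq_len(nLevels - 1L) / nLevels
  if (length(quantiles) != nLevels - 1L)
    stop("'quantiles' must have length nLevels - 1", call. = FALSE)
  if (any(quantiles <= 0) || any(quantiles >= 1) || any(diff(quantiles) <= 0))
    stop("'quantiles' must be strictly increasing within (0, 1)", call. = FALSE)
  vals <- profileMeans(profile)
  pos <- vals[vals > 0]
  if (length(unique(pos)) < length(quantiles))
    stop("fewer distinct positive mean values (", length(unique(pos)),
         ") than quantiles requested; use fewer levels", call. = FALSE)
  upper <- quantile(pos, probs = quantiles, names = FALSE)
  a <- c(0, upper)
  if (any(diff(a) <= 0))
    stop("degenerate anchors (non-increasing): ",
         paste(signif(a, 4), collapse = ", "),
         "; the positive values are too concentrated for this many levels",
         call. = FALSE)
  if (is.null(levels) && nLevels != 4L)
    levels <- paste0("L", seq_len(nLevels) - 1L)
  FuzzySpec(a, levels)
}

#' Triangular level memberships of nonnegative values
#'
#' For anchors \code{a_0 < ... < a_{L-1}} level \code{l} has membership 1 at
#' \code{a_l}, declining linearly to 0 at the adjacent anchors; values at or
#' below \code{a_0} belong fully to the first level, values at or beyond
#' \code{a_{L-1}} fully to the last.  By construction the memberships of any
#' input sum to exactly 1 (partition of unity).
#'
#' @param x numeric vector of nonnegative values.
#' @param spec a [FuzzySpec-class].
#' @return Numeric matrix, \code{length(x)} x levels.
#' @examples
#' fuzzifyValues(c(0, 1, 1.5, 9), FuzzySpec(c(0, 1, 2, 4)))
#' @export
fuzzifyValues <- function(x, spec) {
  stopifnot(is(spec, "FuzzySpec"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("fuzzification requires finite nonnegative values", call. = FALSE)
  a <- anchors(spec)
  L <- length(a)
  mu <- matrix(0, length(x), L,
               dimnames = list(names(x), levelLabels(spec)))
  hi <- x >= a[L]
  mu[hi, L] <- 1
  inner <- !hi
  if (any(inner)) {
    i <- findInterval(x[inner], a, rightmost.closed = FALSE)  # in 1..L-1
    u <- (x[inner] - a[i]) / (a[i + 1L] - a[i])
    rows <- which(inner)
    mu[cbind(rows, i)] <- 1 - u
    mu[cbind(rows, i + 1L)] <- mu[cbind(rows, i + 1L)] + u
  }
  mu
}

#' Fuzzify a grouped profile into a membership tensor
#'
#' Applies the triangular membership functions of a [FuzzySpec-class] to
#' every (gene, group) mean of a [GroupedProfile-class].  Genes detected in
#' less than \code{detectionGate} of cells in \emph{every} group are dropped
#' first (reported), so that flows are not driven by noise-level genes;
#' set \code{detectionGate = 0} to keep all genes.
#'
#' @param profile a [GroupedProfile-class].
#' @param spec a [FuzzySpec-class], e.g. from [fitFuzzySpec()].
#' @param detectionGate minimum fraction of expressing cells required in at
#'   least one group (default 0.01).
#' @param verbose report gated genes.
#' @return A [MembershipTensor-class].
#' @export
fuzzify <- function(profile, spec, detectionGate = 0.01, verbose = TRUE) {
  stopifnot(is(profile, "GroupedProfile"), is(spec, "FuzzySpec"))
  vals <- profileMeans(profile)
  if (detectionGate > 0) {
    keep <- apply(detectionRate(profile), 1L, max) >= detectionGate
    if (verbose && any(!keep))
      message(sprintf(
        "fuzzify: dropping %d gene(s) detected in < %.3g of cells in every group",
        sum(!keep), detectionGate))
    vals <- vals[keep, , drop = FALSE]
    if (!nrow(vals))
      stop("no gene passes the detection gate", call. = FALSE)
  }
  L <- length(levelLabels(spec))
  mu <- array(0, dim = c(nrow(vals), ncol(vals), L),
              dimnames = list(rownames(vals), colnames(vals),
                              levelLabels(spec)))
  for (k in seq_len(ncol(vals)))
    mu[, k, ] <- fuzzifyValues(vals[, k], spec)
  new("MembershipTensor", mu = mu, cluster = profile@cluster,
      condition = profile@condition, levels = levelLabels(spec))
}
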