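#' Enumerate all level paths across the condition series
#'
#' A level path assigns one expression level to each of the \code{T}
#' conditions; with \code{L} levels there are \code{L^T} paths.  Paths are
#' returned in lexicographic order (first condition most significant).
#'
#' @param nLevels number of levels L (>= 2).
#' @param nConditions number of conditions T (>= 2).
#' @param cap refuse enumeration beyond this many paths (default 1e6).
#' @return Integer matrix, \code{L^T} x \code{T}, of 1-based level indices.
#' @examples
#' enumeratePaths(2, 2)
#' @export
enumeratePaths <- function(nLevels, nConditions, cap = 1e6) {
  L <- as.integer(nLevels); T <- as.integer(nConditions)
  if (L < 2L || T < 2L)
    stop("need at least 2 levels and 2 conditions", call. = FALSE)
  nPaths <- L^T
  if (nPaths > cap)
    stop(sprintf("L^T = %d^%d = %.4g exceeds the enumeration cap (%.4g); restrict the pattern or raise 'cap'",
                 L, T, nPaths, cap), call. = FALSE)
  g <- do.call(expand.grid, rep(list(seq_len(L)), T))
  paths <- as.matrix(g[, rev(seq_len(T)), drop = FALSE])
  dimnames(paths) <- list(NULL, paste0("t", seq_len(T)))
  storage.mode(paths) <- "integer"
  paths
}

#' Human-readable path identifiers
#'
#' @param paths integer path matrix from [enumeratePaths()].
#' @param levels level labels.
#' @return Character vector like \code{"Low-Low-High"}.
#' @export
pathIds <- function(paths, levels) {
  apply(paths, 1L, function(p) paste(levels[p], collapse = "-"))
}

## Extract the gene x condition x level membership array for one cluster,
## with conditions ordered along the series.
.cluster_mu <- function(tensor, cluster) {
  stopifnot(is(tensor, "MembershipTensor"))
  cond <- levels(tensor@condition)
  idx <- vapply(cond, function(tt) {
    j <- which(tensor@cluster == cluster & tensor@condition == tt)
    if (length(j) != 1L)
      stop(sprintf("tensor has %d group(s) for cluster '%s', condition '%s'; need exactly 1",
                   length(j), cluster, tt), call. = FALSE)
    j
  }, 0L)
  tensor@mu[, idx, , drop = FALSE]  # G x T x L
}

.check_cluster <- function(tensor, cluster) {
  if (!cluster %in% levels(tensor@cluster))
    stop("unknown cluster: ", cluster, call. = FALSE)
}

## G x P matrix of per-gene path memberships for one cluster, computed by
## accumulating one condition at a time (the factorized route: never loops
## over individual paths).
.path_membership_matrix <- function(muCT, paths, combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  G <- dim(muCT)[1L]
  L <- dim(muCT)[3L]
  pm <- matrix(1, G, nrow(paths))
  for (tt in seq_len(ncol(paths))) {
    slice <- matrix(muCT[, tt, , drop = FALSE], G, L)  # G x L at condition tt
    step <- slice[, paths[, tt], drop = FALSE]         # G x P
    pm <- if (combiner == "product") pm * step else pmin(pm, step)
  }
  rownames(pm) <- dimnames(muCT)[[1L]]
  pm
}

#' Membership of one gene in one level path
#'
#' Combines the gene's per-condition level memberships along the path with a
#' t-norm: \code{"product"} (default; multiplies memberships, giving exact
#' flow-weight conservation) or \code{"min"}.
#'
#' @param tensor a [MembershipTensor-class].
#' @param gene gene id.
#' @param cluster cluster label.
#' @param path integer vector of 1-based level indices, one per condition.
#' @param combiner \code{"product"} or \code{"min"}.
#' @return A value in [0, 1].
#' @export
pathMembership <- function(tensor, gene, cluster, path,
                           combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  .check_cluster(tensor, cluster)
  if (!gene %in% dimnames(tensor@mu)[[1L]])
    stop("unknown gene: ", gene, call. = FALSE)
  muCT <- .cluster_mu(tensor, cluster)
  T <- dim(muCT)[2L]
  if (length(path) != T)
    stop("path length must equal the number of conditions", call. = FALSE)
  vals <- vapply(seq_len(T), function(tt) muCT[gene, tt, path[tt]], 0)
  if (combiner == "product") prod(vals) else min(vals)
}

#' Flow weights: the width of every level path
#'
#' The weight of a flow is the sum over genes of their path memberships —
#' the quantity an alluvial diagram draws as the band width.  Under the
#' product combiner the weights over all \code{L^T} paths sum exactly to the
#' number of genes, because each gene's memberships factorize over
#' conditions and sum to 1 per condition.
#'
#' @param tensor a [MembershipTensor-class].
#' @param cluster cluster label.
#' @param combiner \code{"product"} or \code{"min"}.
#' @param paths optional path matrix (default: all paths).
#' @param cap enumeration cap forwarded to [enumeratePaths()].
#' @return Named numeric vector of weights, one per path.
#' @export
flowWeights <- function(tensor, cluster, combiner = c("product", "min"),
                        paths = NULL, cap = 1e6) {
  combiner <- match.arg(combiner)
  .check_cluster(tensor, cluster)
  muCT <- .cluster_mu(tensor, cluster)
  if (is.null(paths))
    paths <- enumeratePaths(dim(muCT)[3L], dim(muCT)[2L], cap)
  pm <- .path_membership_matrix(muCT, paths, combiner)
  w <- colSums(pm)
  names(w) <- pathIds(paths, tensor@levels)
  w
}

#' Select level paths matching a flow pattern
#'
#' Applies a [FlowPattern-class] predicate to the full path enumeration.
#' Directions: \code{final_above_all_prior} keeps paths whose final level
#' strictly exceeds every earlier level (the formalization of "increased in
#' the final condition compared to every baseline" — a comparison against
#' all baselines, not a monotone trend); \code{final_below_all_prior} is its
#' mirror; \code{nondecreasing}/\code{nonincreasing}/\code{constant} are the
#' usual monotone predicates; \code{any} keeps everything.
#' \code{minFinalLevel} additionally requires the final level to reach the
#' given label.  Cluster scope plays no role here; it applies when gene
#' memberships are combined.
#'
#' @param pattern a [FlowPattern-class].
#' @param levels ordered level labels.
#' @param nConditions number of conditions T.
#' @param cap enumeration cap.
#' @return Integer matrix of the selected paths (possibly 0 rows).
#' @examples
#' p <- FlowPattern("final_above_all_prior", minFinalLevel = "Medium")
#' nrow(selectFlows(p, c("NotExpressed", "Low", "Medium", "High"), 3))
#' @export
selectFlows <- function(pattern, levels, nConditions, cap = 1e6) {
  stopifnot(is(pattern, "FlowPattern"))
  paths <- enumeratePaths(length(levels), nConditions, cap)
  T <- ncol(paths)
  keep <- switch(pattern@direction,
    final_above_all_prior =
      paths[, T] > apply(paths[, -T, drop = FALSE], 1L, max),
    final_below_all_prior =
      paths[, T] < apply(paths[, -T, drop = FALSE], 1L, min),
    nondecreasing = apply(paths, 1L, function(p) all(diff(p) >= 0)),
    nonincreasing = apply(paths, 1L, function(p) all(diff(p) <= 0)),
    constant = apply(paths, 1L, function(p) all(p == p[1L])),
    any = rep(TRUE, nrow(paths)))
  if (!is.na(pattern@minFinalLevel)) {
    lvl <- match(pattern@minFinalLevel, levels)
    if (is.na(lvl))
      stop("'minFinalLevel' (", pattern@minFinalLevel,
           ") is not a valid level label", call. = FALSE)
    keep <- keep & paths[, T] >= lvl
  }
  paths[keep, , drop = FALSE]
}

#' Combined per-gene membership in a selected flow set
#'
#' Per cluster, a gene's membership in a set of (disjoint) selected paths is
#' the sum of its path memberships — at most 1 under the product combiner,
#' since all \code{L^T} path memberships of a gene sum to 1.  Cluster
#' scoping then combines the per-cluster values: \code{all_clusters} takes
#' the minimum (fuzzy AND — the gene must follow a selected flow in every
#' cluster), \code{any_cluster} the maximum, \code{single} one cluster.
#'
#' @param tensor a [MembershipTensor-class].
#' @param selectedPaths integer path matrix from [selectFlows()]; must be
#'   nonempty.
#' @param scope \code{"all_clusters"}, \code{"any_cluster"} or
#'   \code{"single"}.
#' @param cluster cluster label when \code{scope = "single"}.
#' @param combiner \code{"product"} or \code{"min"}.
#' @return Named numeric vector M(g) in [0, 1].
#' @export
combinedMembership <- function(tensor, selectedPaths,
                               scope = c("all_clusters", "any_cluster", "single"),
                               cluster = NULL,
                               combiner = c("product", "min")) {
  scope <- match.arg(scope)
  per <- clusterMembershipMatrix(tensor, selectedPaths, combiner)
  switch(scope,
    all_clusters = apply(per, 1L, min),
    any_cluster = apply(per, 1L, max),
    single = {
      if (is.null(cluster)) stop("scope 'single' needs a cluster", call. = FALSE)
      .check_cluster(tensor, cluster)
      per[, cluster]
    })
}

#' Per-cluster gene membership in a selected flow set
#'
#' @inheritParams combinedMembership
#' @return Numeric matrix, genes x clusters.
#' @export
clusterMembershipMatrix <- function(tensor, selectedPaths,
                                    combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  if (is.null(dim(selectedPaths)) || nrow(selectedPaths) == 0L)
    stop("the selected flow set is empty", call. = FALSE)
  cl <- levels(tensor@cluster)
  out <- vapply(cl, function(cc) {
    pm <- .path_membership_matrix(.cluster_mu(tensor, cc), selectedPaths,
                                  combiner)
    rowSums(pm)
  }, numeric(dim(tensor@mu)[1L]))
  if (is.null(dim(out)))
    out <- matrix(out, ncol = length(cl), dimnames = list(dimnames(tensor@mu)[[1L]], cl))
  out
}

#' Rank genes by combined flow membership
#'
#' Sorts descending; ties are broken by gene id (lexicographic), so the
#' ranking is deterministic.
#'
#' @param membership named numeric vector (e.g. from
#'   [combinedMembership()]) or a [FlowResult-class].
#' @param k number of genes to return (capped at the number available).
#' @return data.frame with columns \code{gene} and \code{membership}.
#' @examples
#' topGenes(c(A = 0.9, B = 0.1, C = 0.9), 2)
#' @export
topGenes <- function(membership, k = 30L) {
  if (is(membership, "FlowResult")) membership <- memberships(membership)
  if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
  ord <- order(-membership, names(membership), method = "radix")
  ord <- ord[seq_len(min(k, length(membership)))]
  data.frame(gene = names(membership)[ord],
             membership = unname(membership[ord]))
}

#' Full flow analysis of a membership tensor
#'
#' Enumerates all level paths, computes per-cluster flow weights, selects
#' flows with the pattern predicate, and combines per-gene memberships in
#' the selected set across clusters according to the pattern scope.
#'
#' @param tensor a [MembershipTensor-class].
#' @param pattern a [FlowPattern-class].
#' @param combiner \code{"product"} (default) or \code{"min"}.
#' @param cap enumeration cap.
#' @return A [FlowResult-class].
#' @export
flowAnalysis <- function(tensor, pattern, combiner = c("product", "min"),
                         cap = 1e6) {
  combiner <- match.arg(combiner)
  stopifnot(is(tensor, "MembershipTensor"), is(pattern, "FlowPattern"))
  lv <- tensor@levels
  T <- nlevels(tensor@condition)
  paths <- enumeratePaths(length(lv), T, cap)
  cl <- levels(tensor@cluster)
  weights <- vapply(cl, function(cc)
    unname(flowWeights(tensor, cc, combiner, paths)),
    numeric(nrow(paths)))
  if (is.null(dim(weights)))
    weights <- matrix(weights, ncol = length(cl))
  colnames(weights) <- cl
  sel <- selectFlows(pattern, lv, T, cap)
  selFlag <- .path_key(paths) %in% .path_key(sel)
  if (!nrow(sel))
    stop("the pattern selects no path for these levels/conditions", call. = FALSE)
  per <- clusterMembershipMatrix(tensor, sel, combiner)
  M <- combinedMembership(tensor, sel, pattern@scope,
                          cluster = if (is.na(pattern@cluster)) NULL else pattern@cluster,
                          combiner = combiner)
  new("FlowResult", paths = paths, weights = weights, selected = selFlag,
      clusterMembership = per, membership = M, pattern = pattern,
      levels = lv, conditions = levels(tensor@condition))
}

.path_key <- function(paths) apply(paths, 1L, paste, collapse = ".")
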