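#' Crisp gene set from fuzzy memberships
#'
#' Reduces a membership vector to the genes at or above a threshold
#' (inclusive boundary).
#'
#' @param membership named numeric vector M(g) in [0, 1].
#' @param threshold value in (0, 1], default 0.5.
#' @return Character vector of gene ids.
#' @examples
#' crispOverlap(c(A = 0.6, B = 0.5, C = 0.49), 0.5)
#' @export
crispOverlap <- function(membership, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  names(membership)[membership >= threshold]
}

.prep_sets <- function(collection, universe) {
  sets <- geneSets(collection)
  sets <- lapply(sets, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("set(s) with no member in the universe dropped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets))
    stop("no gene set intersects the universe", call. = FALSE)
  sets
}

#' Hypergeometric over-representation test
#'
#' For each set S with K members in the universe, a hit list of n genes and
#' an overlap of k, computes the one-sided over-representation p-value
#' P[X >= k] with X hypergeometric(N = |universe|, K, n), then
#' Benjamini-Hochberg adjusts across all tested sets.
#'
#' @param hits character vector of hit genes; must be contained in
#'   \code{universe}.
#' @param collection a [GeneSetCollection-class]; sets with no member in
#'   the universe are dropped with a warning.
#' @param universe gene universe (default the collection's own). In a flow
#'   analysis this should be the genes surviving the expression gate, not
#'   the full annotation, to avoid composition bias.
#' @return data.frame: set, size (within universe), overlap, p, q.
#' @export
hypergeomEnrichment <- function(hits, collection,
                                universe = geneUniverse(collection)) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(hits)) stop("empty hit set", call. = FALSE)
  extra <- setdiff(hits, universe)
  if (length(extra))
    stop("hit gene(s) outside the universe: ",
         paste(head(extra, 3L), collapse = ", "), call. = FALSE)
  hits <- unique(hits)
  sets <- .prep_sets(collection, universe)
  N <- length(universe); n <- length(hits)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, hits)), 0L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(set = names(sets), size = unname(K), overlap = unname(k),
             p = unname(p), q = unname(p.adjust(p, "BH")),
             row.names = NULL)
}

#' Membership-weighted permutation enrichment
#'
#' Scores each set by the sum of member gene memberships and assesses it
#' against a permutation null in which the membership vector is shuffled
#' over the universe.  The p-value is \code{(1 + #{perm >= obs}) /
#' (1 + nPerm)}; Benjamini-Hochberg adjusts across sets.  Identical seeds
#' give identical results.
#'
#' @param membership named numeric vector M(g) over the universe.
#' @param collection a [GeneSetCollection-class].
#' @param universe gene universe (default \code{names(membership)}).
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return data.frame: set, size, score, p, q.
#' @export
weightedEnrichment <- function(membership, collection,
                               universe = names(membership),
                               nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) stop("'nPerm' must be at least 100", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  M <- membership[universe]
  if (anyNA(M))
    stop("membership values missing for part of the universe", call. = FALSE)
  sets <- .prep_sets(collection, universe)
  ind <- vapply(sets, function(s) universe %in% s,
                logical(length(universe)))           # |U| x nSets
  obs <- as.numeric(crossprod(ind, M))
  exceed <- numeric(length(sets))
  with_local_seed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- as.numeric(crossprod(ind, M[sample.int(length(M))]))
      exceed <- exceed + (perm >= obs)
    }
  })
  p <- (1 + exceed) / (1 + nPerm)
  data.frame(set = names(sets), size = unname(lengths(sets)),
             score = obs, p = p, q = p.adjust(p, "BH"), row.names = NULL)
}
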