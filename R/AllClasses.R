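#' GroupedProfile: pseudobulk expression summaries per (cluster, condition)
#'
#' Per-gene, per-group summaries of a single-cell experiment after grouping
#' cells by cluster and by a condition drawn from an ordered condition series:
#' the mean normalized (log1p counts-per-scale) expression, the fraction of
#' cells with a nonzero raw count, and the number of cells in each group.
#' Columns of the two matrices are groups; the \code{cluster} and
#' \code{condition} factors say which (cluster, condition) pair each column
#' summarizes.  The level order of \code{condition} is the ordered condition
#' series along which flows are later traced.
#'
#' @slot mean numeric matrix, genes x groups, mean normalized expression.
#' @slot detection numeric matrix, genes x groups, fraction of cells with
#'   raw count > 0.
#' @slot nCells integer vector, cells per group (all >= 1).
#' @slot cluster factor of length ncol(mean), cluster label per group.
#' @slot condition factor of length ncol(mean); its levels are the ordered
#'   condition series.
#'
#' @aliases GroupedProfile
#' @exportClass GroupedProfile
setClass("GroupedProfile",
  representation(mean = "matrix", detection = "matrix", nCells = "integer",
                 cluster = "factor", condition = "factor"))

setValidity("GroupedProfile", function(object) {
  msg <- NULL
  k <- ncol(object@mean)
  if (!identical(dim(object@mean), dim(object@detection)))
    msg <- c(msg, "'mean' and 'detection' must have identical dimensions")
  if (length(object@nCells) != k || length(object@cluster) != k ||
      length(object@condition) != k)
    msg <- c(msg, "per-group slots must have one entry per column of 'mean'")
  if (any(object@nCells < 1L))
    msg <- c(msg, "every reported group must contain at least one cell")
  if (any(!is.finite(object@mean)))
    msg <- c(msg, "'mean' must be finite")
  if (any(object@mean < 0))
    msg <- c(msg, "'mean' must be nonnegative (normalized log scale)")
  if (any(object@detection < 0 | object@detection > 1))
    msg <- c(msg, "'detection' must lie in [0, 1]")
  if (is.null(rownames(object@mean)))
    msg <- c(msg, "'mean' must carry gene ids as rownames")
  if (nlevels(object@condition) < 2L)
    msg <- c(msg, "the condition series must contain at least two conditions")
  if (is.null(msg)) TRUE else msg
})

#' FuzzySpec: ordered expression levels with triangular membership anchors
#'
#' An ordered vocabulary of expression levels (default NotExpressed, Low,
#' Medium, High) with one anchor value per level on the normalized expression
#' scale.  Membership functions are triangular: level l has membership 1 at
#' its anchor \code{a_l}, declining linearly to 0 at the adjacent anchors;
#' values at or below the first anchor (always 0) belong fully to the first
#' level and values at or beyond the last anchor fully to the last.  For any
#' nonnegative input the memberships over levels sum to 1.
#'
#' @slot levels character vector of level labels, ordered low to high.
#' @slot anchors strictly increasing numeric vector, same length, first
#'   element 0.
#'
#' @aliases FuzzySpec
#' @exportClass FuzzySpec
setClass("FuzzySpec",
  representation(levels = "character", anchors = "numeric"))

setValidity("FuzzySpec", function(object) {
  msg <- NULL
  L <- length(object@levels)
  if (L < 2L) msg <- c(msg, "at least two levels are required")
  if (length(object@anchors) != L)
    msg <- c(msg, "one anchor per level is required")
  if (anyDuplicated(object@levels))
    msg <- c(msg, "level labels must be unique")
  if (length(object@anchors) && object@anchors[1L] != 0)
    msg <- c(msg, "the first anchor must be 0")
  if (any(diff(object@anchors) <= 0))
    msg <- c(msg, "anchors must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FuzzySpec
#'
#' @param anchors strictly increasing numeric vector starting at 0.
#' @param levels level labels (default the four-level vocabulary
#'   NotExpressed/Low/Medium/High, truncated or extended to match
#'   \code{length(anchors)} only if supplied explicitly).
#' @return A [FuzzySpec-class] object.
#' @examples
#' FuzzySpec(c(0, 1, 2, 4))
#' @export
FuzzySpec <- function(anchors, levels = NULL) {
  if (is.null(levels)) {
    if (length(anchors) == 4L) levels <- c("NotExpressed", "Low", "Medium", "High")
    else levels <- paste0("L", seq_along(anchors) - 1L)
  }
  new("FuzzySpec", levels = as.character(levels), anchors = as.numeric(anchors))
}

#' MembershipTensor: gene x group x level fuzzy memberships
#'
#' The fuzzified counterpart of a [GroupedProfile-class]: for every gene and
#' every (cluster, condition) group, a membership value in [0, 1] per
#' expression level, summing to 1 over levels.
#'
#' @slot mu 3-d numeric array, gene x group x level, with dimnames.
#' @slot cluster factor per group (second dimension).
#' @slot condition factor per group; levels are the ordered condition series.
#' @slot levels character vector of level labels (third dimension).
#'
#' @aliases MembershipTensor
#' @exportClass MembershipTensor
setClass("MembershipTensor",
  representation(mu = "array", cluster = "factor", condition = "factor",
                 levels = "character"))

setValidity("MembershipTensor", function(object) {
  msg <- NULL
  d <- dim(object@mu)
  if (length(d) != 3L) return("'mu' must be a 3-d array")
  if (length(object@cluster) != d[2L] || length(object@condition) != d[2L])
    msg <- c(msg, "'cluster'/'condition' must have one entry per group")
  if (length(object@levels) != d[3L])
    msg <- c(msg, "'levels' must match the third dimension of 'mu'")
  if (any(object@mu < -1e-12 | object@mu > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  s <- apply(object@mu, c(1L, 2L), sum)
  if (any(abs(s - 1) > 1e-8))
    msg <- c(msg, "memberships must sum to 1 over levels for every (gene, group)")
  if (is.null(msg)) TRUE else msg
})

#' FlowPattern: a predicate over level paths
#'
#' Describes which level paths ("flows") across the condition series are
#' selected, and how per-cluster memberships are combined into a single
#' per-gene membership.
#'
#' @slot direction one of \code{"final_above_all_prior"},
#'   \code{"final_below_all_prior"}, \code{"nondecreasing"},
#'   \code{"nonincreasing"}, \code{"constant"}, \code{"any"}.
#' @slot minFinalLevel level label the final condition must reach, or
#'   \code{NA_character_} for no constraint.
#' @slot scope \code{"all_clusters"} (fuzzy AND: minimum over clusters),
#'   \code{"any_cluster"} (maximum), or \code{"single"} (one named cluster).
#' @slot cluster cluster name when \code{scope == "single"}, else NA.
#'
#' @aliases FlowPattern
#' @exportClass FlowPattern
setClass("FlowPattern",
  representation(direction = "character", minFinalLevel = "character",
                 scope = "character", cluster = "character"))

.flow_directions <- c("final_above_all_prior", "final_below_all_prior",
                      "nondecreasing", "nonincreasing", "constant", "any")

setValidity("FlowPattern", function(object) {
  msg <- NULL
  if (!object@direction %in% .flow_directions)
    msg <- c(msg, paste0("'direction' must be one of: ",
                         paste(.flow_directions, collapse = ", ")))
  if (!object@scope %in% c("all_clusters", "any_cluster", "single"))
    msg <- c(msg, "'scope' must be all_clusters, any_cluster or single")
  if (object@scope == "single" && is.na(object@cluster))
    msg <- c(msg, "scope 'single' requires a cluster name")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FlowPattern
#'
#' @param direction path predicate; see [FlowPattern-class].
#' @param minFinalLevel optional level label the final condition must reach
#'   (e.g. \code{"Medium"}).
#' @param scope how per-cluster memberships combine: \code{"all_clusters"}
#'   (minimum), \code{"any_cluster"} (maximum) or \code{"single"}.
#' @param cluster cluster name, required when \code{scope = "single"}.
#' @return A [FlowPattern-class] object.
#' @examples
#' FlowPattern("final_above_all_prior", minFinalLevel = "Medium")
#' @export
FlowPattern <- function(direction = c("final_above_all_prior",
                                      "final_below_all_prior",
                                      "nondecreasing", "nonincreasing",
                                      "constant", "any"),
                        minFinalLevel = NULL, scope = "all_clusters",
                        cluster = NULL) {
  direction <- match.arg(direction)
  new("FlowPattern", direction = direction,
      minFinalLevel = if (is.null(minFinalLevel)) NA_character_ else as.character(minFinalLevel),
      scope = scope,
      cluster = if (is.null(cluster)) NA_character_ else as.character(cluster))
}

#' FlowResult: flow weights, selected paths and per-gene memberships
#'
#' The output of [flowAnalysis()]: every level path across the condition
#' series with its per-cluster weight (the flow width: the sum over genes of
#' path memberships), the subset of paths selected by a [FlowPattern-class],
#' the per-cluster gene membership in the selected flow set, and the combined
#' per-gene membership \code{M(g)} after cluster scoping.
#'
#' @slot paths integer matrix, paths x conditions, 1-based level indices in
#'   lexicographic order.
#' @slot weights numeric matrix, paths x clusters.
#' @slot selected logical vector per path.
#' @slot clusterMembership numeric matrix, genes x clusters: per-cluster sum
#'   of path memberships over the selected set.
#' @slot membership named numeric vector, combined membership per gene.
#' @slot pattern the [FlowPattern-class] used.
#' @slot levels level labels.
#' @slot conditions ordered condition labels.
#'
#' @aliases FlowResult
#' @exportClass FlowResult
setClass("FlowResult",
  representation(paths = "matrix", weights = "matrix", selected = "logical",
                 clusterMembership = "matrix", membership = "numeric",
                 pattern = "FlowPattern", levels = "character",
                 conditions = "character"))

setValidity("FlowResult", function(object) {
  msg <- NULL
  if (nrow(object@weights) != nrow(object@paths))
    msg <- c(msg, "'weights' must have one row per path")
  if (length(object@selected) != nrow(object@paths))
    msg <- c(msg, "'selected' must flag every path")
  if (any(object@weights < 0))
    msg <- c(msg, "flow weights must be nonnegative")
  if (any(object@membership < -1e-9 | object@membership > 1 + 1e-9))
    msg <- c(msg, "combined memberships must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' GeneSetCollection: named gene sets over a universe
#'
#' @slot sets named list of character vectors (nonempty, deduplicated).
#' @slot universe character vector of gene ids the sets are tested against.
#'
#' @aliases GeneSetCollection
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
      msg <- c(msg, "every gene set must be named")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "empty gene sets are not allowed")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors; duplicate members within a
#'   set are removed with a warning.
#' @param universe gene universe (default: the union of all members).
#' @return A [GeneSetCollection-class] object.
#' @examples
#' GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
  sets <- lapply(sets, as.character)
  dups <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dups)) {
    warning("duplicate members removed in set(s): ",
            paste(names(sets)[dups], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  new("GeneSetCollection", sets = sets, universe = as.character(universe))
}

#' SyntheticSpec: parameterization of the planted-pattern simulator
#'
#' Full description of a simulated CITE-seq style cohort: negative binomial
#' RNA counts for \code{nGenes} genes over \code{nClusters} clusters x an
#' ordered condition series, with planted fold-change genes in chosen
#' (cluster, condition) blocks, and bimodal antibody capture counts (stained
#' population vs background).  See [syntheticSpec()] for defaults and
#' [simulateCiteSeq()] for the generator.
#'
#' @slot nGenes,nClusters integer sizes.
#' @slot conditions ordered condition labels.
#' @slot samplesPerCondition,cellsPerSample integers; each (cluster,
#'   condition, sample) block contains \code{cellsPerSample} cells.
#' @slot baselineLogMean,baselineLogSd log-normal parameters of baseline
#'   gene mean counts.
#' @slot dispersion NB dispersion of RNA counts (var = mu + dispersion mu^2).
#' @slot plantedGenes number of planted fold-change genes.
#' @slot plantedFoldChange fold change applied in the planted blocks (> 0).
#' @slot plantedConditions,plantedClusters labels of the target blocks
#'   (character(0) = all clusters).
#' @slot plantedBaselineQuantiles numeric length 2; planted genes are drawn
#'   from genes whose baseline mean lies in this quantile band.
#' @slot antibodies antibody names.
#' @slot adtStainedMean,adtBackgroundMean,adtStainedFraction,adtDispersion
#'   NB mixture parameters of the antibody counts.
#' @slot seed mandatory integer seed.
#'
#' @aliases SyntheticSpec
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nGenes = "integer", nClusters = "integer",
                 conditions = "character", samplesPerCondition = "integer",
                 cellsPerSample = "integer", baselineLogMean = "numeric",
                 baselineLogSd = "numeric", dispersion = "numeric",
                 plantedGenes = "integer", plantedFoldChange = "numeric",
                 plantedConditions = "character", plantedClusters = "character",
                 plantedBaselineQuantiles = "numeric", antibodies = "character",
                 adtStainedMean = "numeric", adtBackgroundMean = "numeric",
                 adtStainedFraction = "numeric", adtDispersion = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (object@nGenes < 1L || object@nClusters < 1L ||
      object@samplesPerCondition < 1L || object@cellsPerSample < 1L)
    msg <- c(msg, "all sizes must be positive")
  if (length(object@conditions) < 2L)
    msg <- c(msg, "at least two ordered conditions are required")
  if (object@dispersion <= 0 || object@adtDispersion <= 0)
    msg <- c(msg, "dispersions must be positive")
  if (object@plantedFoldChange <= 0)
    msg <- c(msg, "fold changes must be positive")
  if (object@plantedGenes > object@nGenes)
    msg <- c(msg, "planted subset larger than the number of genes")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "an explicit seed is mandatory")
  if (object@adtStainedFraction < 0 || object@adtStainedFraction > 1)
    msg <- c(msg, "'adtStainedFraction' must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
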