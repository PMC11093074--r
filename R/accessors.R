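#' Accessors for FuzzyFlows objects
#'
#' Small read-only accessors: \code{profileMeans()} and \code{detectionRate()}
#' return the genes x groups summary matrices of a
#' \linkS4class{GroupedProfile}; \code{groupCells()} the per-group cell
#' counts; \code{clusterNames()} and \code{conditionSeries()} the cluster
#' labels and the ordered condition series; \code{levelLabels()} the ordered
#' level vocabulary; \code{memberships()} the gene x group x level array of a
#' \linkS4class{MembershipTensor} or the combined per-gene membership vector
#' of a \linkS4class{FlowResult}; \code{flowWeightTable()} the per-path
#' weight/selection table of a \linkS4class{FlowResult}; \code{geneSets()}
#' and \code{geneUniverse()} the contents of a
#' \linkS4class{GeneSetCollection}.
#'
#' @param x the object.
#' @return See the individual descriptions above.
#' @examples
#' spec <- FuzzySpec(c(0, 1, 2, 4))
#' levelLabels(spec)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))
#' @rdname accessors
#' @export
setMethod("profileMeans", "GroupedProfile", function(x) x@mean)

#' @rdname accessors
#' @export
setGeneric("detectionRate", function(x) standardGeneric("detectionRate"))
#' @rdname accessors
#' @export
setMethod("detectionRate", "GroupedProfile", function(x) x@detection)

#' @rdname accessors
#' @export
setGeneric("groupCells", function(x) standardGeneric("groupCells"))
#' @rdname accessors
#' @export
setMethod("groupCells", "GroupedProfile", function(x) {
  stats::setNames(x@nCells, colnames(x@mean))
})

#' @rdname accessors
#' @export
setGeneric("clusterNames", function(x) standardGeneric("clusterNames"))
#' @rdname accessors
#' @export
setMethod("clusterNames", "GroupedProfile", function(x) levels(x@cluster))
#' @rdname accessors
#' @export
setMethod("clusterNames", "MembershipTensor", function(x) levels(x@cluster))

#' @rdname accessors
#' @export
setGeneric("conditionSeries", function(x) standardGeneric("conditionSeries"))
#' @rdname accessors
#' @export
setMethod("conditionSeries", "GroupedProfile", function(x) levels(x@condition))
#' @rdname accessors
#' @export
setMethod("conditionSeries", "MembershipTensor", function(x) levels(x@condition))
#' @rdname accessors
#' @export
setMethod("conditionSeries", "FlowResult", function(x) x@conditions)

#' @rdname accessors
#' @export
setGeneric("levelLabels", function(x) standardGeneric("levelLabels"))
#' @rdname accessors
#' @export
setMethod("levelLabels", "FuzzySpec", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("levelLabels", "MembershipTensor", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("levelLabels", "FlowResult", function(x) x@levels)

#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname accessors
#' @export
setMethod("anchors", "FuzzySpec", function(x) x@anchors)

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setMethod("memberships", "MembershipTensor", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("memberships", "FlowResult", function(x) x@membership)

#' @rdname accessors
#' @export
setGeneric("flowWeightTable", function(x) standardGeneric("flowWeightTable"))
#' @rdname accessors
#' @export
setMethod("flowWeightTable", "FlowResult", function(x) {
  data.frame(
    path = pathIds(x@paths, x@levels),
    x@weights,
    selected = x@selected,
    row.names = NULL, check.names = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

setMethod("show", "GroupedProfile", function(object) {
  cat("GroupedProfile:", nrow(object@mean), "genes x", ncol(object@mean),
      "groups (", nlevels(object@cluster), "clusters x",
      nlevels(object@condition), "conditions )\n")
  cat("  condition series:", paste(levels(object@condition), collapse = " -> "), "\n")
  cat("  cells per group: ", paste(range(object@nCells), collapse = "-"), "\n")
})

setMethod("show", "FuzzySpec", function(object) {
  cat("FuzzySpec with", length(object@levels), "levels:\n")
  for (i in seq_along(object@levels))
    cat(sprintf("  %-14s anchor = %.4g\n", object@levels[i], object@anchors[i]))
})

setMethod("show", "MembershipTensor", function(object) {
  d <- dim(object@mu)
  cat("MembershipTensor:", d[1L], "genes x", d[2L], "groups x", d[3L],
      "levels\n")
  cat("  levels:", paste(object@levels, collapse = " < "), "\n")
  cat("  condition series:", paste(levels(object@condition), collapse = " -> "), "\n")
})

setMethod("show", "FlowPattern", function(object) {
  cat("FlowPattern:", object@direction)
  if (!is.na(object@minFinalLevel))
    cat(", min final level", object@minFinalLevel)
  cat(", scope", object@scope)
  if (!is.na(object@cluster)) cat(" (", object@cluster, ")")
  cat("\n")
})

setMethod("show", "FlowResult", function(object) {
  cat("FlowResult:", nrow(object@paths), "level paths over",
      length(object@conditions), "conditions;",
      sum(object@selected), "selected\n")
  cat("  clusters:", paste(colnames(object@weights), collapse = ", "), "\n")
  cat("  genes ranked:", length(object@membership), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over",
      length(object@universe), "universe genes\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", paste(range(sz), collapse = "-"), "\n")
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nGenes, "genes,", object@nClusters,
      "clusters,", length(object@conditions), "conditions (",
      paste(object@conditions, collapse = " -> "), ")\n")
  cat("  ", object@samplesPerCondition, "samples/condition x",
      object@cellsPerSample, "cells/(cluster,sample); dispersion",
      object@dispersion, "\n")
  cat("  planted:", object@plantedGenes, "genes, fold change",
      object@plantedFoldChange, "in",
      paste(object@plantedConditions, collapse = ","), "\n")
  cat("  seed:", object@seed, "\n")
})
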