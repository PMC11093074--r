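#' Alluvial (Sankey) description of gene flows for one cluster
#'
#' Nodes are (condition, level) pairs; a node's throughput is the summed
#' gene membership at that condition and level.  A link between
#' \code{(t, l)} and \code{(t+1, l')} carries the product-combiner marginal
#' \code{sum_g mu[g,t,l] * mu[g,t+1,l']}, so links out of a node sum to its
#' throughput and node throughputs at every condition sum to the number of
#' genes.  Links lying on a selected flow are flagged for highlighting.
#'
#' @param tensor a [MembershipTensor-class].
#' @param cluster cluster label (one cluster per diagram).
#' @param selectedPaths optional integer path matrix (from [selectFlows()]
#'   or a [FlowResult-class]) whose links are flagged.
#' @return List with data.frames \code{nodes} (condition, level, throughput)
#'   and \code{links} (from_condition, from_level, to_condition, to_level,
#'   weight, selected).
#' @export
sankeyData <- function(tensor, cluster, selectedPaths = NULL) {
  .check_cluster(tensor, cluster)
  muCT <- .cluster_mu(tensor, cluster)
  cond <- levels(tensor@condition)
  lv <- tensor@levels
  T <- length(cond); L <- length(lv); G <- dim(muCT)[1L]
  slice <- function(tt) matrix(muCT[, tt, , drop = FALSE], G, L)

  nodes <- do.call(rbind, lapply(seq_len(T), function(tt) {
    data.frame(condition = cond[tt], level = lv,
               throughput = colSums(slice(tt)))
  }))
  rownames(nodes) <- NULL

  selKey <- character(0)
  if (!is.null(selectedPaths)) {
    if (is(selectedPaths, "FlowResult"))
      selectedPaths <- selectedPaths@paths[selectedPaths@selected, , drop = FALSE]
    for (tt in seq_len(T - 1L))
      selKey <- c(selKey, paste(tt, selectedPaths[, tt],
                                selectedPaths[, tt + 1L]))
  }
  links <- do.call(rbind, lapply(seq_len(T - 1L), function(tt) {
    w <- crossprod(slice(tt), slice(tt + 1L))  # L x L
    df <- expand.grid(from_level = seq_len(L), to_level = seq_len(L))
    data.frame(
      from_condition = cond[tt], from_level = lv[df$from_level],
      to_condition = cond[tt + 1L], to_level = lv[df$to_level],
      weight = w[cbind(df$from_level, df$to_level)],
      selected = paste(tt, df$from_level, df$to_level) %in% selKey)
  }))
  rownames(links) <- NULL
  list(nodes = nodes, links = links)
}

#' Serialize a Sankey description to JSON
#'
#' Writes the nodes/links document of [sankeyData()] in a form standard
#' plotting front-ends (plotly, d3-sankey) consume.
#'
#' @param sankey list from [sankeyData()].
#' @param path target JSON file.
#' @return \code{path}, invisibly.
#' @export
writeSankey <- function(sankey, path) {
  jsonlite::write_json(sankey, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
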