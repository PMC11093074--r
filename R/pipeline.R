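#' Read a flat run configuration
#'
#' The configuration is a flat YAML key-value file; [runPipeline()]
#' documents the keys.  Missing optional keys receive package defaults;
#' the ordered \code{conditions} series and the \code{seed} are mandatory
#' and validated before any computation.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  validateRunConfig(yaml::read_yaml(path))
}

.config_defaults <- list(
  simulate = FALSE,
  rna = NULL, adt = NULL, meta = NULL, gmt = NULL,
  conditions = NULL, seed = NULL,
  n_genes = 5000L, n_clusters = 5L, cells_per_sample = 100L,
  samples_per_condition = 2L, planted_genes = 50L, fold_change = 4,
  dispersion = 0.3,
  call_cells = NULL, adt_thresholds = NULL, adt_quantile = 0.99,
  umi_cutoff = NULL,
  n_levels = 4L, quantiles = NULL, detection_gate = 0.01,
  direction = "final_above_all_prior", min_final_level = "Medium",
  scope = "all_clusters", scope_cluster = NULL, combiner = "product",
  top = 30L,
  enrich_mode = "crisp", crisp_threshold = 0.5, n_perm = 1000L,
  sankey_clusters = NULL)

#' Validate and complete a run configuration
#'
#' @param config named list (e.g. from YAML).
#' @return The completed configuration.
#' @export
validateRunConfig <- function(config) {
  unknown <- setdiff(names(config), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.config_defaults, config, keep.null = TRUE)
  if (is.null(cfg$conditions) || length(cfg$conditions) < 2L)
    stop("config must declare the ordered 'conditions' series (>= 2 labels)",
         call. = FALSE)
  if (is.null(cfg$seed))
    stop("config must declare an explicit 'seed'", call. = FALSE)
  if (!cfg$simulate && is.null(cfg$rna))
    stop("config needs either simulate: true or an 'rna' input path",
         call. = FALSE)
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full flow-analysis pipeline
#'
#' Chains ingest (read or simulate, optional antibody cell calling and UMI
#' filter) -> pseudobulk -> fuzzification -> flow analysis -> gene ranking
#' -> optional enrichment, and writes every table, the Sankey documents and
#' a self-describing log (package version, all parameters, seeds, input
#' checksums) into \code{outDir}.  Outputs are fully determined by the
#' configuration, the inputs and the seeds: rerunning with an identical
#' configuration reproduces every file byte for byte.
#'
#' Configuration keys (flat YAML): \code{conditions} (ordered series,
#' required), \code{seed} (required); either \code{simulate: true} with
#' \code{n_genes}, \code{n_clusters}, \code{cells_per_sample},
#' \code{samples_per_condition}, \code{planted_genes}, \code{fold_change},
#' \code{dispersion}, or input paths \code{rna} (MTX directory or CSV),
#' \code{adt}, \code{meta}; optional \code{call_cells} (antibody list) with
#' \code{adt_thresholds} or \code{adt_quantile}, \code{umi_cutoff};
#' fuzzification \code{n_levels}, \code{quantiles}, \code{detection_gate};
#' pattern \code{direction}, \code{min_final_level}, \code{scope},
#' \code{combiner}; ranking \code{top}; enrichment \code{gmt},
#' \code{enrich_mode} (crisp/weighted), \code{crisp_threshold},
#' \code{n_perm}; \code{sankey_clusters}.
#'
#' @param config named list or path to a YAML file.
#' @param outDir output directory (created).
#' @return Invisibly, a named list of written file paths.
#' @export
runPipeline <- function(config, outDir) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  inputs <- character(0)

  ## ---- ingest ----
  if (isTRUE(cfg$simulate)) {
    spec <- syntheticSpec(
      nGenes = cfg$n_genes, nClusters = cfg$n_clusters,
      conditions = cfg$conditions,
      samplesPerCondition = cfg$samples_per_condition,
      cellsPerSample = cfg$cells_per_sample,
      plantedGenes = cfg$planted_genes,
      plantedFoldChange = cfg$fold_change,
      dispersion = cfg$dispersion, seed = cfg$seed)
    sce <- simulateCiteSeq(spec)
    paths["ground_truth"] <-
      .write_tsv(S4Vectors::metadata(sce)$ground_truth,
                 file.path(outDir, "ground_truth.tsv"))
  } else {
    sce <- readExpressionMatrix(cfg$rna)
    ann <- readCellAnnotation(cfg$meta)
    sce <- attachCellAnnotation(sce, ann, cfg$conditions)
    inputs <- c(inputs, rna = cfg$rna, meta = cfg$meta)
    if (!is.null(cfg$adt)) {
      adt <- readExpressionMatrix(cfg$adt)
      keep <- intersect(colnames(sce), colnames(adt))
      sce <- sce[, keep]
      SingleCellExperiment::altExp(sce, "ADT") <- adt[, keep]
      inputs <- c(inputs, adt = cfg$adt)
    }
  }
  if (!is.null(cfg$call_cells)) {
    adtM <- SingleCellExperiment::altExp(sce, "ADT")
    mask <- callCells(adtM, cfg$call_cells,
                      thresholds = unlist(cfg$adt_thresholds),
                      backgroundQuantile = cfg$adt_quantile)
    sce <- sce[, mask]
  }
  if (!is.null(cfg$umi_cutoff))
    sce <- sce[, umiFilter(sce, cfg$umi_cutoff)]

  ## ---- pseudobulk + fuzzify ----
  profile <- pseudobulkProfile(sce, conditions = cfg$conditions)
  prof_long <- data.frame(
    gene = rep(rownames(profileMeans(profile)), ncol(profileMeans(profile))),
    cluster = rep(as.character(profile@cluster),
                  each = nrow(profileMeans(profile))),
    condition = rep(as.character(profile@condition),
                    each = nrow(profileMeans(profile))),
    mean_expr = as.vector(profileMeans(profile)),
    frac_expr = as.vector(detectionRate(profile)),
    n_cells = rep(profile@nCells, each = nrow(profileMeans(profile))))
  paths["profile"] <- .write_tsv(prof_long, file.path(outDir, "profile.tsv"))

  fspec <- fitFuzzySpec(profile, nLevels = cfg$n_levels,
                        quantiles = cfg$quantiles)
  yaml::write_yaml(list(levels = levelLabels(fspec),
                        anchors = anchors(fspec)),
                   file.path(outDir, "fuzzy_spec.yaml"))
  paths["fuzzy_spec"] <- file.path(outDir, "fuzzy_spec.yaml")

  tensor <- fuzzify(profile, fspec, detectionGate = cfg$detection_gate)
  mu <- memberships(tensor)
  d <- dim(mu)
  memb_long <- data.frame(
    gene = rep(dimnames(mu)[[1L]], times = d[2L] * d[3L]),
    cluster = rep(rep(as.character(tensor@cluster), each = d[1L]), d[3L]),
    condition = rep(rep(as.character(tensor@condition), each = d[1L]), d[3L]),
    level = rep(dimnames(mu)[[3L]], each = d[1L] * d[2L]),
    membership = as.vector(mu))
  paths["memberships"] <- .write_tsv(memb_long,
                                     file.path(outDir, "memberships.tsv"))

  ## ---- flows ----
  pattern <- FlowPattern(cfg$direction, minFinalLevel = cfg$min_final_level,
                         scope = cfg$scope, cluster = cfg$scope_cluster)
  res <- flowAnalysis(tensor, pattern, combiner = cfg$combiner)
  paths["flows"] <- .write_tsv(flowWeightTable(res),
                               file.path(outDir, "flows.tsv"))
  ranking <- topGenes(res, cfg$top)
  paths["top_genes"] <- .write_tsv(ranking, file.path(outDir, "top_genes.tsv"))

  sankeyClusters <- cfg$sankey_clusters
  if (is.null(sankeyClusters)) sankeyClusters <- clusterNames(tensor)
  for (cc in sankeyClusters) {
    sk <- sankeyData(tensor, cc, res)
    p <- file.path(outDir, paste0("sankey_", cc, ".json"))
    writeSankey(sk, p)
    paths[paste0("sankey_", cc)] <- p
  }

  ## ---- enrichment ----
  if (!is.null(cfg$gmt)) {
    universe <- names(memberships(res))
    collection <- readGMT(cfg$gmt, universe = universe)
    inputs <- c(inputs, gmt = cfg$gmt)
    enr <- if (identical(cfg$enrich_mode, "weighted"))
      weightedEnrichment(memberships(res), collection, universe,
                         nPerm = cfg$n_perm, seed = cfg$seed)
    else
      hypergeomEnrichment(crispOverlap(memberships(res), cfg$crisp_threshold),
                          collection, universe)
    paths["enrichment"] <- .write_tsv(enr, file.path(outDir, "enrichment.tsv"))
  }

  ## ---- log ----
  log <- c(
    sprintf("FuzzyFlows version: %s",
            as.character(utils::packageVersion("FuzzyFlows"))),
    "parameters:",
    vapply(sort(names(cfg)), function(k)
      sprintf("  %s: %s", k, paste(format(cfg[[k]]), collapse = ",")),
      character(1L)),
    "input checksums:",
    if (length(inputs))
      vapply(names(inputs), function(k) {
        f <- inputs[[k]]
        md5 <- if (dir.exists(f))
          paste(unname(tools::md5sum(sort(list.files(f, full.names = TRUE)))),
                collapse = ",")
        else unname(tools::md5sum(f))
        sprintf("  %s: %s", k, md5)
      }, character(1L))
    else "  (simulated inputs; seed above)",
    sprintf("cells analyzed: %d", ncol(sce)),
    sprintf("genes analyzed: %d", nrow(sce)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  paths["log"] <- file.path(outDir, "run_log.txt")

  invisible(as.list(paths))
}
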