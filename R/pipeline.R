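# End-to-end orchestration: ingest -> Jaccard -> global PCA clusters ->
# hierarchical branches of a selected cluster -> subgroup cut -> per-level
# enrichment -> density profiles -> level attribution. Every run writes a
# manifest (parameters, seed, checksums) so reruns are verifiably identical.

.defaultConfig <- function() {
  list(
    gda = NULL,
    annotations = list(),       # named list of GMT paths (e.g. pathways=...)
    themeMap = NULL,            # CSV/TSV annotation -> theme (pathways level)
    moaMap = NULL,              # CSV/TSV drug -> MOA (drugs level)
    chromosomeMap = NULL,       # TSV gene -> chromosome
    minSize = 10L, maxSize = 1000L,
    globalK = 3L, nComponents = 2L, kmeansRestarts = 50L,
    linkage = "average",
    branchK = 3L, subgroupK = 4L,
    selectCluster = "largest",  # label, "largest" or "all"
    selectBranch = "largest",
    qThreshold = 0.05, family = "per-disease",
    flagThresholds = list(pathways = 0.5, celltypes = 0.4, chromosomes = 0.1),
    nPermutations = 1000L,
    seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks that every referenced file exists and that all
#' thresholds are in range, before any computation starts.
#'
#' @param config named list, or path to a YAML file holding one.
#' @return The completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultConfig(), config)
  if (is.null(cfg$gda)) stop("config: 'gda' path is required", call. = FALSE)
  paths <- c(gda = cfg$gda, unlist(cfg$annotations), themeMap = cfg$themeMap,
             moaMap = cfg$moaMap, chromosomeMap = cfg$chromosomeMap)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("config: missing input file(s): %s",
                 paste(sprintf("%s (%s)", names(missing), missing),
                       collapse = ", ")), call. = FALSE)
  }
  if (cfg$qThreshold <= 0 || cfg$qThreshold > 1) {
    stop("config: qThreshold must lie in (0, 1]", call. = FALSE)
  }
  for (nm in names(cfg$flagThresholds)) {
    .assertFraction(cfg$flagThresholds[[nm]],
                    sprintf("flagThresholds$%s", nm))
  }
  if (cfg$minSize < 1 || cfg$minSize > cfg$maxSize) {
    stop("config: need 1 <= minSize <= maxSize", call. = FALSE)
  }
  cfg
}

.selectGroup <- function(partition, choice) {
  assign <- clusterAssignments(partition)
  if (identical(choice, "all")) return(names(assign))
  lab <- if (identical(choice, "largest")) {
    which.max(clusterSizes(partition))
  } else {
    as.integer(choice)
  }
  if (is.na(lab) || lab < 1 || lab > nClusters(partition)) {
    stop(sprintf("cluster selection '%s' is out of range", choice),
         call. = FALSE)
  }
  names(assign)[assign == lab]
}

#' Run the full disease-comparison pipeline
#'
#' Executes the whole workflow against the files named in `config` and
#' writes every stage's output plus a `manifest.json` (parameters, seed, md5
#' checksums of all outputs) into `outdir`. Rerunning with the same config
#' and seed reproduces identical outputs. Stages: size-filtered gene-set
#' ingest; Jaccard similarity; global PCA/k-means clustering; hierarchical
#' clustering of the selected global cluster and a branch cut; a subgroup
#' cut within the selected branch (the reference partition); per-level
#' enrichment (pathways, cell-types, drugs, chromosomes — whichever inputs
#' the config provides); density profiles with flagging; MOA summary; level
#' attribution by Rand-index concordance.
#'
#' @param config configuration list or YAML path; see
#'   [validatePipelineConfig()].
#' @param outdir run directory, created if needed.
#' @return Invisibly, a list with the key in-memory results (`reference`
#'   partition, `concordance`, `densities`, paths of written artifacts).
#' @export
runPipeline <- function(config, outdir) {
  cfg <- validatePipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(name) {
    p <- file.path(outdir, name)
    artifacts[[length(artifacts) + 1L]] <<- p
    p
  }

  # ingest
  gda <- loadGDA(cfg$gda)
  collection <- buildGeneSets(gda, cfg$minSize, cfg$maxSize)
  writeGMT(collection, put("collection.gmt"))

  # similarity + global clustering
  sim <- jaccardMatrix(collection)
  writeSimilarityMatrix(sim, put("similarity.tsv"))
  pca <- pcaCluster(sim, k = min(cfg$globalK, nSets(collection)),
                    nComponents = cfg$nComponents, seed = cfg$seed,
                    nstart = cfg$kmeansRestarts)
  writePartition(pca$partition, put("global_partition.tsv"))
  utils::write.table(
    data.frame(diseaseId = rownames(pca$scores), pca$scores,
               check.names = FALSE),
    put("pc_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # branch structure within the selected global cluster
  clusterIds <- .selectGroup(pca$partition, cfg$selectCluster)
  clusterSim <- jaccardMatrix(collection[clusterIds])
  hc <- hierarchicalCluster(clusterSim, linkage = cfg$linkage)
  writeNewick(hc, put("dendrogram.nwk"))
  branches <- cutTree(hc, min(cfg$branchK, length(clusterIds)))
  writePartition(branches, put("branch_partition.tsv"))

  # subgroup cut within the selected branch: the reference partition
  branchIds <- .selectGroup(branches, cfg$selectBranch)
  branchSim <- jaccardMatrix(collection[branchIds])
  branchHc <- hierarchicalCluster(branchSim, linkage = cfg$linkage)
  writeNewick(branchHc, put("branch_dendrogram.nwk"))
  reference <- cutTree(branchHc, min(cfg$subgroupK, length(branchIds)))
  writePartition(reference, put("subgroup_partition.tsv"))
  focus <- collection[branchIds]

  # per-level enrichment
  tables <- list()
  for (nm in names(cfg$annotations)) {
    ann <- loadGMT(cfg$annotations[[nm]])
    tables[[nm]] <- enrich(focus, ann, background = universe(collection),
                           qThreshold = cfg$qThreshold, family = cfg$family)
    writeEnrichmentTable(tables[[nm]], put(sprintf("enrichment_%s.tsv", nm)))
  }
  if (!is.null(cfg$chromosomeMap)) {
    chromMap <- loadTwoColumnMap(cfg$chromosomeMap)
    tables$chromosomes <- chromosomeEnrich(focus, chromMap,
                                           qThreshold = cfg$qThreshold,
                                           family = cfg$family)
    writeEnrichmentTable(tables$chromosomes, put("enrichment_chromosomes.tsv"))
  }

  # density profiles
  densities <- list()
  if ("pathways" %in% names(tables) && !is.null(cfg$themeMap)) {
    themeMap <- loadTwoColumnMap(cfg$themeMap)
    sub <- subgroupProfiles(tables$pathways, themeMap, reference,
                            qThreshold = cfg$qThreshold)
    flagged <- flagByThreshold(sub$profile,
                               cfg$flagThresholds$pathways %||% 0.5)
    densities$pathways <- flagged
    utils::write.table(densityTable(flagged), put("density_pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(subgroup = rownames(sub$correlation), sub$correlation,
                 check.names = FALSE),
      put("theme_correlation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  for (nm in setdiff(names(tables), "pathways")) {
    # singleton themes: one density per annotation at this level
    map <- stats::setNames(tables[[nm]]@annotationNames,
                           tables[[nm]]@annotationNames)
    prof <- densityIndex(tables[[nm]], map, qThreshold = cfg$qThreshold)
    thr <- cfg$flagThresholds[[nm]] %||% 0.1
    prof <- flagByThreshold(prof, thr)
    densities[[nm]] <- prof
    utils::write.table(densityTable(prof),
                       put(sprintf("density_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("drugs" %in% names(tables) && !is.null(cfg$moaMap)) {
    moaMap <- loadTwoColumnMap(cfg$moaMap)
    moa <- drugMoaSummary(tables$drugs, moaMap)
    utils::write.table(moa$moaFrequency, put("moa_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(moa$drugDensity, put("drug_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # level attribution
  concordance <- NULL
  if (length(tables) >= 1) {
    concordance <- attributeLevels(reference, tables,
                                   nPermutations = cfg$nPermutations,
                                   seed = cfg$seed, linkage = cfg$linkage)
    conc <- do.call(rbind, lapply(concordance$results, function(r) {
      data.frame(level = r@level, randIndex = r@randIndex,
                 adjustedRandIndex = r@adjustedRandIndex, pValue = r@pValue,
                 nPermutations = r@nPermutations, seed = r@seed,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(conc, put("concordance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(concordance$results, function(r) {
        list(level = r@level, randIndex = r@randIndex,
             adjustedRandIndex = r@adjustedRandIndex, pValue = r@pValue,
             nPermutations = r@nPermutations)
      }),
      file.path(outdir, "concordance.json"), auto_unbox = TRUE, digits = NA)
    artifacts[[length(artifacts) + 1L]] <- file.path(outdir, "concordance.json")
  }

  manifest <- list(
    package = "psygset",
    parameters = cfg[setdiff(names(cfg), character(0))],
    seed = cfg$seed,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(collection = collection, globalPartition = pca$partition,
                 branches = branches, reference = reference,
                 enrichment = tables, densities = densities,
                 concordance = concordance, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a completed run directory
#'
#' Writes `report.txt` in the run directory: the filtering funnel, the
#' cluster/branch/subgroup sizes, flagged density rows per level and the
#' level-attribution table. Regeneration is idempotent. Missing stage
#' outputs raise an error naming the absent artifact.
#'
#' @param outdir a directory produced by [runPipeline()].
#' @return The report path, invisibly.
#' @export
makeReport <- function(outdir) {
  need <- c("manifest.json", "collection.gmt", "subgroup_partition.tsv")
  absent <- need[!file.exists(file.path(outdir, need))]
  if (length(absent) > 0) {
    stop(sprintf("incomplete run: missing artifact(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  lines <- c("psygset pipeline report", "=======================", "")
  collection <- loadGMT(file.path(outdir, "collection.gmt"))
  lines <- c(lines, sprintf("gene sets analysed: %d", nSets(collection)),
             sprintf("seed: %s", manifest$seed))
  ref <- loadPartition(file.path(outdir, "subgroup_partition.tsv"))
  lines <- c(lines, sprintf("subgroups (reference partition): %s",
                            paste(clusterSizes(ref), collapse = ", ")), "")
  for (f in list.files(outdir, pattern = "^density_.*\\.tsv$")) {
    df <- utils::read.delim(file.path(outdir, f))
    level <- sub("^density_(.*)\\.tsv$", "\\1", f)
    flagged <- df[df$flagged & df$diseaseSet == "all", , drop = FALSE]
    lines <- c(lines, sprintf("%s: %d theme(s)/annotation(s), %d flagged:",
                              level, length(unique(df$theme)), nrow(flagged)))
    if (nrow(flagged) > 0) {
      lines <- c(lines, sprintf("  %s (density %.3f)", flagged$theme,
                                flagged$density))
    }
    lines <- c(lines, "")
  }
  concPath <- file.path(outdir, "concordance.tsv")
  if (file.exists(concPath)) {
    conc <- utils::read.delim(concPath)
    lines <- c(lines, "level attribution (sorted by Rand index):",
               sprintf("  %-12s RI = %.3f  ARI = %.3f  p = %.4g",
                       conc$level, conc$randIndex, conc$adjustedRandIndex,
                       conc$pValue))
  }
  path <- file.path(outdir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
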