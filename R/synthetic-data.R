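# Synthetic GDA studies with planted structure. Pools are laid out
# deterministically over the universe (shared pool first, then the disjoint
# cluster pools); all randomness is per-entity sampling driven by substreams
# of the global seed, so adding diseases never perturbs earlier ones.

#' Create a synthetic study specification
#'
#' See [SyntheticSpec-class] for the planted-structure model. Defaults mirror
#' the benchmark configuration used throughout the package: 36 diseases in
#' four subgroups of 8, 11, 11 and 6 (the size pattern of the psychiatric
#' cluster the pipeline is designed around), 100 genes per disease over a
#' 1500-gene universe, with half of each set from the cluster-private pool
#' and none shared.
#'
#' @param nDiseases,nClusters,clusterSizes planted grouping.
#' @param geneUniverseSize,corePoolSize,sharedPoolSize pool sizes.
#' @param genesPerDisease exact gene-set size per disease.
#' @param coreFraction,sharedFraction fractions of each set drawn from the
#'   cluster pool / shared pool (sum <= 1; remainder uniform from the rest of
#'   the universe).
#' @param chromosomeCount chromosomes for [generateChromosomeMap()].
#' @param biasedCluster,biasedChromosome,biasWeight optional chromosome bias:
#'   genes of `biasedCluster`'s pool land on `biasedChromosome` with
#'   probability proportional to `biasWeight` (vs 1 for each other
#'   chromosome). `biasWeight = 1` is the unbiased uniform assignment.
#' @param seed global integer seed.
#' @return A validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(seed = 7)
#' spec
#' @export
syntheticSpec <- function(nDiseases = 36L, nClusters = 4L,
                          clusterSizes = c(8L, 11L, 11L, 6L),
                          geneUniverseSize = 1500L, corePoolSize = 200L,
                          genesPerDisease = 100L, coreFraction = 0.5,
                          sharedPoolSize = 150L, sharedFraction = 0,
                          chromosomeCount = 22L, biasedCluster = NA_integer_,
                          biasedChromosome = NA_integer_,
                          biasWeight = NA_real_, seed = 1L) {
  .assertCount(nDiseases, "nDiseases")
  .assertCount(nClusters, "nClusters")
  .assertCount(geneUniverseSize, "geneUniverseSize")
  .assertCount(corePoolSize, "corePoolSize")
  .assertCount(genesPerDisease, "genesPerDisease")
  .assertCount(sharedPoolSize, "sharedPoolSize", min = 0L)
  .assertCount(chromosomeCount, "chromosomeCount")
  .assertFraction(coreFraction, "coreFraction")
  .assertFraction(sharedFraction, "sharedFraction")
  new("SyntheticSpec",
      nDiseases = as.integer(nDiseases), nClusters = as.integer(nClusters),
      clusterSizes = as.integer(clusterSizes),
      geneUniverseSize = as.integer(geneUniverseSize),
      corePoolSize = as.integer(corePoolSize),
      genesPerDisease = as.integer(genesPerDisease),
      coreFraction = as.numeric(coreFraction),
      sharedPoolSize = as.integer(sharedPoolSize),
      sharedFraction = as.numeric(sharedFraction),
      chromosomeCount = as.integer(chromosomeCount),
      biasedCluster = as.integer(biasedCluster),
      biasedChromosome = as.integer(biasedChromosome),
      biasWeight = as.numeric(biasWeight), seed = as.integer(seed))
}

# Deterministic pool layout over the universe.
.genePools <- function(spec) {
  genes <- sprintf("G%05d", seq_len(spec@geneUniverseSize))
  shared <- genes[seq_len(spec@sharedPoolSize)]
  cluster <- vector("list", spec@nClusters)
  offset <- spec@sharedPoolSize
  for (c in seq_len(spec@nClusters)) {
    cluster[[c]] <- genes[offset + seq_len(spec@corePoolSize)]
    offset <- offset + spec@corePoolSize
  }
  list(universe = genes, shared = shared, cluster = cluster)
}

#' Generate a synthetic gene-disease association table
#'
#' Draws each disease's gene set without replacement: `coreFraction` of its
#' genes from its cluster's private pool, `sharedFraction` from the pool
#' shared by all diseases, and the remainder uniformly from the rest of the
#' universe. Every set has exactly `genesPerDisease` distinct genes. Disease
#' names encode the planted cluster ("D<cluster>_<index>").
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with `table` (data.frame diseaseId, diseaseName, geneSymbol)
#'   and `truth` (the planted [Partition-class]).
#' @examples
#' gda <- generateGDA(syntheticSpec(seed = 7))
#' head(gda$table)
#' clusterSizes(gda$truth)
#' @export
generateGDA <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  pools <- .genePools(spec)
  gpd <- spec@genesPerDisease
  nCore <- as.integer(round(spec@coreFraction * gpd))
  nShared <- min(as.integer(round(spec@sharedFraction * gpd)), gpd - nCore)
  nRest <- gpd - nCore - nShared

  clusterOf <- rep(seq_len(spec@nClusters), times = spec@clusterSizes)
  withinIdx <- unlist(lapply(spec@clusterSizes, seq_len), use.names = FALSE)
  ids <- sprintf("DIS%03d", seq_len(spec@nDiseases))
  nms <- sprintf("D%d_%d", clusterOf, withinIdx)

  rows <- vector("list", spec@nDiseases)
  for (i in seq_len(spec@nDiseases)) {
    c <- clusterOf[i]
    genes <- .withSeed(.substream(spec@seed, i), {
      core <- sample(pools$cluster[[c]], nCore)
      shr <- sample(pools$shared, nShared)
      rest <- if (nRest > 0) {
        sample(setdiff(pools$universe, c(core, shr)), nRest)
      } else {
        character(0)
      }
      c(core, shr, rest)
    })
    rows[[i]] <- data.frame(diseaseId = ids[i], diseaseName = nms[i],
                            geneSymbol = genes, stringsAsFactors = FALSE)
  }
  truth <- Partition(clusterOf, items = ids)
  list(table = do.call(rbind, rows), truth = truth)
}

#' Generate an annotation collection with planted themes
#'
#' Builds a GMT-compatible annotation collection whose sets are sampled
#' strictly inside designated gene pools: a theme over the shared pool is
#' ubiquitous (every disease is enriched for it, since every disease draws
#' from that pool), a theme over a cluster pool is private to that cluster's
#' diseases. Themes requesting zero sets are omitted.
#'
#' @param spec a [SyntheticSpec-class].
#' @param themes data.frame with columns `theme` (name), `pool` ("shared",
#'   "universe" or "cluster<i>"), `nSets` (sets to derive) and `setSize`
#'   (genes per set).
#' @return List with `collection` (a [GeneSetCollection-class] over the full
#'   universe) and `themeMap` (named character, annotation -> theme).
#' @examples
#' spec <- syntheticSpec(sharedFraction = 0.5, seed = 7)
#' th <- data.frame(theme = c("ubiquitous", "cluster1_private"),
#'                  pool = c("shared", "cluster1"), nSets = 3, setSize = 40)
#' ann <- generateAnnotations(spec, th)
#' nSets(ann$collection)
#' @export
generateAnnotations <- function(spec, themes) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  need <- c("theme", "pool", "nSets", "setSize")
  if (!is.data.frame(themes) || !all(need %in% names(themes))) {
    stop("'themes' must be a data.frame with columns theme, pool, nSets, setSize",
         call. = FALSE)
  }
  pools <- .genePools(spec)
  sets <- list()
  themeMap <- character(0)
  for (t in seq_len(nrow(themes))) {
    nSets <- themes$nSets[t]
    if (nSets == 0) next
    pool <- .resolvePool(themes$pool[t], pools, spec)
    size <- themes$setSize[t]
    if (size > length(pool)) {
      stop(sprintf("theme '%s': setSize %d exceeds pool size %d",
                   themes$theme[t], size, length(pool)), call. = FALSE)
    }
    for (j in seq_len(nSets)) {
      nm <- sprintf("%s_p%02d", themes$theme[t], j)
      sets[[nm]] <- .withSeed(.substream(spec@seed, 100000 + 1000 * t + j),
                              sort(sample(pool, size)))
      themeMap[nm] <- themes$theme[t]
    }
  }
  list(collection = GeneSetCollection(sets, universe = pools$universe),
       themeMap = themeMap)
}

.resolvePool <- function(label, pools, spec) {
  label <- as.character(label)
  if (label == "shared") {
    if (spec@sharedPoolSize == 0) {
      stop("pool 'shared' is empty (sharedPoolSize = 0)", call. = FALSE)
    }
    return(pools$shared)
  }
  if (label == "universe") return(pools$universe)
  m <- regmatches(label, regexec("^cluster([0-9]+)$", label))[[1]]
  if (length(m) == 2) {
    k <- as.integer(m[2])
    if (k >= 1 && k <= spec@nClusters) return(pools$cluster[[k]])
  }
  stop(sprintf("undefined pool '%s' (use 'shared', 'universe' or 'cluster<i>')",
               label), call. = FALSE)
}

#' Generate a gene-to-chromosome assignment
#'
#' Assigns every universe gene to exactly one chromosome. Without bias the
#' assignment is uniform multinomial. With `biasedCluster`/`biasedChromosome`
#' set, genes of that cluster's pool are assigned to that chromosome with
#' probability `biasWeight / (biasWeight + chromosomeCount - 1)`, i.e.
#' proportional to the bias weight.
#'
#' @param spec a [SyntheticSpec-class].
#' @return Named character vector gene -> "chr<i>".
#' @examples
#' map <- generateChromosomeMap(syntheticSpec(seed = 7))
#' table(map)[1:3]
#' @export
generateChromosomeMap <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  pools <- .genePools(spec)
  chroms <- sprintf("chr%d", seq_len(spec@chromosomeCount))
  assign <- .withSeed(.substream(spec@seed, 900001),
                      sample(chroms, spec@geneUniverseSize, replace = TRUE))
  names(assign) <- pools$universe
  if (!is.na(spec@biasedCluster)) {
    pool <- pools$cluster[[spec@biasedCluster]]
    probs <- rep(1, spec@chromosomeCount)
    probs[spec@biasedChromosome] <- spec@biasWeight
    assign[pool] <- .withSeed(.substream(spec@seed, 900002),
                              sample(chroms, length(pool), replace = TRUE,
                                     prob = probs))
  }
  assign
}

#' Generate drug signatures with a mode-of-action map
#'
#' Samples each drug's signature from a designated pool (default the shared
#' pool, so the drugs enrich across all diseases that draw shared genes) and
#' assigns drugs to modes of action round-robin, so every drug has exactly
#' one MOA.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nDrugs,moaCount counts with `nDrugs >= moaCount >= 1`.
#' @param pool pool label as in [generateAnnotations()].
#' @param signatureSize genes per drug signature.
#' @return List with `collection` (drug signatures as a
#'   [GeneSetCollection-class]) and `moaMap` (named character drug -> MOA).
#' @examples
#' spec <- syntheticSpec(sharedFraction = 0.5, seed = 7)
#' drugs <- generateDrugSignatures(spec, nDrugs = 6, moaCount = 3)
#' drugs$moaMap
#' @export
generateDrugSignatures <- function(spec, nDrugs, moaCount, pool = "shared",
                                   signatureSize = 20L) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  .assertCount(nDrugs, "nDrugs")
  .assertCount(moaCount, "moaCount")
  if (nDrugs < moaCount) {
    stop("'nDrugs' must be >= 'moaCount'", call. = FALSE)
  }
  pools <- .genePools(spec)
  src <- .resolvePool(pool, pools, spec)
  if (signatureSize > length(src)) {
    stop(sprintf("signatureSize %d exceeds pool size %d", signatureSize,
                 length(src)), call. = FALSE)
  }
  drugs <- sprintf("drug%03d", seq_len(nDrugs))
  moas <- sprintf("MOA%02d", seq_len(moaCount))
  sets <- lapply(seq_len(nDrugs), function(i) {
    .withSeed(.substream(spec@seed, 500000 + i),
              sort(sample(src, signatureSize)))
  })
  names(sets) <- drugs
  moaMap <- moas[((seq_len(nDrugs) - 1L) %% moaCount) + 1L]
  names(moaMap) <- drugs
  list(collection = GeneSetCollection(sets, universe = pools$universe),
       moaMap = moaMap)
}
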