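#' Named collection of gene sets over a background universe
#'
#' Container for named sets of gene symbols together with the background
#' universe against which overrepresentation is tested. Every member of every
#' set must belong to the universe; the universe may be larger than the union
#' of the sets (it is fixed by the unfiltered input, not by filtering).
#'
#' @slot sets named list of character vectors (unique gene symbols each).
#' @slot universe character vector of background gene symbols.
#'
#' @seealso [GeneSetCollection()], [buildGeneSets()], [loadGMT()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  nm <- names(object@sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    return("all sets must be named with non-empty names")
  }
  if (anyDuplicated(nm)) {
    return(sprintf("duplicated set name(s): %s",
                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (anyDuplicated(object@universe)) {
    return("universe contains duplicated gene symbols")
  }
  for (i in seq_along(object@sets)) {
    s <- object@sets[[i]]
    if (!is.character(s)) return(sprintf("set '%s' is not character", nm[i]))
    if (anyDuplicated(s)) {
      return(sprintf("set '%s' contains duplicated genes", nm[i]))
    }
    if (!all(s %in% object@universe)) {
      return(sprintf("set '%s' contains genes outside the universe", nm[i]))
    }
  }
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols. Duplicate
#'   symbols within a set are collapsed.
#' @param universe background gene symbols; defaults to the union of `sets`.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' setSizes(gsc)
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) universe <- character(0)
  }
  new("GeneSetCollection", sets = sets, universe = unique(as.character(universe)))
}

#' Disease-by-disease Jaccard similarity matrix
#'
#' Symmetric matrix of Jaccard coefficients J(A,B) = |A n B| / |A u B|
#' between disease gene-sets, with unit diagonal and entries in [0, 1].
#'
#' @slot values numeric matrix with identical row/column dimnames.
#' @seealso [jaccardMatrix()]
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v)) return("values must be square numeric")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    return("row and column names must be present and identical")
  }
  if (any(!is.finite(v))) return("non-finite similarity values")
  if (any(v < 0 | v > 1)) return("similarities must lie in [0, 1]")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
  if (any(abs(diag(v) - 1) > 1e-12)) return("diagonal must be exactly 1")
  TRUE
})

#' Partition of items into clusters
#'
#' Assignment of each item to exactly one cluster. Labels are stored in
#' canonical form: small integers numbered by first appearance along the item
#' order, so two partitions with the same grouping but different label names
#' compare equal after construction.
#'
#' @slot assignment named integer vector; names are item ids, values cluster
#'   labels in 1..k.
#' @seealso [Partition()], [cutTree()], [pcaCluster()]
#' @export
setClass("Partition", representation(assignment = "integer"))

setValidity("Partition", function(object) {
  a <- object@assignment
  if (length(a) == 0L) return("partition must contain at least one item")
  if (is.null(names(a)) || any(!nzchar(names(a)))) {
    return("all items must be named")
  }
  if (anyDuplicated(names(a))) return("duplicated item ids")
  if (any(is.na(a))) return("every item must be assigned a cluster")
  k <- max(a)
  if (min(a) < 1L || !setequal(unique(a), seq_len(k))) {
    return("labels must be canonical integers 1..k")
  }
  TRUE
})

#' Construct a Partition
#'
#' @param assignment vector of cluster labels (integer, character or factor),
#'   named by item id, or unnamed with `items` supplied.
#' @param items item ids; defaults to `names(assignment)`.
#' @return A [Partition-class] with canonical integer labels.
#' @examples
#' p <- Partition(c(a = "x", b = "x", c = "y"))
#' nClusters(p)
#' @export
Partition <- function(assignment, items = names(assignment)) {
  if (is.null(items)) {
    stop("'assignment' must be named or 'items' supplied", call. = FALSE)
  }
  lab <- as.character(assignment)
  canon <- as.integer(factor(lab, levels = unique(lab)))
  names(canon) <- as.character(items)
  new("Partition", assignment = canon)
}

#' Overrepresentation analysis results
#'
#' One row per (disease, annotation) pair with non-empty overlap: overlap
#' count `k`, query size `n`, annotation size `K`, background size `N`,
#' upper-tail hypergeometric p-value, BH q-value and the overlapping genes.
#' Pairs with k = 0 are not stored; downstream code treats absence as
#' non-significance. The full sets of tested diseases and annotations are
#' retained so densities have the correct denominators.
#'
#' @slot results data.frame with columns diseaseId, annotation, k, n, K, N,
#'   pValue, qValue, genes.
#' @slot diseaseIds all query set names that were tested.
#' @slot annotationNames all annotation set names that were tested.
#' @slot backgroundSize size of the hypergeometric background.
#' @slot qThreshold significance threshold recorded at test time.
#' @slot family FDR correction family, "per-disease" or "global".
#' @seealso [enrich()], [chromosomeEnrich()]
#' @export
setClass("EnrichmentTable",
         representation(results = "data.frame", diseaseIds = "character",
                        annotationNames = "character",
                        backgroundSize = "integer", qThreshold = "numeric",
                        family = "character"))

setValidity("EnrichmentTable", function(object) {
  r <- object@results
  need <- c("diseaseId", "annotation", "k", "n", "K", "N", "pValue",
            "qValue", "genes")
  if (!all(need %in% names(r))) {
    return(sprintf("results missing column(s): %s",
                   paste(setdiff(need, names(r)), collapse = ", ")))
  }
  if (nrow(r) > 0) {
    if (any(r$k < 1 | r$k > pmin(r$n, r$K))) {
      return("overlap counts must satisfy 1 <= k <= min(n, K)")
    }
    if (any(r$pValue <= 0 | r$pValue > 1)) return("p-values must lie in (0, 1]")
    if (any(r$qValue <= 0 | r$qValue > 1)) return("q-values must lie in (0, 1]")
    if (!all(r$diseaseId %in% object@diseaseIds)) {
      return("results refer to diseases outside diseaseIds")
    }
    if (!all(r$annotation %in% object@annotationNames)) {
      return("results refer to annotations outside annotationNames")
    }
  }
  if (object@qThreshold <= 0 || object@qThreshold > 1) {
    return("qThreshold must lie in (0, 1]")
  }
  if (!object@family %in% c("per-disease", "global")) {
    return("family must be 'per-disease' or 'global'")
  }
  TRUE
})

#' Density-index profile over themes and disease sets
#'
#' For a theme (a named group of annotations) and a disease set, the density
#' index is the fill fraction of significant cells in the disease-by-
#' theme-annotation significance matrix: n_significant / (n_diseases x
#' n_annotations). Near 1 the theme is shared across the diseases; near 0 it
#' is confined to a few.
#'
#' @slot profile data.frame with columns theme, diseaseSet, density,
#'   nDiseases, nAnnotations, nSignificant, flagged.
#' @slot qThreshold significance threshold used when counting cells.
#' @slot flagThreshold density threshold used by [flagByThreshold()] (NA
#'   before flagging).
#' @seealso [densityIndex()], [subgroupProfiles()]
#' @export
setClass("DensityProfile",
         representation(profile = "data.frame", qThreshold = "numeric",
                        flagThreshold = "numeric"))

setValidity("DensityProfile", function(object) {
  p <- object@profile
  need <- c("theme", "diseaseSet", "density", "nDiseases", "nAnnotations",
            "nSignificant", "flagged")
  if (!all(need %in% names(p))) {
    return(sprintf("profile missing column(s): %s",
                   paste(setdiff(need, names(p)), collapse = ", ")))
  }
  if (nrow(p) > 0 && any(p$density < 0 | p$density > 1)) {
    return("densities must lie in [0, 1]")
  }
  TRUE
})

#' Concordance between two partitions
#'
#' Rand index between a level-derived partition and a reference partition,
#' with an add-one permutation p-value under the size-preserving label
#' permutation null: p = (1 + #\{RI_perm >= RI_obs\}) / (1 + n_permutations).
#'
#' @slot level name of the compared level.
#' @slot randIndex observed Rand index in [0, 1].
#' @slot adjustedRandIndex chance-corrected Rand index (reported for context).
#' @slot pValue add-one permutation p-value in (0, 1].
#' @slot nPermutations number of permutations.
#' @slot seed RNG seed used for the permutations.
#' @slot permSummary named numeric: mean, sd, max of the permuted RI values
#'   and nGE, the count of permutations with RI >= observed.
#' @seealso [permutationTest()], [attributeLevels()]
#' @export
setClass("ConcordanceResult",
         representation(level = "character", randIndex = "numeric",
                        adjustedRandIndex = "numeric", pValue = "numeric",
                        nPermutations = "integer", seed = "integer",
                        permSummary = "numeric"))

setValidity("ConcordanceResult", function(object) {
  if (object@randIndex < 0 || object@randIndex > 1) return("RI must be in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1) return("p-value must be in (0, 1]")
  if (object@nPermutations < 1L) return("nPermutations must be >= 1")
  TRUE
})

#' Specification of a synthetic gene-disease-association study
#'
#' Describes planted structure for the synthetic generators: diseases grouped
#' into clusters, each disease's gene set drawn partly from its cluster's
#' private gene pool (fraction `coreFraction`), partly from a pool shared by
#' all diseases (fraction `sharedFraction`), the remainder uniformly from the
#' rest of the universe. Cluster pools are pairwise disjoint and disjoint
#' from the shared pool. Optionally one cluster's pool is biased towards one
#' chromosome with weight `biasWeight` (1 = unbiased uniform assignment).
#'
#' @slot nDiseases,nClusters,clusterSizes planted grouping; `clusterSizes`
#'   must sum to `nDiseases`.
#' @slot geneUniverseSize,corePoolSize,sharedPoolSize pool sizes (genes).
#' @slot genesPerDisease exact size of every disease gene-set.
#' @slot coreFraction,sharedFraction sampling fractions, sum <= 1.
#' @slot chromosomeCount number of chromosomes for the gene->chromosome map.
#' @slot biasedCluster,biasedChromosome,biasWeight optional chromosome bias
#'   (NA when absent).
#' @slot seed global integer seed; all generators derive per-entity
#'   substreams from it.
#' @seealso [syntheticSpec()], [generateGDA()]
#' @export
setClass("SyntheticSpec",
         representation(nDiseases = "integer", nClusters = "integer",
                        clusterSizes = "integer", geneUniverseSize = "integer",
                        corePoolSize = "integer", genesPerDisease = "integer",
                        coreFraction = "numeric", sharedPoolSize = "integer",
                        sharedFraction = "numeric", chromosomeCount = "integer",
                        biasedCluster = "integer", biasedChromosome = "integer",
                        biasWeight = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@clusterSizes) != object@nClusters) {
    return("clusterSizes: must contain one size per cluster")
  }
  if (any(object@clusterSizes < 1L)) return("clusterSizes: all must be >= 1")
  if (sum(object@clusterSizes) != object@nDiseases) {
    return("clusterSizes: must sum to nDiseases")
  }
  if (object@coreFraction + object@sharedFraction > 1 + 1e-12) {
    return("coreFraction + sharedFraction must be <= 1")
  }
  pools <- object@sharedPoolSize + object@nClusters * object@corePoolSize
  if (pools > object@geneUniverseSize) {
    return("geneUniverseSize: too small for disjoint shared and cluster pools")
  }
  if (object@genesPerDisease > object@geneUniverseSize) {
    return("genesPerDisease: exceeds geneUniverseSize")
  }
  nCore <- round(object@coreFraction * object@genesPerDisease)
  nShared <- min(round(object@sharedFraction * object@genesPerDisease),
                 object@genesPerDisease - nCore)
  if (nCore > object@corePoolSize) {
    return("coreFraction: requires more genes than corePoolSize")
  }
  if (nShared > object@sharedPoolSize) {
    return("sharedFraction: requires more genes than sharedPoolSize")
  }
  if (object@chromosomeCount < 1L) return("chromosomeCount: must be >= 1")
  bias <- c(is.na(object@biasedCluster), is.na(object@biasedChromosome),
            is.na(object@biasWeight))
  if (any(bias) && !all(bias)) {
    return("biasedCluster/biasedChromosome/biasWeight must be set together")
  }
  if (!any(bias)) {
    if (object@biasedCluster < 1L || object@biasedCluster > object@nClusters) {
      return("biasedCluster: out of range")
    }
    if (object@biasedChromosome < 1L ||
        object@biasedChromosome > object@chromosomeCount) {
      return("biasedChromosome: out of range")
    }
    if (object@biasWeight < 1) return("biasWeight: must be >= 1")
  }
  TRUE
})
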