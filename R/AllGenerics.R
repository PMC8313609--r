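#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' Jaccard similarity matrix between all pairs of gene sets
#'
#' Computes J(A,B) = |A n B| / |A u B| for every pair of sets in the
#' collection; exact integer arithmetic, symmetric with unit diagonal.
#'
#' @param x a [GeneSetCollection-class] with at least two non-empty sets.
#' @return A [SimilarityMatrix-class].
#' @examples
#' gsc <- GeneSetCollection(list(A = c("g1", "g2", "g3"),
#'                               B = c("g2", "g3", "g4")))
#' simValues(jaccardMatrix(gsc))["A", "B"]  # 2/4
#' @export
setGeneric("jaccardMatrix", function(x) standardGeneric("jaccardMatrix"))

#' @rdname SimilarityMatrix-class
#' @param x a `SimilarityMatrix`.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname Partition-class
#' @param x a `Partition`.
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname Partition-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname Partition-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname EnrichmentTable-class
#' @param x an `EnrichmentTable`.
#' @export
setGeneric("enrichmentResults",
           function(x) standardGeneric("enrichmentResults"))

#' Significant enrichment rows
#'
#' @param x an [EnrichmentTable-class].
#' @param qThreshold significance threshold; defaults to the one recorded at
#'   test time.
#' @return data.frame of rows with qValue < qThreshold.
#' @export
setGeneric("significantHits",
           function(x, qThreshold = NULL) standardGeneric("significantHits"))

#' @rdname DensityProfile-class
#' @param x a `DensityProfile`.
#' @export
setGeneric("densityTable", function(x) standardGeneric("densityTable"))

#' Rand index between two partitions
#'
#' Fraction of item pairs on which the two partitions agree (co-clustered in
#' both or separated in both): RI = (agreeing pairs) / C(n, 2). Symmetric and
#' invariant to cluster relabelling.
#'
#' @param p1,p2 [Partition-class] objects over identical item sets (>= 2
#'   items).
#' @return Numeric scalar in [0, 1].
#' @examples
#' p <- Partition(c(a = 1, b = 1, c = 2, d = 2))
#' q <- Partition(c(a = 1, b = 2, c = 1, d = 2))
#' randIndex(p, q)  # 1/3
#' @export
setGeneric("randIndex", function(p1, p2) standardGeneric("randIndex"))

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected version of the Rand index (expected value 0 under the
#' generalized hypergeometric null, 1 for identical groupings).
#'
#' @inheritParams randIndex
#' @return Numeric scalar (<= 1; can be negative).
#' @export
setGeneric("adjustedRandIndex",
           function(p1, p2) standardGeneric("adjustedRandIndex"))
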