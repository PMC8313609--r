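# Accessors, show methods and small utilities for the core classes.

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("nSets", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("setSizes", "GeneSetCollection",
          function(x) vapply(x@sets, length, integer(1)))

#' @describeIn GeneSetCollection-class subset the collection by set name;
#'   the universe is unchanged (the background is defined by the input data,
#'   not by filtering).
#' @param i character or integer index of sets to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    missing <- setdiff(i, names(x@sets))
    if (length(missing) > 0) {
      stop(sprintf("unknown set(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  new("GeneSetCollection", sets = x@sets[i], universe = x@universe)
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- setSizes(object)
  cat(sprintf("GeneSetCollection: %d set(s), universe of %d gene(s)\n",
              nSets(object), length(object@universe)))
  if (length(sz) > 0) {
    cat(sprintf("  set sizes: min %d, median %s, max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
  }
})

#' @rdname SimilarityMatrix-class
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("SimilarityMatrix: %d x %d diseases\n", nrow(v), ncol(v)))
  if (length(off) > 0) {
    cat(sprintf("  off-diagonal Jaccard: min %.3f, mean %.3f, max %.3f\n",
                min(off), mean(off), max(off)))
  }
})

#' @rdname Partition-class
#' @export
setMethod("clusterAssignments", "Partition", function(x) x@assignment)

#' @rdname Partition-class
#' @export
setMethod("nClusters", "Partition", function(x) max(x@assignment))

#' @rdname Partition-class
#' @export
setMethod("clusterSizes", "Partition",
          function(x) tabulate(x@assignment, nbins = max(x@assignment)))

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d item(s) in %d cluster(s); sizes: %s\n",
              length(object@assignment), nClusters(object),
              paste(clusterSizes(object), collapse = ", ")))
})

#' @describeIn Partition-class coerce to a two-column data.frame
#'   (item, cluster).
#' @param row.names,optional,... passed over from the generic (unused).
#' @export
setMethod("as.data.frame", "Partition",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(item = names(x@assignment), cluster = unname(x@assignment),
             stringsAsFactors = FALSE)
})

#' @rdname EnrichmentTable-class
#' @export
setMethod("enrichmentResults", "EnrichmentTable", function(x) x@results)

#' @rdname significantHits
#' @export
setMethod("significantHits", "EnrichmentTable",
          function(x, qThreshold = NULL) {
  thr <- if (is.null(qThreshold)) x@qThreshold else qThreshold
  x@results[x@results$qValue < thr, , drop = FALSE]
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf(paste0("EnrichmentTable: %d disease(s) x %d annotation(s), ",
                     "background %d genes\n"),
              length(object@diseaseIds), length(object@annotationNames),
              object@backgroundSize))
  cat(sprintf("  %d pair(s) with overlap; %d significant at q < %g (%s BH)\n",
              nrow(object@results),
              sum(object@results$qValue < object@qThreshold),
              object@qThreshold, object@family))
})

#' @rdname DensityProfile-class
#' @export
setMethod("densityTable", "DensityProfile", function(x) x@profile)

setMethod("show", "DensityProfile", function(object) {
  p <- object@profile
  cat(sprintf("DensityProfile: %d theme(s) x %d disease set(s)\n",
              length(unique(p$theme)), length(unique(p$diseaseSet))))
  if (!is.na(object@flagThreshold)) {
    cat(sprintf("  %d row(s) flagged at density >= %g\n",
                sum(p$flagged), object@flagThreshold))
  }
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult '%s': RI = %.3f (ARI = %.3f), p = %.4g\n",
              object@level, object@randIndex, object@adjustedRandIndex,
              object@pValue))
  cat(sprintf("  permutation null: %d permutation(s), seed %d, mean RI %.3f\n",
              object@nPermutations, object@seed,
              object@permSummary[["mean"]]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d diseases in %d cluster(s) (%s); ",
                     "%d genes/disease\n"),
              object@nDiseases, object@nClusters,
              paste(object@clusterSizes, collapse = ", "),
              object@genesPerDisease))
  cat(sprintf("  universe %d; core %.2f of %d/cluster; shared %.2f of %d\n",
              object@geneUniverseSize, object@coreFraction,
              object@corePoolSize, object@sharedFraction,
              object@sharedPoolSize))
  if (!is.na(object@biasedCluster)) {
    cat(sprintf("  chromosome bias: cluster %d -> chr%d, weight %g\n",
                object@biasedCluster, object@biasedChromosome,
                object@biasWeight))
  }
})
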