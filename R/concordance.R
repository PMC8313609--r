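# Level attribution: cluster diseases from each level's enrichment profile,
# compare partitions by the Rand index, attach a permutation p-value under
# the size-preserving label-permutation null.

.alignPartitions <- function(p1, p2) {
  i1 <- names(clusterAssignments(p1))
  i2 <- names(clusterAssignments(p2))
  only1 <- setdiff(i1, i2)
  only2 <- setdiff(i2, i1)
  if (length(only1) > 0 || length(only2) > 0) {
    stop(sprintf(
      "partitions cover different items (only in p1: %s; only in p2: %s)",
      paste(only1, collapse = ","), paste(only2, collapse = ",")),
      call. = FALSE)
  }
  if (length(i1) < 2) stop("need at least 2 items", call. = FALSE)
  list(l1 = unname(clusterAssignments(p1)[i1]),
       l2 = unname(clusterAssignments(p2)[i1]))
}

# Rand index from two aligned integer label vectors (pair-count identity on
# the contingency table).
.randFromLabels <- function(l1, l2) {
  n <- length(l1)
  tab <- table(l1, l2)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sumij - sumi - sumj) / total
}

.adjustedRandFromLabels <- function(l1, l2) {
  n <- length(l1)
  tab <- table(l1, l2)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sumi * sumj / total
  denom <- (sumi + sumj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in form
  (sumij - expected) / denom
}

#' @rdname randIndex
#' @export
setMethod("randIndex", signature("Partition", "Partition"), function(p1, p2) {
  a <- .alignPartitions(p1, p2)
  .randFromLabels(a$l1, a$l2)
})

#' @rdname adjustedRandIndex
#' @export
setMethod("adjustedRandIndex", signature("Partition", "Partition"),
          function(p1, p2) {
  a <- .alignPartitions(p1, p2)
  .adjustedRandFromLabels(a$l1, a$l2)
})

#' Permutation test for partition concordance
#'
#' Permutes the item -> label assignment of `p2` uniformly (preserving its
#' cluster sizes), recomputes the Rand index against `p1` for each
#' permutation, and reports the add-one p-value
#' p = (1 + #\{RI_perm >= RI_obs\}) / (1 + nPermutations), which is never 0
#' and exactly valid under exchangeability.
#'
#' @param p1,p2 [Partition-class] objects over identical item sets.
#' @param nPermutations number of label permutations (default 10000, enough
#'   to resolve p-values near 1e-4).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param level name recorded in the result.
#' @return A [ConcordanceResult-class].
#' @examples
#' p <- Partition(c(a = 1, b = 1, c = 2, d = 2, e = 3, f = 3))
#' permutationTest(p, p, nPermutations = 99, seed = 1)
#' @export
permutationTest <- function(p1, p2, nPermutations = 10000L, seed = 1L,
                            level = "level") {
  a <- .alignPartitions(p1, p2)
  .assertCount(nPermutations, "nPermutations")
  obs <- .randFromLabels(a$l1, a$l2)
  perm <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(b) {
      .randFromLabels(a$l1, sample(a$l2))
    }, numeric(1))
  })
  nGE <- sum(perm >= obs - 1e-12)
  new("ConcordanceResult", level = level,
      randIndex = obs,
      adjustedRandIndex = .adjustedRandFromLabels(a$l1, a$l2),
      pValue = (1 + nGE) / (1 + nPermutations),
      nPermutations = as.integer(nPermutations), seed = as.integer(seed),
      permSummary = c(mean = mean(perm), sd = stats::sd(perm),
                      max = max(perm), nGE = nGE))
}

#' Cluster diseases from an enrichment profile
#'
#' Embeds each disease as the binary vector of its significant annotations,
#' computes Jaccard distance between those vectors, and hierarchically
#' clusters (shared engine with the gene-set clustering) cut at `k`.
#' Diseases with no significant annotation at this level form one extra
#' "unenriched" cluster rather than being dropped, so C(n, 2) — and with it
#' cross-level Rand comparisons — stays fixed.
#'
#' @param enrichment an [EnrichmentTable-class].
#' @param k target number of clusters among the enriched diseases (capped at
#'   their count).
#' @param qThreshold significance threshold; defaults to the recorded one.
#' @param linkage linkage for [hierarchicalCluster()].
#' @param emptyLevel what to do when no disease has any significant
#'   annotation: "error" (default) or "unenriched" (return the trivial
#'   all-in-one-unenriched-cluster partition, as used by
#'   [attributeLevels()] so a signal-free level scores as uninformative
#'   rather than aborting the comparison).
#' @return A [Partition-class] over all tested diseases.
#' @export
levelPartition <- function(enrichment, k, qThreshold = NULL,
                           linkage = c("average", "complete", "ward"),
                           emptyLevel = c("error", "unenriched")) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  linkage <- match.arg(linkage)
  emptyLevel <- match.arg(emptyLevel)
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  .assertCount(k, "k")
  m <- significanceMatrix(enrichment, thr) > 0
  enriched <- rownames(m)[rowSums(m) > 0]
  if (length(enriched) == 0) {
    if (emptyLevel == "error") {
      stop("no disease has a significant annotation at this level",
           call. = FALSE)
    }
    return(Partition(rep(1L, length(enrichment@diseaseIds)),
                     items = enrichment@diseaseIds))
  }
  kEff <- min(k, length(enriched))
  labels <- integer(0)
  if (length(enriched) == 1L) {
    labels <- stats::setNames(1L, enriched)
  } else {
    sets <- apply(m[enriched, , drop = FALSE], 1, function(r) {
      colnames(m)[r]
    }, simplify = FALSE)
    gsc <- GeneSetCollection(sets, universe = colnames(m))
    sim <- jaccardMatrix(gsc)
    if (kEff == 1L) {
      labels <- stats::setNames(rep(1L, length(enriched)), enriched)
    } else {
      part <- cutTree(hierarchicalCluster(sim, linkage = linkage), kEff)
      labels <- clusterAssignments(part)[enriched]
    }
  }
  unenriched <- setdiff(enrichment@diseaseIds, enriched)
  if (length(unenriched) > 0) {
    labels <- c(labels, stats::setNames(rep(max(labels) + 1L,
                                            length(unenriched)), unenriched))
  }
  Partition(labels[enrichment@diseaseIds],
            items = enrichment@diseaseIds)
}

#' Rank biological levels by concordance with a reference partition
#'
#' For each level's enrichment table, derives a disease partition with
#' [levelPartition()] (at the reference's granularity by default), tests its
#' concordance with the reference via [permutationTest()], and additionally
#' reports all pairwise level-vs-level Rand indices. The level whose
#' enrichment profile best reproduces the reference grouping ranks first.
#'
#' @param reference a [Partition-class] (e.g. the gene-set subgroup
#'   partition).
#' @param levels named list of [EnrichmentTable-class] objects, one per
#'   biological level; all must cover the reference disease set.
#' @param k clusters for each level partition; default: the number of
#'   clusters in the reference, so Rand comparisons are made at matched
#'   granularity.
#' @param nPermutations,seed permutation-null settings (per-level substreams
#'   are derived from `seed`).
#' @param qThreshold threshold passed to [levelPartition()] (NULL: each
#'   table's recorded threshold).
#' @param linkage linkage for the level clusterings.
#' @return List with `results` (list of [ConcordanceResult-class], sorted by
#'   decreasing RI), `partitions` (the level partitions) and `pairwise`
#'   (level x level RI matrix).
#' @export
attributeLevels <- function(reference, levels, k = nClusters(reference),
                            nPermutations = 10000L, seed = 1L,
                            qThreshold = NULL,
                            linkage = c("average", "complete", "ward")) {
  stopifnot(is(reference, "Partition"), is.list(levels))
  linkage <- match.arg(linkage)
  if (is.null(names(levels)) || any(!nzchar(names(levels)))) {
    stop("'levels' must be a named list of EnrichmentTable objects",
         call. = FALSE)
  }
  partitions <- lapply(levels, levelPartition, k = k,
                       qThreshold = qThreshold, linkage = linkage,
                       emptyLevel = "unenriched")
  results <- lapply(seq_along(levels), function(i) {
    permutationTest(reference, partitions[[i]],
                    nPermutations = nPermutations,
                    seed = .substream(seed, i), level = names(levels)[i])
  })
  names(results) <- names(levels)
  ord <- order(-vapply(results, function(r) r@randIndex, numeric(1)))
  nm <- names(levels)
  pairwise <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) > 1) {
    for (i in seq_along(nm)) {
      for (j in seq_along(nm)) {
        if (i < j) {
          pairwise[i, j] <- pairwise[j, i] <-
            randIndex(partitions[[i]], partitions[[j]])
        }
      }
    }
  }
  list(results = results[ord], partitions = partitions, pairwise = pairwise)
}
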