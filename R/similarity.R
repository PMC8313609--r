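# Disease-disease similarity and its two clustering views: PCA + k-means on
# the similarity rows for the global picture, hierarchical clustering of
# 1 - Jaccard with dendrogram cuts below.

#' @rdname jaccardMatrix
#' @export
setMethod("jaccardMatrix", "GeneSetCollection", function(x) {
  sets <- geneSets(x)
  if (length(sets) < 2) {
    stop("need at least 2 gene sets to build a similarity matrix",
         call. = FALSE)
  }
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop(sprintf("empty gene set(s): %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  }
  uni <- universe(x)
  inc <- matrix(0, length(sets), length(uni),
                dimnames = list(names(sets), NULL))
  for (i in seq_along(sets)) {
    inc[i, match(sets[[i]], uni)] <- 1
  }
  inter <- tcrossprod(inc)          # integer-valued pairwise intersections
  sz <- lengths(sets)
  un <- outer(sz, sz, `+`) - inter
  j <- inter / un
  diag(j) <- 1
  dimnames(j) <- list(names(sets), names(sets))
  new("SimilarityMatrix", values = j)
})

#' Global clustering by PCA and k-means
#'
#' Treats each row of the similarity matrix as the disease's feature vector,
#' column-centres, projects onto the top `nComponents` principal axes and
#' runs k-means (with `nstart` restarts under a fixed seed) on the scores.
#' This is a reproducible surrogate for grouping diseases in the PC1/PC2
#' plane by eye.
#'
#' @param similarity a [SimilarityMatrix-class].
#' @param k number of clusters, `1 <= k <= n` diseases.
#' @param nComponents number of principal axes to keep (>= 2, capped at n).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return List with `partition` (a [Partition-class]) and `scores`
#'   (diseases x components matrix of PC scores, for plotting).
#' @examples
#' gda <- generateGDA(syntheticSpec(coreFraction = 1, seed = 7))
#' sim <- jaccardMatrix(buildGeneSets(gda$table, 1, 1e6))
#' pcaCluster(sim, k = 4, seed = 1)$partition
#' @export
pcaCluster <- function(similarity, k, nComponents = 2L, seed = 1L,
                       nstart = 50L) {
  stopifnot(is(similarity, "SimilarityMatrix"))
  v <- simValues(similarity)
  n <- nrow(v)
  if (k < 1 || k > n) {
    stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
  }
  if (nComponents < 2) stop("nComponents must be >= 2", call. = FALSE)
  nComponents <- min(as.integer(nComponents), n)
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(nComponents, ncol(pc$x))), drop = FALSE]
  cl <- if (k == 1L) {
    rep(1L, n)
  } else {
    .withSeed(seed, stats::kmeans(scores, centers = k, nstart = nstart)$cluster)
  }
  list(partition = Partition(cl, items = rownames(v)), scores = scores)
}

#' Hierarchical clustering of diseases on 1 - Jaccard distance
#'
#' @param similarity a [SimilarityMatrix-class].
#' @param linkage one of "average" (default), "complete", "ward" (Ward on
#'   the distance matrix, `hclust` method "ward.D2").
#' @return An `hclust` tree over the disease ids (merge heights are
#'   non-decreasing along any root path for these linkages).
#' @examples
#' gda <- generateGDA(syntheticSpec(coreFraction = 1, seed = 7))
#' hc <- hierarchicalCluster(jaccardMatrix(buildGeneSets(gda$table, 1, 1e6)))
#' cutTree(hc, k = 4)
#' @export
hierarchicalCluster <- function(similarity,
                                linkage = c("average", "complete", "ward")) {
  stopifnot(is(similarity, "SimilarityMatrix"))
  linkage <- match.arg(linkage)
  d <- stats::as.dist(1 - simValues(similarity))
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[linkage]
  stats::hclust(d, method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Cutting at `k + 1` always refines the cut at `k` (nested consistency of
#' `hclust` trees).
#'
#' @param dendrogram an `hclust` tree from [hierarchicalCluster()].
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return A [Partition-class] over the leaf ids.
#' @export
cutTree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
  cl <- stats::cutree(dendrogram, k = k)
  Partition(cl, items = names(cl))
}

#' Write a dendrogram as Newick
#'
#' @param dendrogram an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}
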