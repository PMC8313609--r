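# Hypergeometric overrepresentation of disease gene-sets against annotation
# collections, with BH FDR control per disease (default) or globally.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` are annotated. Exact
#' (equivalent to a one-sided Fisher test); vectorised over its arguments.
#'
#' @param k observed overlap, `0 <= k <= min(n, K)`.
#' @param n query size.
#' @param K annotation size.
#' @param N background size.
#' @return p-value(s) in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeomTail(2, 2, 2, 4)  # 1/6
#' @export
hypergeomTail <- function(k, n, K, N) {
  bad <- K > N | n > N | k > pmin(n, K) | k < 0 | n < 0 | K < 0 | N < 0
  if (any(is.na(bad)) || any(bad)) {
    stop("inconsistent counts: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return q-values in (0, 1], in the input order; empty input gives an
#'   empty result.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pValues) {
  if (length(pValues) == 0) return(numeric(0))
  if (any(is.na(pValues)) || any(pValues <= 0 | pValues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pValues, method = "BH")
}

#' Overrepresentation of query sets against an annotation collection
#'
#' Tests every (query set, annotation set) pair with the upper-tail
#' hypergeometric test over a fixed background. Genes outside the background
#' are dropped (with a `message()` count). BH correction is applied within
#' each query's family of annotation tests (`family = "per-disease"`, the
#' default: each disease's profile is interpreted on its own) or across all
#' pairs (`"global"`); pairs with zero overlap participate in the correction
#' with p = 1 but are not emitted.
#'
#' @param query a [GeneSetCollection-class] of disease gene-sets.
#' @param annotations a [GeneSetCollection-class] of annotation sets
#'   (pathways, markers, drug signatures, ...).
#' @param background character vector of background genes; defaults to the
#'   query universe.
#' @param qThreshold significance level recorded in the result (default
#'   0.05).
#' @param family FDR correction family.
#' @return An [EnrichmentTable-class].
#' @examples
#' q <- GeneSetCollection(list(d1 = c("g1", "g2", "g3")),
#'                        universe = sprintf("g%d", 1:20))
#' a <- GeneSetCollection(list(path1 = c("g1", "g2", "g9")))
#' enrichmentResults(enrich(q, a))
#' @export
enrich <- function(query, annotations, background = NULL, qThreshold = 0.05,
                   family = c("per-disease", "global")) {
  stopifnot(is(query, "GeneSetCollection"), is(annotations, "GeneSetCollection"))
  family <- match.arg(family)
  if (qThreshold <= 0 || qThreshold > 1) {
    stop("qThreshold must lie in (0, 1]", call. = FALSE)
  }
  bg <- unique(if (is.null(background)) universe(query) else as.character(background))
  if (length(bg) == 0) stop("empty background", call. = FALSE)

  qsets <- geneSets(query)
  asets <- geneSets(annotations)
  qTrim <- lapply(qsets, function(s) s[s %in% bg])
  aTrim <- lapply(asets, function(s) s[s %in% bg])
  droppedQ <- sum(lengths(qsets)) - sum(lengths(qTrim))
  droppedA <- sum(lengths(asets)) - sum(lengths(aTrim))
  if (droppedQ + droppedA > 0) {
    message(sprintf(
      "dropped genes outside background: %d from queries, %d from annotations",
      droppedQ, droppedA))
  }

  D <- length(qTrim); A <- length(aTrim); N <- length(bg)
  qInc <- matrix(0, D, N)
  for (i in seq_len(D)) qInc[i, match(qTrim[[i]], bg)] <- 1
  aInc <- matrix(0, A, N)
  for (i in seq_len(A)) aInc[i, match(aTrim[[i]], bg)] <- 1
  kMat <- tcrossprod(qInc, aInc)
  nVec <- lengths(qTrim)
  KVec <- lengths(aTrim)
  KM <- matrix(KVec, D, A, byrow = TRUE)
  nM <- matrix(nVec, D, A)
  pMat <- stats::phyper(kMat - 1, KM, N - KM, nM, lower.tail = FALSE)
  qMat <- switch(family,
    "per-disease" = t(apply(pMat, 1, stats::p.adjust, method = "BH")),
    "global" = stats::p.adjust(pMat, method = "BH"))
  qMat <- matrix(qMat, D, A)  # restore dims dropped by apply() edge cases

  hit <- which(t(kMat) >= 1, arr.ind = TRUE)  # transpose: order by disease
  di <- hit[, 2L]; ai <- hit[, 1L]
  genes <- vapply(seq_along(di), function(r) {
    paste(sort(intersect(qTrim[[di[r]]], aTrim[[ai[r]]])), collapse = ",")
  }, character(1))
  results <- data.frame(
    diseaseId = names(qTrim)[di], annotation = names(aTrim)[ai],
    k = as.integer(kMat[cbind(di, ai)]), n = as.integer(nVec[di]),
    K = as.integer(KVec[ai]), N = rep(as.integer(N), length(di)),
    pValue = pMat[cbind(di, ai)], qValue = qMat[cbind(di, ai)],
    genes = genes, stringsAsFactors = FALSE)
  new("EnrichmentTable", results = results, diseaseIds = names(qTrim),
      annotationNames = names(aTrim), backgroundSize = as.integer(N),
      qThreshold = as.numeric(qThreshold), family = family)
}

#' Chromosome overrepresentation
#'
#' Treats each chromosome's gene complement as an annotation set and reuses
#' the hypergeometric machinery. The background is restricted to mapped
#' genes: genes without a chromosome assignment are uninformative for
#' chromosomal bias and are dropped (with a `message()` count).
#'
#' @param query a [GeneSetCollection-class] of disease gene-sets.
#' @param chromosomeMap named character vector gene -> chromosome.
#' @param qThreshold,family as in [enrich()].
#' @return An [EnrichmentTable-class] with chromosomes as annotations.
#' @export
chromosomeEnrich <- function(query, chromosomeMap, qThreshold = 0.05,
                             family = c("per-disease", "global")) {
  if (is.null(names(chromosomeMap)) || length(chromosomeMap) == 0) {
    stop("'chromosomeMap' must be a non-empty named vector", call. = FALSE)
  }
  mapped <- names(chromosomeMap)
  unmapped <- length(setdiff(universe(query), mapped))
  if (unmapped > 0) {
    message(sprintf("%d background gene(s) lack a chromosome assignment; dropped",
                    unmapped))
  }
  chromSets <- split(names(chromosomeMap), as.character(chromosomeMap))
  chrom <- GeneSetCollection(chromSets, universe = mapped)
  enrich(query, chrom, background = intersect(universe(query), mapped),
         qThreshold = qThreshold, family = match.arg(family))
}

#' Summarise drug enrichment by mode of action
#'
#' Counts, over a disease set, the distinct significantly enriched drugs per
#' mode of action (the "15/64"-style numerators of an MOA frequency table)
#' and each drug's density: the fraction of diseases in the set whose
#' gene-set is significantly enriched for that drug's signature.
#'
#' @param enrichment an [EnrichmentTable-class] of disease vs drug-signature
#'   tests.
#' @param moaMap named character vector drug -> MOA; every significant drug
#'   must be present.
#' @param diseaseSet disease ids to summarise over (default: all tested).
#' @param qThreshold significance threshold; defaults to the recorded one.
#' @return List with `moaFrequency` (data.frame moa, nDrugs, sorted
#'   decreasing) and `drugDensity` (data.frame drug, moa, density).
#' @export
drugMoaSummary <- function(enrichment, moaMap, diseaseSet = NULL,
                           qThreshold = NULL) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  if (is.null(diseaseSet)) diseaseSet <- enrichment@diseaseIds
  sig <- significantHits(enrichment, thr)
  sig <- sig[sig$diseaseId %in% diseaseSet, , drop = FALSE]
  sigDrugs <- unique(sig$annotation)
  missing <- setdiff(sigDrugs, names(moaMap))
  if (length(missing) > 0) {
    stop(sprintf("drug(s) missing from the MOA map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  moaFrequency <- if (length(sigDrugs) > 0) {
    tab <- table(unname(moaMap[sigDrugs]))
    df <- data.frame(moa = names(tab), nDrugs = as.integer(tab),
                     stringsAsFactors = FALSE)
    df[order(-df$nDrugs, df$moa), , drop = FALSE]
  } else {
    data.frame(moa = character(0), nDrugs = integer(0))
  }
  drugs <- enrichment@annotationNames
  density <- vapply(drugs, function(d) {
    sum(sig$annotation == d) / length(diseaseSet)
  }, numeric(1))
  drugDensity <- data.frame(
    drug = drugs,
    moa = unname(moaMap[drugs]),
    density = unname(density), stringsAsFactors = FALSE)
  drugDensity <- drugDensity[order(-drugDensity$density, drugDensity$drug), ,
                             drop = FALSE]
  rownames(drugDensity) <- NULL
  rownames(moaFrequency) <- NULL
  list(moaFrequency = moaFrequency, drugDensity = drugDensity)
}
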