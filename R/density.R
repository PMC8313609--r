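# Density-index summaries: the fill fraction of significant cells in the
# disease x theme-annotation significance matrix. Absent enrichment rows
# (zero overlap) count as non-significant.

.densityRows <- function(enrichment, themeMap, diseaseSet, qThreshold,
                         setName, method, cap) {
  sig <- significantHits(enrichment, qThreshold)
  sig <- sig[sig$diseaseId %in% diseaseSet, , drop = FALSE]
  themes <- unique(unname(themeMap))
  rows <- lapply(themes, function(th) {
    anns <- names(themeMap)[themeMap == th]
    nCells <- length(diseaseSet) * length(anns)
    dens <- if (method == "binary") {
      sum(sig$annotation %in% anns) / nCells
    } else {
      # weighted variant: mean of min(1, -log10(q)/cap) over all cells
      s <- sig[sig$annotation %in% anns, , drop = FALSE]
      sum(pmin(1, -log10(s$qValue) / cap)) / nCells
    }
    data.frame(theme = th, diseaseSet = setName, density = dens,
               nDiseases = length(diseaseSet), nAnnotations = length(anns),
               nSignificant = sum(sig$annotation %in% anns),
               flagged = NA, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Density index per theme over a disease set
#'
#' For each theme, density = (significant (disease, annotation) pairs with
#' the disease in `diseaseSet` and the annotation in the theme) /
#' (n_diseases x n_theme_annotations). A density near 1 marks a theme shared
#' across the diseases; near 0, a theme confined to a few.
#'
#' @param enrichment an [EnrichmentTable-class].
#' @param themeMap named character vector annotation -> theme
#'   (many-to-one); must cover every annotation in the enrichment table.
#' @param diseaseSet disease ids to profile (default: all tested).
#' @param qThreshold significance threshold; defaults to the recorded one.
#' @param setName label for the disease set in the output.
#' @param method "binary" (default; the density index proper) or "weighted"
#'   (mean of `min(1, -log10(q)/cap)` over all cells).
#' @param cap saturation for the weighted variant.
#' @return A [DensityProfile-class].
#' @examples
#' # 2 pathways in one theme, 3 diseases, 3 significant pairs -> 0.5
#' @export
densityIndex <- function(enrichment, themeMap, diseaseSet = NULL,
                         qThreshold = NULL, setName = "all",
                         method = c("binary", "weighted"), cap = 10) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  method <- match.arg(method)
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  if (is.null(diseaseSet)) diseaseSet <- enrichment@diseaseIds
  if (length(diseaseSet) == 0) stop("empty disease set", call. = FALSE)
  if (is.null(names(themeMap)) || length(themeMap) == 0) {
    stop("'themeMap' must be a non-empty named vector", call. = FALSE)
  }
  uncovered <- setdiff(enrichment@annotationNames, names(themeMap))
  if (length(uncovered) > 0) {
    stop(sprintf("annotation(s) missing from the theme map: %s",
                 paste(uncovered, collapse = ", ")), call. = FALSE)
  }
  profile <- .densityRows(enrichment, themeMap, diseaseSet, thr, setName,
                          method, cap)
  new("DensityProfile", profile = profile, qThreshold = as.numeric(thr),
      flagThreshold = NA_real_)
}

#' Density of a single annotation across a disease set
#'
#' The theme formula with a singleton theme: the fraction of diseases in the
#' set significantly enriched for the annotation (zero when none is — a
#' "hollow dot" in the dot-plot reports).
#'
#' @inheritParams densityIndex
#' @param annotation one annotation name that was tested.
#' @return Numeric density in [0, 1].
#' @export
singleAnnotationDensity <- function(enrichment, annotation, diseaseSet = NULL,
                                    qThreshold = NULL) {
  stopifnot(is(enrichment, "EnrichmentTable"))
  if (!annotation %in% enrichment@annotationNames) {
    stop(sprintf("unknown annotation '%s'", annotation), call. = FALSE)
  }
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  if (is.null(diseaseSet)) diseaseSet <- enrichment@diseaseIds
  if (length(diseaseSet) == 0) stop("empty disease set", call. = FALSE)
  map <- stats::setNames(annotation, annotation)
  prof <- .densityRows(enrichment, map, diseaseSet, thr, "all", "binary", 10)
  prof$density
}

#' Flag high-density rows
#'
#' Marks rows with density >= `threshold` and records the threshold in the
#' profile metadata. Conventional presentation thresholds are 0.5 for
#' pathway themes, 0.4 for cell-types and 0.1 for chromosomes; all are
#' arbitrary display choices, not test levels.
#'
#' @param profile a [DensityProfile-class].
#' @param threshold density threshold in [0, 1].
#' @return The flagged [DensityProfile-class].
#' @export
flagByThreshold <- function(profile, threshold) {
  stopifnot(is(profile, "DensityProfile"))
  .assertFraction(threshold, "threshold")
  profile@profile$flagged <- profile@profile$density >= threshold
  profile@flagThreshold <- as.numeric(threshold)
  validObject(profile)
  profile
}

#' Theme-density profiles per subgroup
#'
#' Computes one density profile per cluster of `partition` plus an "all"
#' profile over every disease, and the between-subgroup Pearson correlation
#' matrix of theme densities (how similar two subgroups' theme involvement
#' is).
#'
#' @inheritParams densityIndex
#' @param partition a [Partition-class] covering every tested disease.
#' @return List with `profile` (one combined [DensityProfile-class]; the
#'   disease-set column holds "all" and "subgroup<k>") and `correlation`
#'   (subgroup x subgroup matrix).
#' @export
subgroupProfiles <- function(enrichment, themeMap, partition,
                             qThreshold = NULL,
                             method = c("binary", "weighted"), cap = 10) {
  stopifnot(is(enrichment, "EnrichmentTable"), is(partition, "Partition"))
  method <- match.arg(method)
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  assign <- clusterAssignments(partition)
  missing <- setdiff(enrichment@diseaseIds, names(assign))
  if (length(missing) > 0) {
    stop(sprintf("disease(s) absent from the partition: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  all <- densityIndex(enrichment, themeMap, qThreshold = thr,
                      setName = "all", method = method, cap = cap)
  pieces <- list(densityTable(all))
  densByGroup <- list()
  for (k in seq_len(nClusters(partition))) {
    ids <- intersect(names(assign)[assign == k], enrichment@diseaseIds)
    if (length(ids) == 0) next
    nm <- sprintf("subgroup%d", k)
    prof <- densityIndex(enrichment, themeMap, diseaseSet = ids,
                         qThreshold = thr, setName = nm, method = method,
                         cap = cap)
    pieces[[length(pieces) + 1L]] <- densityTable(prof)
    densByGroup[[nm]] <- stats::setNames(densityTable(prof)$density,
                                         densityTable(prof)$theme)
  }
  combined <- new("DensityProfile", profile = do.call(rbind, pieces),
                  qThreshold = as.numeric(thr), flagThreshold = NA_real_)
  correlation <- if (length(densByGroup) >= 2) {
    m <- do.call(cbind, densByGroup)
    suppressWarnings(stats::cor(m))
  } else {
    matrix(1, 1, 1, dimnames = list(names(densByGroup), names(densByGroup)))
  }
  list(profile = combined, correlation = correlation)
}
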