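# Readers and writers for the pipeline's plain-text formats: DisGeNET-style
# GDA TSV, GMT annotation collections, two-column maps.

#' Load a gene-disease association table
#'
#' Reads a DisGeNET-style TSV. Column names are configurable through
#' `dialect`; a missing disease-name column falls back to the disease id.
#' Duplicate (disease, gene) pairs are collapsed (first name kept) and the
#' collapse count is reported via `message()`.
#'
#' @param path TSV file with a header.
#' @param dialect named list mapping the logical columns `diseaseId`,
#'   `diseaseName`, `geneSymbol` to the file's column names.
#' @return data.frame with columns diseaseId, diseaseName, geneSymbol.
#' @export
loadGDA <- function(path,
                    dialect = list(diseaseId = "diseaseId",
                                   diseaseName = "diseaseName",
                                   geneSymbol = "geneSymbol")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    stop(sprintf("empty GDA file: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("diseaseId", "geneSymbol")) {
    if (!dialect[[col]] %in% names(df)) {
      stop(sprintf("GDA file lacks required column '%s'", dialect[[col]]),
           call. = FALSE)
    }
  }
  hasName <- !is.null(dialect$diseaseName) && dialect$diseaseName %in% names(df)
  out <- data.frame(
    diseaseId = as.character(df[[dialect$diseaseId]]),
    diseaseName = if (hasName) as.character(df[[dialect$diseaseName]])
                  else as.character(df[[dialect$diseaseId]]),
    geneSymbol = as.character(df[[dialect$geneSymbol]]),
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$diseaseId)) || any(!nzchar(out$geneSymbol))) {
    stop("diseaseId and geneSymbol must be non-empty strings", call. = FALSE)
  }
  dup <- duplicated(out[c("diseaseId", "geneSymbol")])
  message(sprintf("loaded %d GDA row(s); collapsed %d duplicate pair(s)",
                  nrow(out), sum(dup)))
  out[!dup, , drop = FALSE]
}

#' Write a gene-disease association table as TSV
#'
#' @param table data.frame with columns diseaseId, diseaseName, geneSymbol.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGDA <- function(table, path) {
  utils::write.table(table[c("diseaseId", "diseaseName", "geneSymbol")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build size-filtered disease gene-sets from a GDA table
#'
#' One set per disease id, keeping diseases whose set size lies in
#' `[minSize, maxSize]`. The background universe is the union of all genes in
#' the unfiltered table: filtering diseases never shrinks the hypergeometric
#' background. Dropped-disease counts are reported via `message()`.
#'
#' @param table GDA data.frame as returned by [loadGDA()].
#' @param minSize,maxSize inclusive size bounds (defaults 10 and 1000, the
#'   conventional overrepresentation-analysis bounds).
#' @return A [GeneSetCollection-class] keyed by disease id.
#' @examples
#' gda <- generateGDA(syntheticSpec(seed = 7))
#' gsc <- buildGeneSets(gda$table, minSize = 10, maxSize = 1000)
#' nSets(gsc)
#' @export
buildGeneSets <- function(table, minSize = 10L, maxSize = 1000L) {
  if (minSize < 1 || minSize > maxSize) {
    stop("must have 1 <= minSize <= maxSize", call. = FALSE)
  }
  sets <- lapply(split(table$geneSymbol, table$diseaseId), unique)
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= minSize & sizes <= maxSize
  message(sprintf(
    "size filter [%d, %d]: kept %d of %d disease(s) (%d below, %d above)",
    as.integer(minSize), as.integer(maxSize), sum(keep), length(sets),
    sum(sizes < minSize), sum(sizes > maxSize)))
  if (!any(keep)) {
    stop("no diseases survive the gene-set size filter", call. = FALSE)
  }
  GeneSetCollection(sets[keep], universe = unique(table$geneSymbol))
}

#' Load a GMT annotation collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Blank lines are skipped; lines with fewer than three fields or
#' duplicated set names raise an error with the line number.
#'
#' @param path GMT file.
#' @param universe optional explicit background; defaults to the union of
#'   the members.
#' @return A [GeneSetCollection-class].
#' @export
loadGMT <- function(path, universe = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i),
           call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop(sprintf("duplicated set name '%s' at GMT line %d", nm, i),
           call. = FALSE)
    }
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  GeneSetCollection(sets, universe = universe)
}

#' Write a collection as GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output file.
#' @param descriptions optional named character of per-set descriptions
#'   (defaults to "na").
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  nms <- names(geneSets(collection))
  desc <- if (is.null(descriptions)) rep("na", length(nms)) else descriptions[nms]
  lines <- vapply(seq_along(nms), function(i) {
    paste(c(nms[i], desc[i], geneSets(collection)[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a two-column key-value map
#'
#' Reads a two-column CSV (".csv") or TSV (anything else) with a header.
#' Rows with a duplicated key and conflicting values raise an error naming
#' the key; consistent duplicates are collapsed.
#'
#' @param path map file.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return Named character vector (key -> value).
#' @export
loadTwoColumnMap <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  if (ncol(df) != 2) {
    stop(sprintf("map file must have exactly 2 columns, found %d", ncol(df)),
         call. = FALSE)
  }
  key <- as.character(df[[1]])
  val <- as.character(df[[2]])
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(val[key == k])) > 1) {
      stop(sprintf("conflicting values for duplicated key '%s'", k),
           call. = FALSE)
    }
  }
  keep <- !duplicated(key)
  stats::setNames(val[keep], key[keep])
}

#' Write a two-column key-value map
#'
#' @param map named character vector.
#' @param path output file (".csv" writes CSV, otherwise TSV).
#' @param columns header names for the key and value columns.
#' @return `path`, invisibly.
#' @export
writeTwoColumnMap <- function(map, path, columns = c("key", "value")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(names(map), unname(map), stringsAsFactors = FALSE)
  names(df) <- columns
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-express a collection as a long-format GDA table
#'
#' Inverse of [buildGeneSets()] up to disease names (set names are used for
#' both id and name). Useful for filter-idempotence checks and round trips.
#'
#' @param collection a [GeneSetCollection-class].
#' @return data.frame with columns diseaseId, diseaseName, geneSymbol.
#' @export
collectionToTable <- function(collection) {
  sets <- geneSets(collection)
  data.frame(
    diseaseId = rep(names(sets), lengths(sets)),
    diseaseName = rep(names(sets), lengths(sets)),
    geneSymbol = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Write / read a partition as a two-column TSV
#'
#' @param partition a [Partition-class].
#' @param path file path.
#' @return `path` (write) or a [Partition-class] (read).
#' @export
writePartition <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
loadPartition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  Partition(df$cluster, items = df$item)
}

#' Write / read a similarity matrix as TSV with id header row and column
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path file path.
#' @return `path` (write) or a [SimilarityMatrix-class] (read).
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- simValues(sim)
  df <- data.frame(diseaseId = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @export
loadSimilarityMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- (m + t(m)) / 2  # undo asymmetric round-off from text serialisation
  diag(m) <- 1
  new("SimilarityMatrix", values = m)
}

#' Write an enrichment table as TSV
#'
#' @param enrichment an [EnrichmentTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(enrichment, path) {
  utils::write.table(enrichmentResults(enrichment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the significant-only -log10(q) matrix
#'
#' Diseases x annotations matrix holding -log10(q) for significant pairs and
#' zero elsewhere, the numeric analogue of an enrichment heatmap.
#'
#' @param enrichment an [EnrichmentTable-class].
#' @param qThreshold significance threshold; defaults to the recorded one.
#' @return Numeric matrix (all tested diseases x all tested annotations).
#' @export
significanceMatrix <- function(enrichment, qThreshold = NULL) {
  thr <- if (is.null(qThreshold)) enrichment@qThreshold else qThreshold
  m <- matrix(0, length(enrichment@diseaseIds),
              length(enrichment@annotationNames),
              dimnames = list(enrichment@diseaseIds,
                              enrichment@annotationNames))
  sig <- significantHits(enrichment, thr)
  if (nrow(sig) > 0) {
    m[cbind(sig$diseaseId, sig$annotation)] <- -log10(sig$qValue)
  }
  m
}
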