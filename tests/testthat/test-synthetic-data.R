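# Synthetic GDA generator: planted structure, determinism, validation.

test_that("generated tables are deterministic and respect the planted sizes", {
  spec <- plantedSpec(seed = 7, coreFraction = 0.5)
  a <- generateGDA(spec)
  b <- generateGDA(spec)
  expect_identical(a$table, b$table)
  expect_identical(clusterAssignments(a$truth), clusterAssignments(b$truth))
  expect_identical(clusterSizes(a$truth), c(8L, 11L, 11L, 6L))

  sizes <- vapply(split(a$table$geneSymbol, a$table$diseaseId),
                  function(g) length(unique(g)), integer(1))
  expect_true(all(sizes == 100L))
  expect_equal(sum(sizes), nrow(a$table))  # all rows distinct per disease
})

test_that("adding diseases does not perturb earlier diseases' gene sets", {
  small <- syntheticSpec(nDiseases = 10L, nClusters = 2L,
                         clusterSizes = c(5L, 5L), seed = 11)
  big <- syntheticSpec(nDiseases = 12L, nClusters = 2L,
                       clusterSizes = c(5L, 7L), seed = 11)
  gSmall <- split(generateGDA(small)$table$geneSymbol,
                  generateGDA(small)$table$diseaseId)
  gBig <- split(generateGDA(big)$table$geneSymbol,
                generateGDA(big)$table$diseaseId)
  for (id in names(gSmall)[1:5]) {  # cluster 1 is untouched by the extension
    expect_identical(gSmall[[id]], gBig[[id]])
  }
})

test_that("disjoint pools force zero between-cluster overlap, positive within", {
  gda <- generateGDA(plantedSpec(seed = 3))
  sets <- split(gda$table$geneSymbol, gda$table$diseaseId)
  truth <- clusterAssignments(gda$truth)
  ids <- names(truth)
  between <- c(); within <- c()
  for (i in 1:10) {       # spot-check pairs across the grid
    for (j in (i + 1):15) {
      jac <- oracleJaccard(sets[[ids[i]]], sets[[ids[j]]])
      if (truth[ids[i]] == truth[ids[j]]) within <- c(within, jac)
      else between <- c(between, jac)
    }
  }
  expect_true(all(between == 0))
  expect_true(all(within > 0))
})

test_that("a single shared pool gives every pair positive expected overlap", {
  spec <- syntheticSpec(nDiseases = 8L, nClusters = 1L, clusterSizes = 8L,
                        corePoolSize = 150L, genesPerDisease = 100L,
                        coreFraction = 1, seed = 5)
  gda <- generateGDA(spec)
  sets <- split(gda$table$geneSymbol, gda$table$diseaseId)
  jac <- utils::combn(names(sets), 2, function(p) {
    oracleJaccard(sets[[p[1]]], sets[[p[2]]])
  })
  # 100 of 150 genes each: any two sets intersect by pigeonhole
  expect_true(all(jac > 0))
  expect_gt(mean(jac), 0.3)
})

test_that("inconsistent specs fail validation naming the offending field", {
  expect_error(syntheticSpec(coreFraction = 0.8, sharedFraction = 0.5),
               "coreFraction \\+ sharedFraction")
  expect_error(syntheticSpec(geneUniverseSize = 100L), "geneUniverseSize")
  expect_error(syntheticSpec(clusterSizes = c(8L, 11L, 11L, 7L)),
               "clusterSizes")
  expect_error(syntheticSpec(coreFraction = 1, corePoolSize = 50L,
                             genesPerDisease = 100L), "coreFraction")
})

test_that("annotation themes come from their pools; empty themes are absent", {
  spec <- plantedSpec(seed = 9, coreFraction = 0.5, sharedFraction = 0.4)
  themes <- benchmarkThemes()
  themes$nSets[themes$theme == "private4"] <- 0
  ann <- generateAnnotations(spec, themes)
  expect_false("private4" %in% ann$themeMap)
  expect_setequal(unique(unname(ann$themeMap)),
                  c("ubiquitous", sprintf("private%d", 1:3)))
  # every ubiquitous pathway is a subset of the shared pool (first block)
  shared <- sprintf("G%05d", 1:150)
  for (nm in names(ann$themeMap)[ann$themeMap == "ubiquitous"]) {
    expect_true(all(geneSets(ann$collection)[[nm]] %in% shared))
  }
  expect_identical(generateAnnotations(spec, themes)$collection@sets,
                   ann$collection@sets)
  expect_error(generateAnnotations(spec, data.frame(
    theme = "x", pool = "cluster9", nSets = 1, setSize = 5)),
    "undefined pool")
})

test_that("chromosome maps cover the universe; bias lands where planted", {
  spec <- plantedSpec(seed = 2, biasedCluster = 1L, biasedChromosome = 5L,
                      biasWeight = 25)
  map <- generateChromosomeMap(spec)
  expect_length(map, 1500L)
  expect_true(all(!is.na(map)))
  expect_identical(map, generateChromosomeMap(spec))
  pool1 <- sprintf("G%05d", 151:350)  # cluster 1 pool block
  expect_gt(mean(map[pool1] == "chr5"), 0.4)       # ~25/46 expected
  unbiased <- generateChromosomeMap(plantedSpec(seed = 2))
  expect_lt(mean(unbiased[pool1] == "chr5"), 0.15)  # ~1/22 expected
})

test_that("drug signatures map one-to-one onto MOAs and are reproducible", {
  spec <- plantedSpec(seed = 4, coreFraction = 0.5, sharedFraction = 0.5)
  expect_error(generateDrugSignatures(spec, nDrugs = 2, moaCount = 3),
               "nDrugs")
  one <- generateDrugSignatures(spec, nDrugs = 1, moaCount = 1)
  expect_identical(one$moaMap, c(drug001 = "MOA01"))
  drugs <- generateDrugSignatures(spec, nDrugs = 7, moaCount = 3)
  expect_length(drugs$moaMap, 7L)
  expect_true(all(drugs$moaMap %in% sprintf("MOA%02d", 1:3)))
  expect_identical(generateDrugSignatures(spec, 7, 3)$collection@sets,
                   drugs$collection@sets)
  shared <- sprintf("G%05d", 1:150)
  for (s in geneSets(drugs$collection)) expect_true(all(s %in% shared))
  # GMT round trip is byte-identical under the same seed
  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  writeGMT(drugs$collection, f1)
  writeGMT(generateDrugSignatures(spec, 7, 3)$collection, f2)
  expect_identical(readLines(f1), readLines(f2))
})
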