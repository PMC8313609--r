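# Hypergeometric ORA, BH correction, drug/MOA summaries.

test_that("hypergeometric tail matches hand values and the enumeration oracle", {
  expect_identical(hypergeomTail(0, 5, 3, 20), 1)
  expect_equal(hypergeomTail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  set.seed(101)
  for (rep in 1:200) {
    N <- sample(2:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomTail(k, n, K, N), oracleHypergeomTail(k, n, K, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomTail(3, 2, 5, 10), "inconsistent")
  expect_error(hypergeomTail(1, 2, 5, 4), "inconsistent")
})

test_that("increasing overlap never increases the p-value", {
  for (k in 0:9) {
    expect_gte(hypergeomTail(k, 10, 12, 40), hypergeomTail(k + 1, 10, 12, 40))
  }
})

test_that("BH adjustment matches the literal step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("thresholding q at alpha equals the step-up rule on sorted p", {
  set.seed(8)
  alpha <- 0.05
  for (rep in 1:50) {
    p <- runif(30)^2
    q <- bhAdjust(p)
    ps <- sort(p)
    cutoff <- max(c(0, which(ps <= alpha * seq_along(ps) / length(ps))))
    stepUp <- p <= (if (cutoff == 0) -1 else ps[cutoff])
    expect_identical(q <= alpha, stepUp)
  }
})

test_that("saturated and disjoint queries behave degenerately", {
  genes <- sprintf("g%d", 1:10)
  q <- GeneSetCollection(list(d1 = genes), universe = genes)
  a <- GeneSetCollection(list(s1 = genes), universe = genes)
  et <- enrich(q, a, background = genes)
  expect_identical(enrichmentResults(et)$pValue, 1)  # n = K = N = k

  a2 <- GeneSetCollection(list(s1 = c("x1", "x2")),
                          universe = c(genes, "x1", "x2"))
  et2 <- enrich(q, a2, background = c(genes, "x1", "x2"))
  expect_identical(nrow(enrichmentResults(et2)), 0L)  # k = 0 rows not emitted
})

test_that("a planted ubiquitous pathway is significant for every disease", {
  spec <- plantedSpec(seed = 31, coreFraction = 0.4, sharedFraction = 0.5)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  ann <- generateAnnotations(spec, data.frame(
    theme = "ubiquitous", pool = "shared", nSets = 3, setSize = 60))
  et <- quietly(enrich(gsc, ann$collection))
  sig <- significantHits(et)
  for (nm in names(ann$themeMap)) {
    expect_setequal(sig$diseaseId[sig$annotation == nm], et@diseaseIds)
  }
})

test_that("enrichment is invariant to disease and annotation input order", {
  spec <- plantedSpec(seed = 37, coreFraction = 0.5, sharedFraction = 0.4)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  ann <- generateAnnotations(spec, benchmarkThemes())$collection
  et1 <- quietly(enrich(gsc, ann))
  permD <- sample(names(geneSets(gsc)))
  permA <- sample(names(geneSets(ann)))
  et2 <- quietly(enrich(gsc[permD], ann[permA]))
  r1 <- enrichmentResults(et1)
  r2 <- enrichmentResults(et2)
  key <- function(r) r[order(r$diseaseId, r$annotation), ]
  expect_equal(key(r1), key(r2), ignore_attr = TRUE)
})

test_that("genes outside the background are dropped with a count", {
  q <- GeneSetCollection(list(d1 = c("g1", "g2", "zz")),
                         universe = c("g1", "g2", "zz"))
  a <- GeneSetCollection(list(s1 = c("g1", "g3")))
  expect_message(enrich(q, a, background = sprintf("g%d", 1:5)),
                 "dropped genes outside background")
  expect_error(enrich(q, a, background = character(0)), "empty background")
})

test_that("one chromosome holding all genes gives p = 1 everywhere", {
  spec <- syntheticSpec(nDiseases = 6L, nClusters = 2L,
                        clusterSizes = c(3L, 3L), chromosomeCount = 1L,
                        coreFraction = 1, seed = 41)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  ce <- quietly(chromosomeEnrich(gsc, generateChromosomeMap(spec)))
  expect_true(all(enrichmentResults(ce)$pValue == 1))
})

test_that("a planted chromosome bias shows up for the right subgroup only", {
  spec <- plantedSpec(seed = 43, biasedCluster = 1L, biasedChromosome = 5L,
                      biasWeight = 25)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  ce <- quietly(chromosomeEnrich(gsc, generateChromosomeMap(spec)))
  truth <- clusterAssignments(gda$truth)
  sig <- significantHits(ce)
  c1 <- names(truth)[truth == 1]
  expect_setequal(sig$diseaseId[sig$annotation == "chr5"], c1)
})

test_that("drug/MOA summaries count distinct significant drugs per MOA", {
  results <- data.frame(
    diseaseId = c(sprintf("d%d", 1:10), "d1", "d2"),
    annotation = c(rep("drugA", 10), "drugB", "drugB"),
    k = 5L, n = 20L, K = 30L, N = 500L,
    pValue = 1e-6, qValue = 1e-5, genes = "g1",
    stringsAsFactors = FALSE)
  et <- new("EnrichmentTable", results = results,
            diseaseIds = sprintf("d%d", 1:10),
            annotationNames = c("drugA", "drugB", "drugC"),
            backgroundSize = 500L, qThreshold = 0.05,
            family = "per-disease")
  out <- drugMoaSummary(et, c(drugA = "MOA1", drugB = "MOA1", drugC = "MOA2"))
  expect_identical(out$moaFrequency,
                   data.frame(moa = "MOA1", nDrugs = 2L))
  dens <- setNames(out$drugDensity$density, out$drugDensity$drug)
  expect_identical(dens[["drugA"]], 1.0)
  expect_identical(dens[["drugB"]], 0.2)
  expect_identical(dens[["drugC"]], 0.0)
  expect_error(drugMoaSummary(et, c(drugA = "MOA1")), "drugB")
})

test_that("a planted shared-pool drug has the highest density", {
  spec <- plantedSpec(seed = 47, coreFraction = 0.4, sharedFraction = 0.5)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  shared <- generateDrugSignatures(spec, nDrugs = 2, moaCount = 2,
                                   pool = "shared", signatureSize = 60)
  noise <- generateDrugSignatures(spec, nDrugs = 3, moaCount = 3,
                                  pool = "universe", signatureSize = 60)
  sets <- c(geneSets(shared$collection),
            setNames(geneSets(noise$collection), paste0("rand_", 1:3)))
  drugs <- GeneSetCollection(sets, universe = universe(shared$collection))
  moaMap <- c(shared$moaMap, setNames(rep("MOAnoise", 3), paste0("rand_", 1:3)))
  et <- quietly(enrich(gsc, drugs))
  out <- drugMoaSummary(et, moaMap)
  top <- out$drugDensity$drug[1]
  expect_true(top %in% names(shared$moaMap))
  expect_gt(out$drugDensity$density[1],
            max(out$drugDensity$density[out$drugDensity$drug %in%
                                          paste0("rand_", 1:3)]))
})
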