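# Density-index summaries over themes and disease sets.

# Hand-built enrichment table: diseases d1..d3, annotations p1, p2 in theme
# "T", with 3 significant (disease, annotation) cells.
makeEnrichment <- function(sig, diseases, annotations, qThreshold = 0.05) {
  results <- data.frame(
    diseaseId = sig$diseaseId, annotation = sig$annotation,
    k = 5L, n = 20L, K = 30L, N = 500L, pValue = sig$q / 2, qValue = sig$q,
    genes = "g1", stringsAsFactors = FALSE)
  new("EnrichmentTable", results = results, diseaseIds = diseases,
      annotationNames = annotations, backgroundSize = 500L,
      qThreshold = qThreshold, family = "per-disease")
}

test_that("density is the fill fraction of significant cells", {
  et <- makeEnrichment(
    data.frame(diseaseId = c("d1", "d1", "d2"),
               annotation = c("p1", "p2", "p1"), q = 0.01),
    diseases = c("d1", "d2", "d3"), annotations = c("p1", "p2"))
  prof <- densityTable(densityIndex(et, c(p1 = "T", p2 = "T")))
  expect_identical(prof$density, 0.5)  # 3 / (3 x 2)
  expect_identical(prof$nSignificant, 3L)

  # all cells significant -> 1; none -> 0
  full <- makeEnrichment(
    expand.grid(diseaseId = c("d1", "d2", "d3"),
                annotation = c("p1", "p2"), q = 0.01,
                stringsAsFactors = FALSE),
    diseases = c("d1", "d2", "d3"), annotations = c("p1", "p2"))
  expect_identical(densityTable(densityIndex(full, c(p1 = "T", p2 = "T")))$density, 1)
  none <- makeEnrichment(
    data.frame(diseaseId = "d1", annotation = "p1", q = 0.9),
    diseases = c("d1", "d2", "d3"), annotations = c("p1", "p2"))
  expect_identical(densityTable(densityIndex(none, c(p1 = "T", p2 = "T")))$density, 0)
})

test_that("absence of zero-overlap rows and row order do not change density", {
  sig <- data.frame(diseaseId = c("d2", "d1", "d1"),
                    annotation = c("p1", "p2", "p1"), q = 0.01)
  et1 <- makeEnrichment(sig, c("d1", "d2", "d3"), c("p1", "p2"))
  et2 <- makeEnrichment(sig[3:1, ], c("d1", "d2", "d3"), c("p1", "p2"))
  m <- c(p1 = "T", p2 = "T")
  expect_identical(densityTable(densityIndex(et1, m)),
                   densityTable(densityIndex(et2, m)))
})

test_that("merging themes gives the annotation-count-weighted mean density", {
  et <- makeEnrichment(
    data.frame(diseaseId = c("d1", "d2", "d3", "d1"),
               annotation = c("p1", "p1", "p2", "p3"), q = 0.01),
    diseases = c("d1", "d2", "d3"), annotations = c("p1", "p2", "p3"))
  split <- densityTable(densityIndex(et, c(p1 = "A", p2 = "A", p3 = "B")))
  merged <- densityTable(densityIndex(et, c(p1 = "M", p2 = "M", p3 = "M")))
  dA <- split$density[split$theme == "A"]; nA <- split$nAnnotations[split$theme == "A"]
  dB <- split$density[split$theme == "B"]; nB <- split$nAnnotations[split$theme == "B"]
  expect_identical(merged$density, (dA * nA + dB * nB) / (nA + nB))
})

test_that("singleton themes reduce to single-annotation density", {
  sig <- data.frame(diseaseId = sprintf("d%02d", 1:18),
                    annotation = "SST_L23", q = 0.001)
  et <- makeEnrichment(sig, sprintf("d%02d", 1:36), c("SST_L23", "PV_L5"))
  expect_identical(singleAnnotationDensity(et, "SST_L23"), 0.5)  # 18 of 36
  expect_identical(singleAnnotationDensity(et, "PV_L5"), 0)     # hollow dot
  viaTheme <- densityTable(densityIndex(et, c(SST_L23 = "a", PV_L5 = "b")))
  expect_identical(viaTheme$density[viaTheme$theme == "a"], 0.5)
  expect_identical(viaTheme$density[viaTheme$theme == "b"], 0)
  expect_error(singleAnnotationDensity(et, "nope"), "unknown annotation")
})

test_that("uncovered annotations and empty disease sets raise errors", {
  et <- makeEnrichment(
    data.frame(diseaseId = "d1", annotation = "p1", q = 0.01),
    c("d1", "d2"), c("p1", "p2"))
  expect_error(densityIndex(et, c(p1 = "T")), "p2")
  expect_error(densityIndex(et, c(p1 = "T", p2 = "T"),
                            diseaseSet = character(0)), "empty disease set")
})

test_that("threshold flagging is a pure >= comparison with recorded metadata", {
  et <- makeEnrichment(
    data.frame(diseaseId = c("d1", "d2", "d3", "d1", "d2"),
               annotation = c("p1", "p1", "p1", "p2", "p2"),
               q = c(0.01, 0.01, 0.04, 0.01, 0.2)),
    diseases = c("d1", "d2", "d3"), annotations = c("p1", "p2"))
  prof <- densityIndex(et, c(p1 = "high", p2 = "low"))
  # densities: high = 3/3, low ~ 0.333
  flagged <- flagByThreshold(prof, 0.4)
  tab <- densityTable(flagged)
  expect_identical(tab$flagged[tab$theme == "high"], TRUE)
  expect_identical(tab$flagged[tab$theme == "low"], FALSE)
  expect_identical(flagged@flagThreshold, 0.4)
  expect_true(all(densityTable(flagByThreshold(prof, 0))$flagged))
  allFlag <- densityTable(flagByThreshold(prof, 1))
  expect_identical(allFlag$flagged, allFlag$density == 1)
})

test_that("the weighted density variant saturates at the cap", {
  et <- makeEnrichment(
    data.frame(diseaseId = c("d1", "d2"), annotation = "p1",
               q = c(1e-20, 1e-3)),
    diseases = c("d1", "d2"), annotations = "p1")
  w <- densityTable(densityIndex(et, c(p1 = "T"), method = "weighted",
                                 cap = 10))$density
  expect_equal(w, (1 + 0.3) / 2, tolerance = 1e-12)  # min(1, 20/10), 3/10
})

test_that("subgroup profiles split by partition and correlate themes", {
  spec <- plantedSpec(seed = 53, coreFraction = 0.5, sharedFraction = 0.4)
  gda <- generateGDA(spec)
  gsc <- quietly(buildGeneSets(gda$table, 1, 1e6))
  ann <- generateAnnotations(spec, benchmarkThemes())
  et <- quietly(enrich(gsc, ann$collection))

  one <- Partition(rep(1, 36), items = et@diseaseIds)
  sp <- subgroupProfiles(et, ann$themeMap, one)
  tab <- densityTable(sp$profile)
  expect_identical(tab$density[tab$diseaseSet == "all"],
                   tab$density[tab$diseaseSet == "subgroup1"])

  sp4 <- subgroupProfiles(et, ann$themeMap, gda$truth)
  tab4 <- densityTable(sp4$profile)
  for (k in 1:4) {
    own <- tab4$density[tab4$theme == sprintf("private%d", k) &
                          tab4$diseaseSet == sprintf("subgroup%d", k)]
    others <- tab4$density[tab4$theme == sprintf("private%d", k) &
                             grepl("^subgroup", tab4$diseaseSet) &
                             tab4$diseaseSet != sprintf("subgroup%d", k)]
    expect_true(all(own > others))
  }
  expect_identical(dim(sp4$correlation), c(4L, 4L))

  bad <- Partition(rep(1, 10), items = sprintf("x%d", 1:10))
  expect_error(subgroupProfiles(et, ann$themeMap, bad), "absent from")
})

test_that("identical enrichment across two clusters correlates perfectly", {
  sig <- rbind(
    data.frame(diseaseId = "d1", annotation = c("p1", "p2"), q = 0.01),
    data.frame(diseaseId = "d3", annotation = c("p1", "p2"), q = 0.01))
  et <- makeEnrichment(sig, c("d1", "d2", "d3", "d4"), c("p1", "p2", "p3"))
  part <- Partition(c(d1 = 1, d2 = 1, d3 = 2, d4 = 2))
  sp <- subgroupProfiles(et, c(p1 = "A", p2 = "B", p3 = "C"), part)
  expect_equal(sp$correlation["subgroup1", "subgroup2"], 1)
})
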