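# Write a complete synthetic study (GDA + annotations + maps) to disk and
# return a ready-to-run pipeline config.

writeSyntheticStudy <- function(dir, seed = 7,
                                coreFraction = 0.5, sharedFraction = 0.4,
                                biasWeight = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- syntheticSpec(coreFraction = coreFraction,
                        sharedFraction = sharedFraction,
                        biasedCluster = 1L, biasedChromosome = 5L,
                        biasWeight = biasWeight, seed = seed)
  gda <- generateGDA(spec)
  writeGDA(gda$table, file.path(dir, "gda.tsv"))

  ann <- generateAnnotations(spec, benchmarkThemes())
  writeGMT(ann$collection, file.path(dir, "pathways.gmt"))
  writeTwoColumnMap(ann$themeMap, file.path(dir, "themes.csv"),
                    columns = c("annotation", "theme"))

  cells <- generateAnnotations(spec, data.frame(
    theme = sprintf("cell%d", 1:4), pool = sprintf("cluster%d", 1:4),
    nSets = 1, setSize = 60))
  writeGMT(cells$collection, file.path(dir, "celltypes.gmt"))

  drugs <- generateDrugSignatures(spec, nDrugs = 8, moaCount = 4,
                                  pool = "shared", signatureSize = 60)
  writeGMT(drugs$collection, file.path(dir, "drugs.gmt"))
  writeTwoColumnMap(drugs$moaMap, file.path(dir, "moa.csv"),
                    columns = c("drug", "moa"))

  chrom <- generateChromosomeMap(spec)
  writeTwoColumnMap(chrom, file.path(dir, "chromosomes.tsv"),
                    columns = c("geneSymbol", "chromosome"))

  config <- list(
    gda = file.path(dir, "gda.tsv"),
    annotations = list(pathways = file.path(dir, "pathways.gmt"),
                       celltypes = file.path(dir, "celltypes.gmt"),
                       drugs = file.path(dir, "drugs.gmt")),
    themeMap = file.path(dir, "themes.csv"),
    moaMap = file.path(dir, "moa.csv"),
    chromosomeMap = file.path(dir, "chromosomes.tsv"),
    globalK = 3L, selectCluster = "all", branchK = 1L,
    selectBranch = "all", subgroupK = 4L,
    nPermutations = 199L, seed = seed)
  list(spec = spec, gda = gda, config = config)
}
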