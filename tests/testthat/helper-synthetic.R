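# Small study configurations shared across test files; full-size runs live
# only in the acceptance suite.

tinyConfig <- function(seed = 7, ...) {
  args <- list(nCellLines = 6, nCompounds = 4, nProteins = 20,
               nGenes = 30, targetsPerCompound = 3, nDriverGenes = 3,
               noiseSd = 0.02, gapRate = 0.05, outlierRate = 0,
               growthFraction = 0, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(syntheticConfig, args)
}

# A clean (no gaps / outliers / noise / growth curves) tiny study.
cleanConfig <- function(seed = 7, ...) {
  tinyConfig(seed = seed, noiseSd = 0, gapRate = 0, outlierRate = 0, ...)
}

tinyStudyTable <- function(config = tinyConfig(), classes = c("act", "exp")) {
  study <- generateSyntheticStudy(config)
  pre <- preprocessInhibition(
    study$inhibition$records,
    compounds = sort(unique(study$inhibition$records$compound)),
    proteins = study$annotation$protein,
    doseGrid = config@doseGrid)
  filt <- filterGrowthEnhancing(study$doseResponse$params, config@doseGrid)
  viab <- imputeViability(filt$kept, config@doseGrid)
  ft <- assembleDesign(viab, pre$profile, prefixFeatures(study$omics),
                       classes = classes)
  list(study = study, profile = pre$profile, viability = viab, table = ft)
}
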