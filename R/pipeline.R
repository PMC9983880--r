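# Run configuration and the staged pipeline driver. Stages write their
# outputs plus a manifest (input hashes, seeds, config hash) so unchanged
# reruns are skipped and any output can be reproduced exactly.

.configDefaults <- function() {
  list(
    output_dir = "kinoviab-run",
    dose_grid = defaultDoseGrid(),
    feature_classes = c("act", "exp"),
    k_folds = 10L,
    seeds = list(fold = 1L, model = 1L, resample = 1L),
    k_features = 100L,
    hyper_grid = list(trees = c(500L, 1000L, 1500L, 2000L)),
    flags = list(clip = FALSE, signed_ranking = FALSE,
                 importance_mode = "impurity", r2_method = "pearson",
                 include_dose = TRUE, truncation_percentile = 99.99),
    synthetic = list(),
    inputs = list()
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, applies defaults, rejects unknown keys by
#' name, checks that every referenced input path exists, and echoes the
#' effective configuration (including every paper-gap decision flag in
#' effect) to the run log.
#'
#' @param path YAML file path.
#' @return A validated `kinoviab_run_config` list.
#' @export
loadRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  asRunConfig(raw)
}

#' @rdname loadRunConfig
#' @param config A named list of configuration values.
#' @export
asRunConfig <- function(config) {
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  eff <- defaults
  eff[names(config)] <- config
  eff$k_folds <- as.integer(eff$k_folds)
  eff$k_features <- as.integer(unlist(eff$k_features))
  eff$dose_grid <- as.numeric(unlist(eff$dose_grid))
  eff$feature_classes <- as.character(unlist(eff$feature_classes))
  eff$seeds <- lapply(eff$seeds, as.integer)
  if (any(diff(eff$dose_grid) <= 0) || any(eff$dose_grid <= 0)) {
    stop("configuration field 'dose_grid' must be positive and increasing",
         call. = FALSE)
  }
  if (!all(vapply(eff$seeds, function(s) length(s) == 1L && !is.na(s),
                  logical(1)))) {
    stop("configuration field 'seeds' must hold single integers",
         call. = FALSE)
  }
  for (nm in names(eff$inputs)) {
    p <- eff$inputs[[nm]]
    if (!file.exists(p)) {
      stop(sprintf("configuration input '%s' refers to a missing path: %s",
                   nm, p), call. = FALSE)
    }
  }
  .log("effective config: clip=%s, signed_ranking=%s, importance=%s, R2=%s, include_dose=%s, truncation=%s",
       eff$flags$clip, eff$flags$signed_ranking, eff$flags$importance_mode,
       eff$flags$r2_method, eff$flags$include_dose,
       eff$flags$truncation_percentile)
  class(eff) <- "kinoviab_run_config"
  eff
}

#' @rdname loadRunConfig
#' @export
saveRunConfig <- function(config, path) {
  out <- unclass(config)
  yaml::write_yaml(out, path)
  invisible(path)
}

.stageOrder <- c("synth", "preprocess", "impute", "assemble", "cv",
                 "final", "predict", "enrich")

.stageDeps <- list(
  synth = character(0),
  preprocess = "synth",
  impute = "synth",
  assemble = c("preprocess", "impute"),
  cv = "assemble",
  enrich = c("synth", "final"),
  final = "assemble",
  predict = "final"
)

.manifestPath <- function(dir, stage) {
  file.path(dir, sprintf("%s.manifest.json", stage))
}

.writeManifest <- function(dir, stage, inputs, config, outputs) {
  manifest <- list(
    stage = stage,
    inputs = if (length(inputs)) .hashFiles(inputs) else list(),
    config_hash = .hashObject(unclass(config)),
    outputs = basename(outputs),
    seeds = config$seeds,
    package_version = as.character(utils::packageVersion("kinoviab")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, .manifestPath(dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.stageUpToDate <- function(dir, stage, inputs, config) {
  mf <- .manifestPath(dir, stage)
  if (!file.exists(mf)) return(FALSE)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$config_hash,
                 unname(.hashObject(unclass(config))))) {
    return(FALSE)
  }
  current <- if (length(inputs)) .hashFiles(inputs) else list()
  if (!identical(lapply(manifest$inputs, as.character),
                 lapply(current, as.character))) {
    return(FALSE)
  }
  outs <- file.path(dir, unlist(manifest$outputs))
  all(file.exists(outs))
}

#' Run pipeline stages
#'
#' Executes the requested stages in the published order — synthesize inputs,
#' preprocess inhibition records, impute viability, assemble the design
#' matrix, cross-validate, fit the final model, predict untested
#' combinations, enrich — writing each stage's outputs and a manifest into
#' `config$output_dir`. A stage whose inputs, outputs and configuration are
#' unchanged is skipped unless `force = TRUE`; a stage requested before its
#' dependencies have produced outputs errors.
#'
#' @param config A run configuration (see [loadRunConfig()]).
#' @param stages Character vector of stages to run, in any order; executed
#'   in canonical order.
#' @param force Rerun stages even when up to date.
#' @return Invisibly, the output directory; per-stage status is attached as
#'   the `"status"` attribute ("ran" or "skipped").
#' @export
runPipeline <- function(config, stages = c("synth", "preprocess", "impute",
                                           "assemble", "cv"),
                        force = FALSE) {
  if (!inherits(config, "kinoviab_run_config")) config <- asRunConfig(config)
  stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
  stages <- .stageOrder[.stageOrder %in% stages]
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  status <- character(0)

  stageInputs <- function(stage) {
    deps <- .stageDeps[[stage]]
    out <- character(0)
    for (d in deps) {
      mf <- .manifestPath(dir, d)
      if (!file.exists(mf)) {
        stop(sprintf("stage '%s' requested before dependency '%s' has run",
                     stage, d), call. = FALSE)
      }
      manifest <- jsonlite::read_json(mf)
      out <- c(out, file.path(dir, unlist(manifest$outputs)))
    }
    out
  }

  for (stage in stages) {
    inputs <- stageInputs(stage)
    if (!force && .stageUpToDate(dir, stage, inputs, config)) {
      status[stage] <- "skipped"
      .log("stage %s up to date; skipped", stage)
      next
    }
    outputs <- switch(stage,
      synth = .stageSynth(config, dir),
      preprocess = .stagePreprocess(config, dir),
      impute = .stageImpute(config, dir),
      assemble = .stageAssemble(config, dir),
      cv = .stageCv(config, dir),
      final = .stageFinal(config, dir),
      predict = .stagePredict(config, dir),
      enrich = .stageEnrich(config, dir))
    .writeManifest(dir, stage, inputs, config, outputs)
    status[stage] <- "ran"
  }
  structure(invisible(dir), status = status)
}

.synthConfigFromRun <- function(config) {
  args <- config$synthetic
  args$doseGrid <- config$dose_grid
  do.call(syntheticConfig, args)
}

.stageSynth <- function(config, dir) {
  sc <- .synthConfigFromRun(config)
  study <- generateSyntheticStudy(sc)
  paths <- c(
    writeInhibitionRecords(study$inhibition$records,
                           file.path(dir, "inhibition_records.csv")),
    writeOmicsMatrix(omicsMatrix(study$omics, "expression"),
                     file.path(dir, "expression.csv")),
    writeOmicsMatrix(omicsMatrix(study$omics, "cnv"),
                     file.path(dir, "cnv.csv")),
    writeOmicsMatrix(omicsMatrix(study$omics, "proteomics"),
                     file.path(dir, "proteomics.csv")),
    writeOmicsMatrix(omicsMatrix(study$omics, "dependency"),
                     file.path(dir, "dependency.csv")),
    writeDoseResponseParams(study$doseResponse$params,
                            file.path(dir, "dose_response_params.csv")),
    writeNetwork(study$network, file.path(dir, "network.tsv")))
  annPath <- file.path(dir, "kinase_annotation.csv")
  write.csv(study$annotation, annPath, row.names = FALSE)
  truth <- study$doseResponse$truth
  truthPath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    target_sets = truth@targetSets,
    driver_genes = truth@driverGenes,
    sensitivity = as.data.frame(truth@sensitivity),
    growth_combos = truth@growthCombos), truthPath, pretty = TRUE)
  basename(c(paths, annPath, truthPath))
}

.stagePreprocess <- function(config, dir) {
  records <- readInhibitionRecords(file.path(dir, "inhibition_records.csv"))
  sc <- .synthConfigFromRun(config)
  res <- preprocessInhibition(records, .compoundNames(sc), .proteinNames(sc),
                              config$dose_grid,
                              config$flags$truncation_percentile)
  prof <- res$profile
  arr <- intensityTensor(prof)
  long <- data.frame(
    compound = rep(compounds(prof), times = dim(arr)[2] * dim(arr)[3]),
    concentration = rep(rep(doseGrid(prof), each = dim(arr)[1]),
                        times = dim(arr)[3]),
    protein = rep(proteins(prof), each = dim(arr)[1] * dim(arr)[2]),
    relative_intensity = as.vector(arr))
  profPath <- file.path(dir, "dense_profile.csv")
  write.csv(long, profPath, row.names = FALSE)
  provPath <- file.path(dir, "preprocess_provenance.json")
  jsonlite::write_json(list(
    truncation_percentile = config$flags$truncation_percentile,
    truncation_threshold = res$threshold,
    quantile_convention = "type 7 (linear interpolation)"),
    provPath, auto_unbox = TRUE, pretty = TRUE)
  basename(c(profPath, provPath))
}

.stageImpute <- function(config, dir) {
  params <- readDoseResponseParams(file.path(dir, "dose_response_params.csv"))
  filt <- filterGrowthEnhancing(params, config$dose_grid)
  clip <- if (isTRUE(config$flags$clip)) c(0, 1.2) else NULL
  viab <- imputeViability(filt$kept, config$dose_grid, clip = clip)
  vPath <- file.path(dir, "viability.csv")
  write.csv(viab, vPath, row.names = FALSE)
  rPath <- file.path(dir, "growth_removed.csv")
  write.csv(filt$removed[, c("cell_line", "compound")], rPath,
            row.names = FALSE)
  basename(c(vPath, rPath))
}

# Rebuild the in-memory profile/omics from stage outputs.
.loadStageData <- function(config, dir) {
  sc <- .synthConfigFromRun(config)
  long <- read.csv(file.path(dir, "dense_profile.csv"),
                   stringsAsFactors = FALSE)
  comps <- .compoundNames(sc); prots <- .proteinNames(sc)
  grid <- config$dose_grid
  arr <- array(NA_real_, dim = c(length(comps), length(grid), length(prots)),
               dimnames = list(comps, .doseKey(grid), prots))
  arr[cbind(match(long$compound, comps),
            .doseIndex(long$concentration, grid),
            match(long$protein, prots))] <- long$relative_intensity
  profile <- KinaseInhibitionProfile(arr, grid)
  bundle <- OmicsBundle(
    expression = readOmicsMatrix(file.path(dir, "expression.csv")),
    cnv = readOmicsMatrix(file.path(dir, "cnv.csv")),
    proteomics = imputeProteomics(
      readOmicsMatrix(file.path(dir, "proteomics.csv"))),
    dependency = dropIncompleteLines(
      readOmicsMatrix(file.path(dir, "dependency.csv"))))
  viability <- read.csv(file.path(dir, "viability.csv"),
                        stringsAsFactors = FALSE)
  list(profile = profile, omics = prefixFeatures(bundle),
       viability = viability)
}

.stageAssemble <- function(config, dir) {
  data <- .loadStageData(config, dir)
  ft <- assembleDesign(data$viability, data$profile, data$omics,
                       classes = config$feature_classes,
                       includeDose = config$flags$include_dose)
  ftPath <- file.path(dir, "feature_table.csv")
  write.csv(cbind(rowKeys(ft), response = response(ft),
                  as.data.frame(featureMatrix(ft), check.names = FALSE)),
            ftPath, row.names = FALSE)
  schemaPath <- file.path(dir, "feature_table.schema.json")
  jsonlite::write_json(list(
    key_columns = c("cell_line", "compound", "concentration"),
    response = "response",
    feature_class = as.list(featureClasses(ft))), schemaPath,
    auto_unbox = TRUE, pretty = TRUE)
  basename(c(ftPath, schemaPath))
}

.loadFeatureTable <- function(dir) {
  d <- read.csv(file.path(dir, "feature_table.csv"),
                stringsAsFactors = FALSE, check.names = FALSE)
  schema <- jsonlite::read_json(file.path(dir,
                                          "feature_table.schema.json"))
  cls <- unlist(schema$feature_class)
  featCols <- names(cls)
  FeatureTable(
    features = as.matrix(d[, featCols, drop = FALSE]),
    rowKeys = d[, c("cell_line", "compound", "concentration")],
    response = d$response,
    featureClass = cls)
}

.stageCv <- function(config, dir) {
  ft <- .loadFeatureTable(dir)
  folds <- makeGroupFolds(rowKeys(ft), K = config$k_folds,
                          seed = config$seeds$fold)
  rows <- list()
  selections <- NULL
  for (k in config$k_features) {
    for (fam in c("baseline_dose", "random_forest")) {
      spec <- modelSpec(fam, nFeatures = k, seed = config$seeds$model,
                        importanceMode = config$flags$importance_mode,
                        r2Method = config$flags$r2_method,
                        includeDose = config$flags$include_dose)
      res <- crossValidate(ft, spec, folds)
      rows[[paste(fam, k)]] <- data.frame(family = fam, k = k, r2 = res@r2,
                                          rmse = res@rmse)
      if (fam == "random_forest") selections <- foldSelections(res)
    }
  }
  mPath <- file.path(dir, "cv_metrics.csv")
  write.csv(do.call(rbind, rows), mPath, row.names = FALSE)
  sPath <- file.path(dir, "cv_selected_features.json")
  jsonlite::write_json(selections, sPath, pretty = TRUE)
  basename(c(mPath, sPath))
}

.stageFinal <- function(config, dir) {
  ft <- .loadFeatureTable(dir)
  k <- min(max(config$k_features),
           nrow(rankingTable(correlateFeatures(ft))))
  spec <- modelSpec("random_forest", nFeatures = k,
                    seed = config$seeds$model,
                    importanceMode = config$flags$importance_mode,
                    r2Method = config$flags$r2_method,
                    includeDose = config$flags$include_dose)
  fm <- fitFinalModel(ft, k = k, spec = spec)
  selPath <- file.path(dir, "final_selected_features.txt")
  writeLines(fm$features, selPath)
  impPath <- file.path(dir, "final_importance.csv")
  ann <- tryCatch(read.csv(file.path(dir, "kinase_annotation.csv"),
                           stringsAsFactors = FALSE),
                  error = function(e) NULL)
  write.csv(featureImportance(fm, ann), impPath, row.names = FALSE)
  modelPath <- file.path(dir, "final_model.rds")
  saveRDS(fm, modelPath)
  basename(c(selPath, impPath, modelPath))
}

.stagePredict <- function(config, dir) {
  fm <- readRDS(file.path(dir, "final_model.rds"))
  data <- .loadStageData(config, dir)
  tested <- unique(data$viability[, c("cell_line", "compound")])
  pred <- predictUntested(fm, data$profile, data$omics, tested)
  pPath <- file.path(dir, "untested_predictions.csv")
  write.csv(pred$predictions, pPath, row.names = FALSE)
  basename(pPath)
}

.stageEnrich <- function(config, dir) {
  net <- filterNetwork(readNetwork(file.path(dir, "network.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  sel <- readLines(file.path(dir, "final_selected_features.txt"))
  query <- sub("^exp_", "", grep("^exp_", sel, value = TRUE))
  targets <- unique(unlist(truth$target_sets))
  sc <- .synthConfigFromRun(config)
  universe <- .geneNames(sc)
  if (length(query) == 0L) query <- unique(unlist(truth$driver_genes))
  res <- resampleNull(query, universe, targets, net,
                      nDraws = 10000L, seed = config$seeds$resample)
  ePath <- file.path(dir, "enrichment.json")
  jsonlite::write_json(list(
    observed_n_interacting = res@observedNInteracting,
    observed_mean_interactors = res@observedMeanInteractors,
    percentile_n = res@percentileN,
    percentile_mean = res@percentileMean,
    n_draws = res@nDraws, seed = res@seed,
    null_summary = list(
      n_interacting_mean = mean(res@nullNInteracting),
      n_interacting_sd = sd(res@nullNInteracting),
      mean_interactors_mean = mean(res@nullMeanInteractors),
      mean_interactors_sd = sd(res@nullMeanInteractors))),
    ePath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  basename(ePath)
}
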