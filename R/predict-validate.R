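# Final-model fitting, prediction for untested combinations, plate
# normalization, QC filtering and validation metrics.

#' Fit the final full-data model
#'
#' Correlation ranking on all rows, top-k selection, then a single fit on
#' the entire table — the model used to predict untested combinations.
#'
#' @param table A [FeatureTable].
#' @param k Feature budget; must not exceed the available feature count.
#' @param spec A [modelSpec()].
#' @return List with `model` (fitted engine object), `features` (selection,
#'   in rank order), `spec`, `ranking` and `featureHash` (provenance).
#' @export
fitFinalModel <- function(table, k = 500L, spec = modelSpec()) {
  stopifnot(is(table, "FeatureTable"), is(spec, "ModelSpec"))
  ranking <- correlateFeatures(table)
  nAvail <- nrow(rankingTable(ranking))
  if (k > nAvail) {
    stop(sprintf("k = %d exceeds the %d available features", k, nAvail),
         call. = FALSE)
  }
  sel <- rankAndSelect(ranking, k)
  useCols <- sel
  if (spec@includeDose &&
      "concentration" %in% colnames(featureMatrix(table))) {
    useCols <- c(sel, "concentration")
  }
  X <- featureMatrix(table)[, useCols, drop = FALSE]
  conc <- rowKeys(table)$concentration
  fit <- .fitModel(spec, X, response(table), conc, importance = TRUE)
  out <- list(model = fit, features = sel, useCols = useCols, spec = spec,
              ranking = ranking, featureHash = .hashObject(useCols))
  class(out) <- "kinoviab_final_model"
  out
}

#' Predict viability for untested combinations
#'
#' Builds feature rows for every (cell line, compound) pair not in the
#' tested mask — cell lines needing expression (and any other omics class
#' the model uses), compounds needing an inhibition profile — and predicts
#' viability at each grid concentration. Pairs with missing inputs are
#' skipped and reported, never errored.
#'
#' @param finalModel Output of [fitFinalModel()].
#' @param profile A dense [KinaseInhibitionProfile].
#' @param omics A prefixed [OmicsBundle].
#' @param testedMask data.frame with cell_line, compound marking pairs
#'   already assayed.
#' @param cellLines,compounds Optional restrictions of the prediction
#'   universe; defaults are all cell lines with expression and all profiled
#'   compounds.
#' @param doseGrid Concentrations to predict at (default: the profile's).
#' @return List with `predictions` (data.frame cell_line, compound,
#'   concentration, predicted_viability) and `skipped` (pairs lacking
#'   inputs, with a reason).
#' @export
predictUntested <- function(finalModel, profile, omics, testedMask,
                            cellLines = NULL, compounds = NULL,
                            doseGrid = NULL) {
  stopifnot(inherits(finalModel, "kinoviab_final_model"))
  if (is.null(doseGrid)) doseGrid <- doseGrid(profile)
  expr <- omicsMatrix(omics, "expression")
  if (is.null(cellLines)) cellLines <- rownames(expr)
  if (is.null(compounds)) compounds <- compounds(profile)

  all <- expand.grid(cell_line = cellLines, compound = compounds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  testedKey <- paste(testedMask$cell_line, testedMask$compound, sep = "\r")
  untested <- all[!paste(all$cell_line, all$compound, sep = "\r") %in%
                  testedKey, , drop = FALSE]
  haveExpr <- untested$cell_line %in% rownames(expr)
  haveProf <- untested$compound %in% compounds(profile)
  skipped <- untested[!(haveExpr & haveProf), , drop = FALSE]
  if (nrow(skipped)) {
    skipped$reason <- ifelse(!skipped$cell_line %in% rownames(expr),
                             "no expression", "no inhibition profile")
  } else {
    skipped$reason <- character(0)
  }
  todo <- untested[haveExpr & haveProf, , drop = FALSE]
  if (nrow(todo) == 0L) {
    return(list(predictions = data.frame(
      cell_line = character(0), compound = character(0),
      concentration = numeric(0), predicted_viability = numeric(0)),
      skipped = skipped))
  }
  # Placeholder response: assembleDesign only uses it as the row's response.
  pseudo <- data.frame(
    cell_line = rep(todo$cell_line, each = length(doseGrid)),
    compound = rep(todo$compound, each = length(doseGrid)),
    concentration = rep(doseGrid, times = nrow(todo)),
    imputed_viability = 0, stringsAsFactors = FALSE)
  classes <- unique(c("act", sub("_.*$", "",
                                 grep("^(exp|cnv|prot|dep)_",
                                      finalModel$features, value = TRUE))))
  ft <- assembleDesign(pseudo, profile, omics, classes = classes,
                       includeDose = finalModel$spec@includeDose)
  X <- featureMatrix(ft)[, finalModel$useCols, drop = FALSE]
  preds <- .predictModel(finalModel$spec, finalModel$model, X,
                         rowKeys(ft)$concentration)
  out <- cbind(rowKeys(ft), predicted_viability = preds)
  rownames(out) <- NULL
  list(predictions = out, skipped = skipped)
}

#' Normalize plate luminescence to DMSO controls
#'
#' Relative viability of a treated well is its signal divided by the mean of
#' the DMSO-only control signals on the same plate row. Rows whose control
#' mean is zero or negative are flagged invalid and excluded with a log
#' entry. Replicate averaging happens after normalization, via
#' [averageReplicates()].
#'
#' @param measurements data.frame with row_id, cell_line, compound,
#'   concentration, replicate, signal; control wells carry compound "DMSO".
#' @return data.frame of per-well normalized records (row_id, cell_line,
#'   compound, concentration, replicate, viability); invalid rows attached
#'   as the `"invalidRows"` attribute.
#' @export
normalizePlate <- function(measurements) {
  need <- c("row_id", "cell_line", "compound", "concentration", "replicate",
            "signal")
  stopifnot(all(need %in% colnames(measurements)))
  isCtrl <- measurements$compound == "DMSO"
  ctrlMeans <- tapply(measurements$signal[isCtrl],
                      measurements$row_id[isCtrl], mean)
  treated <- measurements[!isCtrl, , drop = FALSE]
  noCtrl <- setdiff(unique(treated$row_id), names(ctrlMeans))
  if (length(noCtrl)) {
    stop(sprintf("plate row(s) without DMSO controls: %s",
                 paste(noCtrl, collapse = ", ")), call. = FALSE)
  }
  cm <- ctrlMeans[treated$row_id]
  invalid <- unique(treated$row_id[cm <= 0])
  if (length(invalid)) {
    .log("excluding %d plate rows with non-positive control means",
         length(invalid))
  }
  keep <- !(treated$row_id %in% invalid)
  out <- data.frame(
    row_id = treated$row_id[keep], cell_line = treated$cell_line[keep],
    compound = treated$compound[keep],
    concentration = treated$concentration[keep],
    replicate = treated$replicate[keep],
    viability = treated$signal[keep] / cm[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "invalidRows") <- invalid
  out
}

#' Quality-control filter on normalized plate rows
#'
#' A plate row is removed when any of its normalized viabilities reaches
#' `maxFraction` of the DMSO control (default 1.2, i.e. the "< 120% of
#' DMSO" criterion); removals are logged with their identifiers.
#'
#' @param normalized Output of [normalizePlate()].
#' @param maxFraction Breach threshold (a value >= it removes the row).
#' @return List with `kept` and `removed` data.frames partitioning the
#'   input rows.
#' @export
qcFilter <- function(normalized, maxFraction = 1.2) {
  stopifnot(all(c("row_id", "viability") %in% colnames(normalized)))
  breach <- tapply(normalized$viability, normalized$row_id,
                   function(v) any(v >= maxFraction))
  bad <- names(breach)[breach]
  if (length(bad)) {
    .log("QC removed plate rows: %s", paste(bad, collapse = ", "))
  }
  isBad <- normalized$row_id %in% bad
  list(kept = normalized[!isBad, , drop = FALSE],
       removed = normalized[isBad, , drop = FALSE])
}

#' Average replicate wells after normalization
#'
#' @param normalized Per-well normalized records.
#' @return data.frame with one viability per (cell line, compound,
#'   concentration).
#' @export
averageReplicates <- function(normalized) {
  key <- paste(normalized$cell_line, normalized$compound,
               .doseKey(normalized$concentration), sep = "\r")
  agg <- tapply(normalized$viability, key, mean)
  first <- !duplicated(key)
  out <- data.frame(
    cell_line = normalized$cell_line[first],
    compound = normalized$compound[first],
    concentration = normalized$concentration[first],
    viability = unname(agg[key[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare predictions (or reference viabilities) with measurements
#'
#' Joins the two tables on (cell line, compound, concentration) and computes
#' R^2 and RMSE over the pairs via [evaluatePredictions()]. Unmatched keys
#' on either side are reported.
#'
#' @param reference data.frame with cell_line, compound, concentration and a
#'   value column (`predicted_viability`, `imputed_viability` or
#'   `viability`).
#' @param measured data.frame with the same keys and a `viability` column.
#' @param r2Method Passed to [evaluatePredictions()].
#' @return List with `r2`, `rmse`, `paired` (the joined table) and
#'   `unmatched` (keys present on one side only).
#' @export
compareValidation <- function(reference, measured,
                              r2Method = c("pearson", "traditional")) {
  r2Method <- match.arg(r2Method)
  valCol <- intersect(c("predicted_viability", "imputed_viability",
                        "viability"), colnames(reference))[1]
  if (is.na(valCol)) stop("reference lacks a viability value column",
                          call. = FALSE)
  keyOf <- function(d) paste(d$cell_line, d$compound,
                             .doseKey(d$concentration), sep = "\r")
  kr <- keyOf(reference); km <- keyOf(measured)
  idx <- match(kr, km)
  hit <- !is.na(idx)
  if (sum(hit) == 0L) stop("empty join between reference and measured",
                           call. = FALSE)
  if (sum(hit) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  paired <- data.frame(
    cell_line = reference$cell_line[hit],
    compound = reference$compound[hit],
    concentration = reference$concentration[hit],
    reference = reference[[valCol]][hit],
    measured = measured$viability[idx[hit]],
    stringsAsFactors = FALSE)
  m <- evaluatePredictions(paired$reference, paired$measured, r2Method)
  unmatched <- list(reference = kr[!hit], measured = setdiff(km, kr))
  list(r2 = unname(m["r2"]), rmse = unname(m["rmse"]), paired = paired,
       unmatched = unmatched)
}
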