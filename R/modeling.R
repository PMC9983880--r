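# Grouped cross-validation with in-fold feature selection, model families,
# metrics, hyperparameter sweeps, importance and ablations.

#' Grouped fold assignment over (cell line, compound) combinations
#'
#' Every record sharing a (cell line, compound) key — the whole viability
#' curve from one treatment — is one unit for cross-validation, so all its
#' concentrations land in the same fold and no curve leaks between training
#' and test. The partition is random, balanced (fold sizes differ by at most
#' one combination) and deterministic given the seed.
#'
#' @param combinations data.frame with cell_line and compound columns
#'   (duplicates are collapsed).
#' @param K Number of folds.
#' @param seed Fold seed (separate from any model seed).
#' @return data.frame with cell_line, compound, fold.
#' @export
makeGroupFolds <- function(combinations, K = 10L, seed = 1L) {
  stopifnot(all(c("cell_line", "compound") %in% colnames(combinations)))
  combos <- unique(combinations[, c("cell_line", "compound"), drop = FALSE])
  n <- nrow(combos)
  if (K > n) stop(sprintf("K = %d exceeds the %d combinations", K, n),
                  call. = FALSE)
  .withSeed(seed, {
    fold <- rep_len(seq_len(K), n)[sample.int(n)]
    out <- data.frame(cell_line = combos$cell_line,
                      compound = combos$compound, fold = fold,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# Map table rows to fold ids via their (cell line, compound) key.
.rowFolds <- function(table, folds) {
  keys <- rowKeys(table)
  idx <- match(paste(keys$cell_line, keys$compound, sep = "\r"),
               paste(folds$cell_line, folds$compound, sep = "\r"))
  if (anyNA(idx)) {
    stop("table contains combinations without a fold assignment",
         call. = FALSE)
  }
  folds$fold[idx]
}

#' Dose-only baseline model
#'
#' The naive benchmark: predict the training-set mean viability at each grid
#' concentration. Any model worth keeping must beat it.
#'
#' @param concentrations Training concentrations (molar).
#' @param responses Training viabilities.
#' @return A predictor object; call [predictBaselineDose()] on new
#'   concentrations.
#' @export
baselineDoseModel <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  key <- .doseKey(concentrations)
  means <- tapply(responses, key, mean)
  structure(list(means = means), class = "kinoviab_baseline_dose")
}

#' @rdname baselineDoseModel
#' @param model A baseline predictor.
#' @param newConcentrations Concentrations to predict at; each must have been
#'   seen in training.
#' @export
predictBaselineDose <- function(model, newConcentrations) {
  stopifnot(inherits(model, "kinoviab_baseline_dose"))
  key <- .doseKey(newConcentrations)
  miss <- setdiff(unique(key), names(model$means))
  if (length(miss)) {
    stop(sprintf("concentration(s) unseen in training: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  as.vector(model$means[key])
}

# predictors-per-split: the tuning-grid default of 22 where the feature
# count allows it, otherwise the square-root heuristic.
.resolveMtry <- function(spec, p) {
  if (!is.na(spec@mtry)) return(as.integer(min(spec@mtry, p)))
  if (p >= 22L) 22L else max(1L, floor(sqrt(p)))
}

# Fit one model family on a design matrix.
.fitModel <- function(spec, X, y, concentrations, importance = FALSE) {
  switch(spec@family,
    baseline_dose = baselineDoseModel(concentrations, y),
    linear = {
      df <- as.data.frame(X)
      names(df) <- make.names(names(df))
      df$.y <- y
      lm(.y ~ ., data = df)
    },
    random_forest = {
      ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = spec@trees,
        mtry = .resolveMtry(spec, ncol(X)),
        min.node.size = spec@minNodeSize,
        importance = if (importance) spec@importanceMode else "none",
        seed = spec@seed, num.threads = 1L, verbose = FALSE)
    },
    gradient_boosting = {
      xgboost::xgboost(
        data = X, label = y, nrounds = min(spec@trees, 300L),
        params = list(eta = 0.1, max_depth = 6, nthread = 1,
                      seed = spec@seed),
        verbose = 0)
    },
    stop("unknown model family: ", spec@family, call. = FALSE))
}

.predictModel <- function(spec, fit, X, concentrations) {
  switch(spec@family,
    baseline_dose = predictBaselineDose(fit, concentrations),
    linear = {
      df <- as.data.frame(X)
      names(df) <- make.names(names(df))
      unname(predict(fit, newdata = df))
    },
    random_forest = predict(fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions,
    gradient_boosting = predict(fit, newdata = X))
}

#' Prediction metrics
#'
#' `r2Method = "pearson"` defines R^2 as the squared Pearson correlation of
#' predictions and observations (insensitive to calibration shifts);
#' `"traditional"` is the coefficient of determination 1 - SSE/SST. RMSE is
#' the root mean squared error in either case. Zero-variance predictions
#' yield R^2 = 0 with a warning.
#'
#' @param predictions,observed Equal-length numeric vectors (>= 2).
#' @param r2Method "pearson" or "traditional".
#' @return Named numeric c(r2 = , rmse = ).
#' @export
#' @examples
#' evaluatePredictions(c(0.5, 0.7), c(0.6, 0.8))
evaluatePredictions <- function(predictions, observed,
                                r2Method = c("pearson", "traditional")) {
  r2Method <- match.arg(r2Method)
  stopifnot(length(predictions) == length(observed),
            length(predictions) >= 2L)
  rmse <- sqrt(mean((predictions - observed)^2))
  if (sd(predictions) == 0 || sd(observed) == 0) {
    warning("zero-variance predictions or observations; R^2 set to 0")
    r2 <- 0
  } else if (r2Method == "pearson") {
    r2 <- cor(predictions, observed)^2
  } else {
    r2 <- 1 - sum((observed - predictions)^2) /
      sum((observed - mean(observed))^2)
  }
  c(r2 = r2, rmse = rmse)
}

#' Grouped cross-validation with in-fold feature selection
#'
#' For each fold: Pearson correlations are recomputed on the training rows
#' only, the top-k features are selected, the model is fitted and the
#' held-out rows predicted. Out-of-fold predictions are concatenated in
#' table row order, so they are a pure function of the training folds.
#' Per-fold selected feature lists are retained for stability analysis.
#'
#' @param table A [FeatureTable].
#' @param spec A [modelSpec()].
#' @param folds A fold assignment from [makeGroupFolds()].
#' @return A `CvResult`.
#' @export
crossValidate <- function(table, spec, folds) {
  stopifnot(is(table, "FeatureTable"), is(spec, "ModelSpec"))
  rowFold <- .rowFolds(table, folds)
  n <- nrow(table)
  preds <- rep(NA_real_, n)
  selections <- list()
  for (f in sort(unique(rowFold))) {
    trainIdx <- which(rowFold != f)
    testIdx <- which(rowFold == f)
    train <- .subsetRows(table, trainIdx)
    trainConc <- rowKeys(train)$concentration
    testConc <- rowKeys(table)$concentration[testIdx]
    if (length(unique(trainConc)) == 0L) {
      stop("fold with empty training concentrations", call. = FALSE)
    }
    if (spec@family == "baseline_dose") {
      fit <- baselineDoseModel(trainConc, response(train))
      preds[testIdx] <- predictBaselineDose(fit, testConc)
      selections[[as.character(f)]] <- character(0)
      next
    }
    ranking <- correlateFeatures(train)
    k <- min(spec@nFeatures, nrow(rankingTable(ranking)))
    sel <- rankAndSelect(ranking, k)
    selections[[as.character(f)]] <- sel
    useCols <- sel
    if (spec@includeDose &&
        "concentration" %in% colnames(featureMatrix(table))) {
      useCols <- c(sel, "concentration")
    }
    Xtr <- featureMatrix(train)[, useCols, drop = FALSE]
    Xte <- featureMatrix(table)[testIdx, useCols, drop = FALSE]
    fit <- .fitModel(spec, Xtr, response(train), trainConc)
    preds[testIdx] <- .predictModel(spec, fit, Xte, testConc)
  }
  m <- evaluatePredictions(preds, response(table), spec@r2Method)
  new("CvResult", predictions = preds, observed = response(table),
      rowKeys = rowKeys(table), folds = as.integer(rowFold),
      r2 = unname(m["r2"]), rmse = unname(m["rmse"]),
      selectedFeatures = selections, spec = spec)
}

#' Per-compound or per-cell-line metrics
#'
#' Recomputes R^2 and RMSE within each group of the out-of-fold predictions.
#' Groups with fewer than 3 rows are excluded and flagged.
#'
#' @param result A `CvResult`.
#' @param by "compound" or "cell_line".
#' @return data.frame with group, n, r2, rmse; excluded groups attached as
#'   the `"excluded"` attribute.
#' @export
subsetMetrics <- function(result, by = c("compound", "cell_line")) {
  by <- match.arg(by)
  stopifnot(is(result, "CvResult"))
  g <- result@rowKeys[[by]]
  groups <- unique(g)
  rows <- list()
  excluded <- character(0)
  for (grp in groups) {
    idx <- which(g == grp)
    if (length(idx) < 3L) {
      excluded <- c(excluded, grp)
      next
    }
    m <- suppressWarnings(evaluatePredictions(
      result@predictions[idx], result@observed[idx],
      result@spec@r2Method))
    rows[[grp]] <- data.frame(group = grp, n = length(idx),
                              r2 = unname(m["r2"]), rmse = unname(m["rmse"]),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Hyperparameter sweep over the tuning grid
#'
#' Cross-validates one model configuration per grid point — tree count,
#' predictors per split, minimal node size — using identical folds
#' throughout, so rows are directly comparable.
#'
#' @param table A [FeatureTable].
#' @param folds Fold assignment shared by all grid points.
#' @param grid Named list with any of `trees`, `mtry`, `minNodeSize`;
#'   defaults to the standard tuning grid (trees 500/1000/1500/2000 only).
#' @param baseSpec The [modelSpec()] whose other settings are held fixed.
#' @return data.frame with trees, mtry, minNodeSize, r2, rmse.
#' @export
hyperparameterSweep <- function(table, folds,
                                grid = list(trees = c(500L, 1000L, 1500L,
                                                      2000L)),
                                baseSpec = modelSpec("random_forest",
                                                     nFeatures = 100L)) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  full <- list(trees = baseSpec@trees, mtry = baseSpec@mtry,
               minNodeSize = baseSpec@minNodeSize)
  unknown <- setdiff(names(grid), names(full))
  if (length(unknown)) {
    stop("unknown grid dimension(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full[names(grid)] <- grid
  pts <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    spec <- baseSpec
    spec@trees <- as.integer(pts$trees[i])
    spec@mtry <- as.numeric(pts$mtry[i])
    spec@minNodeSize <- as.integer(pts$minNodeSize[i])
    res <- crossValidate(table, spec, folds)
    out[[i]] <- data.frame(trees = pts$trees[i], mtry = pts$mtry[i],
                           minNodeSize = pts$minNodeSize[i],
                           r2 = res@r2, rmse = res@rmse)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variable importance with kinase class tags
#'
#' Extracts importance scores from a fitted tree ensemble (see
#' [fitFinalModel()]), ranks them descending and tags each feature:
#' inhibition features by their protein's kinase annotation ("dark kinase",
#' "light kinase", "non-kinase"; unannotated proteins fall back to
#' "non-kinase" with a warning), expression features as "expression", other
#' omics by their class prefix.
#'
#' @param finalModel Output of [fitFinalModel()] for a tree-ensemble family.
#' @param annotation data.frame with protein and class columns (see
#'   [generateKinaseAnnotation()]); `NULL` tags all inhibition features
#'   "non-kinase".
#' @return data.frame with feature, importance, rank, tag.
#' @export
featureImportance <- function(finalModel, annotation = NULL) {
  spec <- finalModel$spec
  if (!spec@family %in% c("random_forest", "gradient_boosting")) {
    stop(sprintf("family '%s' does not support importance extraction",
                 spec@family), call. = FALSE)
  }
  if (spec@family == "random_forest") {
    imp <- finalModel$model$variable.importance
  } else {
    tab <- xgboost::xgb.importance(model = finalModel$model)
    imp <- setNames(tab$Gain, tab$Feature)
    # xgboost omits unused features; report them with zero importance.
    missing <- setdiff(finalModel$features, names(imp))
    imp <- c(imp, setNames(rep(0, length(missing)), missing))
  }
  feat <- names(imp)
  tag <- rep(NA_character_, length(feat))
  isAct <- startsWith(feat, "act_")
  if (any(isAct)) {
    prot <- sub("^act_", "", feat[isAct])
    if (is.null(annotation)) {
      tag[isAct] <- "non-kinase"
    } else {
      idx <- match(prot, annotation$protein)
      if (anyNA(idx)) {
        warning(sprintf("%d inhibition proteins lack annotation; tagged %s",
                        sum(is.na(idx)), "'non-kinase'"))
      }
      tag[isAct] <- ifelse(is.na(idx), "non-kinase", annotation$class[idx])
    }
  }
  tag[startsWith(feat, "exp_")] <- "expression"
  for (pre in c("cnv", "prot", "dep")) {
    tag[startsWith(feat, paste0(pre, "_"))] <- pre
  }
  tag[feat == "concentration"] <- "dose"
  ord <- order(-imp, feat)
  out <- data.frame(feature = feat[ord], importance = unname(imp[ord]),
                    rank = seq_along(feat), tag = tag[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature-class ablations
#'
#' Cross-validated metrics over the shared folds for restricted feature
#' sets: chosen classes only, optionally the kinase subset of the inhibition
#' columns, optionally single-dose rows (each compound restricted to its
#' maximum-variance dose via [pickMaxVarianceDose()]). By default the dose
#' covariate is included only when inhibition features are — an
#' expression-only model is meant to test baseline omics alone, without
#' treatment information.
#'
#' @param table A full [FeatureTable].
#' @param folds Fold assignment from [makeGroupFolds()].
#' @param classes Feature classes to keep (e.g. `c("exp")`).
#' @param kList Feature budgets to evaluate.
#' @param baseSpec The [modelSpec()] template.
#' @param kinaseOnly Restrict inhibition columns to annotated kinases.
#' @param annotation Kinase annotation (required when `kinaseOnly`).
#' @param singleDose Restrict rows to each compound's maximum-variance dose.
#' @param includeDose Override the default dose-covariate rule.
#' @return data.frame with classes, kinase_only, single_dose, k, r2, rmse.
#' @export
ablationRun <- function(table, folds, classes = c("act", "exp"),
                        kList = c(100L), baseSpec = modelSpec(),
                        kinaseOnly = FALSE, annotation = NULL,
                        singleDose = FALSE, includeDose = NULL) {
  stopifnot(is(table, "FeatureTable"))
  cls <- featureClasses(table)
  keep <- names(cls)[cls %in% classes]
  if (kinaseOnly) {
    if (is.null(annotation)) stop("kinaseOnly requires an annotation",
                                  call. = FALSE)
    kinases <- annotation$protein[annotation$is_kinase]
    actCols <- keep[startsWith(keep, "act_")]
    dropAct <- actCols[!sub("^act_", "", actCols) %in% kinases]
    keep <- setdiff(keep, dropAct)
  }
  if (!length(keep)) stop("empty feature set after restriction",
                          call. = FALSE)
  if (is.null(includeDose)) includeDose <- "act" %in% classes
  hasDose <- "concentration" %in% colnames(featureMatrix(table))
  useCols <- if (includeDose && hasDose) c(keep, "concentration") else keep

  sub <- new("FeatureTable",
             features = featureMatrix(table)[, useCols, drop = FALSE],
             rowKeys = rowKeys(table), response = response(table),
             featureClass = cls[useCols])
  if (singleDose) {
    viability <- cbind(rowKeys(table),
                       imputed_viability = response(table))
    best <- pickMaxVarianceDose(viability)
    keys <- rowKeys(table)
    rowsKeep <- which(.doseKey(keys$concentration) ==
                      .doseKey(best[keys$compound]))
    sub <- .subsetRows(sub, rowsKeep)
  }
  out <- vector("list", length(kList))
  for (i in seq_along(kList)) {
    spec <- baseSpec
    spec@nFeatures <- as.integer(min(kList[i], length(keep)))
    spec@includeDose <- includeDose
    res <- crossValidate(sub, spec, folds)
    out[[i]] <- data.frame(
      classes = paste(classes, collapse = "+"), kinase_only = kinaseOnly,
      single_dose = singleDose, k = kList[i], r2 = res@r2, rmse = res@rmse,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
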