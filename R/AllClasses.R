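#' @import methods
NULL

# The eight concentrations (molar) used throughout: 3 nM to 30 uM.
#' Default concentration grid
#'
#' The eight assay concentrations shared by the inhibition profiling and the
#' viability imputation: 3 nM, 10 nM, 30 nM, 100 nM, 300 nM, 1 uM, 3 uM and
#' 30 uM, in molar units.
#'
#' @return Numeric vector of length 8, strictly increasing.
#' @export
#' @examples
#' defaultDoseGrid()
defaultDoseGrid <- function() {
  c(3e-9, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6, 3e-5)
}

## ---------------------------------------------------------------------------
## SyntheticConfig
## ---------------------------------------------------------------------------

#' @rdname syntheticConfig
#' @export
setClass("SyntheticConfig",
  representation(
    nCellLines = "integer",
    nCompounds = "integer",
    nProteins = "integer",
    nGenes = "integer",
    doseGrid = "numeric",
    targetsPerCompound = "integer",
    nDriverGenes = "integer",
    noiseSd = "numeric",
    gapRate = "numeric",
    outlierRate = "numeric",
    growthFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  for (s in c("nCellLines", "nCompounds", "nProteins", "nGenes",
              "targetsPerCompound", "nDriverGenes")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L) {
      msgs <- c(msgs, sprintf("'%s' must be a count >= 1", s))
    }
  }
  g <- object@doseGrid
  if (length(g) < 2L || any(!is.finite(g)) || any(g <= 0) ||
      any(diff(g) <= 0)) {
    msgs <- c(msgs, "doseGrid must be strictly increasing and all > 0")
  }
  for (s in c("gapRate", "outlierRate", "growthFraction")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msgs <- c(msgs, sprintf("'%s' must be in [0, 1]", s))
    }
  }
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) ||
      object@noiseSd < 0) {
    msgs <- c(msgs, "noiseSd must be a single value >= 0")
  }
  if (object@targetsPerCompound > object@nProteins) {
    msgs <- c(msgs, "targetsPerCompound cannot exceed nProteins")
  }
  if (object@nDriverGenes > object@nGenes) {
    msgs <- c(msgs, "nDriverGenes cannot exceed nGenes")
  }
  if (length(msgs)) msgs else TRUE
})

#' Configuration for the synthetic study generator
#'
#' Defines the dimensions and noise structure of a synthetic kinome-inhibition
#' viability study with known ground truth. The defaults describe the study
#' conditions used throughout the package's tests: 40 cell lines, 30
#' compounds profiled over the standard 8-dose grid against 150 proteins,
#' 200 expression genes, 4 planted targets and 5 planted driver genes per
#' compound, Gaussian viability noise of 0.05, a 1.8% single-concentration
#' gap rate and a 0.01% outlier rate (the rates observed in real kinobead
#' tables), and 2% growth-enhancing curves.
#'
#' @param nCellLines,nCompounds,nProteins,nGenes Study dimensions (counts).
#' @param doseGrid Strictly increasing molar concentrations.
#' @param targetsPerCompound Number of planted target proteins per compound.
#' @param nDriverGenes Number of planted sensitivity-driver genes per
#'   compound.
#' @param noiseSd Gaussian noise sd added to true viability before curve
#'   fitting.
#' @param gapRate Probability that an interior single-concentration value of
#'   a target series is withheld from the sparse records.
#' @param outlierRate Probability that a recorded intensity is inflated by a
#'   factor > 3.
#' @param growthFraction Fraction of (cell line, compound) combinations given
#'   an increasing (growth-enhancing) dose-response curve.
#' @param seed Integer seed; identical configs produce identical outputs.
#' @return A `SyntheticConfig` object.
#' @export
#' @examples
#' cfg <- syntheticConfig(nCellLines = 6, nCompounds = 4, seed = 7)
#' cfg
syntheticConfig <- function(nCellLines = 40, nCompounds = 30,
                            nProteins = 150, nGenes = 200,
                            doseGrid = defaultDoseGrid(),
                            targetsPerCompound = 4, nDriverGenes = 5,
                            noiseSd = 0.05, gapRate = 0.018,
                            outlierRate = 1e-4, growthFraction = 0.02,
                            seed = 1) {
  new("SyntheticConfig",
      nCellLines = as.integer(nCellLines),
      nCompounds = as.integer(nCompounds),
      nProteins = as.integer(nProteins),
      nGenes = as.integer(nGenes),
      doseGrid = as.numeric(doseGrid),
      targetsPerCompound = as.integer(targetsPerCompound),
      nDriverGenes = as.integer(nDriverGenes),
      noiseSd = as.numeric(noiseSd),
      gapRate = as.numeric(gapRate),
      outlierRate = as.numeric(outlierRate),
      growthFraction = as.numeric(growthFraction),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## KinaseInhibitionProfile: dense compound x concentration x protein tensor
## ---------------------------------------------------------------------------

#' @rdname KinaseInhibitionProfile
#' @export
setClass("KinaseInhibitionProfile",
  representation(
    intensity = "array",
    doseGrid = "numeric"
  )
)

setValidity("KinaseInhibitionProfile", function(object) {
  msgs <- character(0)
  a <- object@intensity
  if (length(dim(a)) != 3L) {
    msgs <- c(msgs, "intensity must be a 3-d array [compound x dose x protein]")
  } else {
    dn <- dimnames(a)
    if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
      msgs <- c(msgs, "intensity must carry compound/dose/protein dimnames")
    }
    if (dim(a)[2] != length(object@doseGrid)) {
      msgs <- c(msgs, "second dimension must match doseGrid length")
    }
  }
  if (any(diff(object@doseGrid) <= 0) || any(object@doseGrid <= 0)) {
    msgs <- c(msgs, "doseGrid must be strictly increasing and positive")
  }
  vals <- object@intensity[!is.na(object@intensity)]
  if (length(vals) && any(vals < 0)) {
    msgs <- c(msgs, "relative intensities must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Dense kinase-inhibition profile
#'
#' A dense compound x concentration x protein tensor of relative intensities
#' (the "kinase inhibition state"): 0 means a fully inhibited target, 1 means
#' unaffected; values above 1 indicate apparent increased capture. Cells may
#' be `NA` between densification and gap imputation.
#'
#' @param intensity 3-d array with dimnames (compound, dose, protein).
#' @param doseGrid Molar concentrations matching the second dimension.
#' @return A `KinaseInhibitionProfile`.
#' @seealso [densifyInhibition()], [imputeMissingConcentrations()],
#'   [truncateOutliers()]
#' @export
KinaseInhibitionProfile <- function(intensity, doseGrid) {
  new("KinaseInhibitionProfile", intensity = intensity,
      doseGrid = as.numeric(doseGrid))
}

#' @describeIn KinaseInhibitionProfile Compound identifiers.
#' @param object,x A `KinaseInhibitionProfile`.
#' @export
setGeneric("compounds", function(object) standardGeneric("compounds"))

#' @rdname KinaseInhibitionProfile
#' @export
setMethod("compounds", "KinaseInhibitionProfile",
          function(object) dimnames(object@intensity)[[1]])

#' @describeIn KinaseInhibitionProfile Protein identifiers.
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))

#' @rdname KinaseInhibitionProfile
#' @export
setMethod("proteins", "KinaseInhibitionProfile",
          function(object) dimnames(object@intensity)[[3]])

#' @describeIn KinaseInhibitionProfile Concentration grid (molar).
#' @export
setGeneric("doseGrid", function(object) standardGeneric("doseGrid"))

#' @rdname KinaseInhibitionProfile
#' @export
setMethod("doseGrid", "KinaseInhibitionProfile",
          function(object) object@doseGrid)

#' @describeIn KinaseInhibitionProfile The intensity tensor.
#' @export
setGeneric("intensityTensor", function(object) standardGeneric("intensityTensor"))

#' @rdname KinaseInhibitionProfile
#' @export
setMethod("intensityTensor", "KinaseInhibitionProfile",
          function(object) object@intensity)

setMethod("show", "KinaseInhibitionProfile", function(object) {
  d <- dim(object@intensity)
  nNA <- sum(is.na(object@intensity))
  cat(sprintf(paste0("KinaseInhibitionProfile: %d compounds x %d doses x ",
                     "%d proteins\n"), d[1], d[2], d[3]))
  cat(sprintf("  dose grid: %s M\n",
              paste(signif(object@doseGrid, 3), collapse = ", ")))
  cat(sprintf("  missing cells: %d\n", nNA))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## OmicsBundle
## ---------------------------------------------------------------------------

#' @rdname OmicsBundle
#' @export
setClass("OmicsBundle",
  representation(
    expression = "ANY",
    cnv = "ANY",
    proteomics = "ANY",
    dependency = "ANY"
  )
)

setValidity("OmicsBundle", function(object) {
  msgs <- character(0)
  for (s in c("expression", "cnv", "proteomics", "dependency")) {
    m <- slot(object, s)
    if (is.null(m)) next
    if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
      msgs <- c(msgs, sprintf(
        "'%s' must be a matrix with cell-line rownames and feature colnames", s))
      next
    }
    if (anyDuplicated(colnames(m))) {
      msgs <- c(msgs, sprintf("duplicate feature labels within '%s'", s))
    }
  }
  ex <- object@expression
  if (is.matrix(ex) && any(ex[!is.na(ex)] < 0)) {
    msgs <- c(msgs, "expression values must be >= 0 (log2 TPM+1 scale)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Baseline omics bundle
#'
#' Per-cell-line baseline measurements: gene expression (log2 TPM with
#' pseudocount 1), gene-level copy number, proteomics (possibly with missing
#' protein readings) and CRISPR-KO dependency scores. Matrices are keyed by
#' cell line in the rows; any slot may be `NULL` when that class is not
#' available.
#'
#' @param expression,cnv,proteomics,dependency Matrices (cell line x feature)
#'   or `NULL`.
#' @return An `OmicsBundle`.
#' @export
OmicsBundle <- function(expression = NULL, cnv = NULL, proteomics = NULL,
                        dependency = NULL) {
  new("OmicsBundle", expression = expression, cnv = cnv,
      proteomics = proteomics, dependency = dependency)
}

#' @describeIn OmicsBundle Retrieve one omics matrix by class name
#'   ("expression", "cnv", "proteomics", "dependency").
#' @param object An `OmicsBundle`.
#' @param what Class name.
#' @export
setGeneric("omicsMatrix", function(object, what) standardGeneric("omicsMatrix"))

#' @rdname OmicsBundle
#' @export
setMethod("omicsMatrix", "OmicsBundle", function(object, what) {
  what <- match.arg(what, c("expression", "cnv", "proteomics", "dependency"))
  slot(object, what)
})

setMethod("show", "OmicsBundle", function(object) {
  cat("OmicsBundle\n")
  for (s in c("expression", "cnv", "proteomics", "dependency")) {
    m <- slot(object, s)
    if (is.null(m)) {
      cat(sprintf("  %-11s: <absent>\n", s))
    } else {
      cat(sprintf("  %-11s: %d cell lines x %d features (%d NA)\n",
                  s, nrow(m), ncol(m), sum(is.na(m))))
    }
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' @rdname GroundTruth
#' @export
setClass("GroundTruth",
  representation(
    targetSets = "list",
    driverGenes = "list",
    sensitivity = "matrix",
    trueViability = "array",
    growthCombos = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character(0)
  if (any(vapply(object@targetSets, length, integer(1)) < 1L)) {
    msgs <- c(msgs, "every compound must have at least one target")
  }
  s <- object@sensitivity
  if (any(s < 0 | s > 1)) msgs <- c(msgs, "sensitivity must lie in [0, 1]")
  v <- object@trueViability[!is.na(object@trueViability)]
  if (length(v) && (min(v) < 0 || max(v) > 1.2)) {
    msgs <- c(msgs, "true viability must lie in [0, 1.2]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' Records everything needed to verify downstream recovery: the planted
#' target set and driver-gene set per compound, the (cell line, compound)
#' sensitivity matrix in \[0, 1\], the noise-free true viability tensor over
#' the dose grid, and the combinations planted with growth-enhancing curves.
#'
#' @param targetSets Named list, compound -> character vector of proteins.
#' @param driverGenes Named list, compound -> character vector of genes.
#' @param sensitivity Matrix (cell line x compound) in \[0, 1\].
#' @param trueViability 3-d array (cell line x compound x dose).
#' @param growthCombos data.frame with columns cell_line, compound.
#' @return A `GroundTruth`.
#' @export
GroundTruth <- function(targetSets, driverGenes, sensitivity, trueViability,
                        growthCombos = data.frame(cell_line = character(0),
                                                  compound = character(0))) {
  new("GroundTruth", targetSets = targetSets, driverGenes = driverGenes,
      sensitivity = sensitivity, trueViability = trueViability,
      growthCombos = growthCombos)
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d compounds, %d cell lines, %d doses\n",
              length(object@targetSets), nrow(object@sensitivity),
              dim(object@trueViability)[3]))
  cat(sprintf("  growth-enhancing combos: %d\n", nrow(object@growthCombos)))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## FeatureTable
## ---------------------------------------------------------------------------

#' @rdname FeatureTable
#' @export
setClass("FeatureTable",
  representation(
    features = "matrix",
    rowKeys = "data.frame",
    response = "numeric",
    featureClass = "character"
  )
)

setValidity("FeatureTable", function(object) {
  msgs <- character(0)
  n <- nrow(object@features)
  if (nrow(object@rowKeys) != n || length(object@response) != n) {
    msgs <- c(msgs, "features, rowKeys and response must agree in length")
  }
  if (!all(c("cell_line", "compound", "concentration") %in%
           colnames(object@rowKeys))) {
    msgs <- c(msgs, "rowKeys needs cell_line, compound, concentration")
  }
  cn <- colnames(object@features)
  if (is.null(cn) || anyDuplicated(cn)) {
    msgs <- c(msgs, "feature columns must carry unique names")
  } else if (!identical(sort(names(object@featureClass)), sort(cn))) {
    msgs <- c(msgs, "featureClass must be named by every feature column")
  }
  if (anyNA(object@features)) msgs <- c(msgs, "feature matrix has missing cells")
  if (length(msgs)) msgs else TRUE
})

#' Modeling design matrix
#'
#' Rows are (cell line, compound, concentration) treatment combinations; the
#' response is the imputed relative viability for that row. Columns are
#' class-prefixed features: inhibition states (`act_*`) varying with
#' (compound, concentration), omics columns (`exp_*`, `cnv_*`, `prot_*`,
#' `dep_*`) broadcast per cell line, and optionally the raw concentration
#' covariate (class `"dose"`).
#'
#' @param features Numeric matrix with named columns.
#' @param rowKeys data.frame with cell_line, compound, concentration.
#' @param response Numeric response per row.
#' @param featureClass Named character vector giving each column's class.
#' @return A `FeatureTable`.
#' @seealso [assembleDesign()]
#' @export
FeatureTable <- function(features, rowKeys, response, featureClass) {
  new("FeatureTable", features = features, rowKeys = rowKeys,
      response = as.numeric(response), featureClass = featureClass)
}

#' @describeIn FeatureTable Number of rows.
#' @param object,x A `FeatureTable`.
#' @export
setMethod("nrow", "FeatureTable", function(x) nrow(x@features))

#' @describeIn FeatureTable Feature matrix accessor.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname FeatureTable
#' @export
setMethod("featureMatrix", "FeatureTable", function(object) object@features)

#' @describeIn FeatureTable Row key accessor.
#' @export
setGeneric("rowKeys", function(object) standardGeneric("rowKeys"))

#' @rdname FeatureTable
#' @export
setMethod("rowKeys", "FeatureTable", function(object) object@rowKeys)

#' @describeIn FeatureTable Response accessor.
#' @export
setGeneric("response", function(object) standardGeneric("response"))

#' @rdname FeatureTable
#' @export
setMethod("response", "FeatureTable", function(object) object@response)

#' @describeIn FeatureTable Per-column feature class accessor.
#' @export
setGeneric("featureClasses", function(object) standardGeneric("featureClasses"))

#' @rdname FeatureTable
#' @export
setMethod("featureClasses", "FeatureTable", function(object) object@featureClass)

# Row subsetting used by the cross-validation engine.
.subsetRows <- function(ft, idx) {
  new("FeatureTable",
      features = ft@features[idx, , drop = FALSE],
      rowKeys = ft@rowKeys[idx, , drop = FALSE],
      response = ft@response[idx],
      featureClass = ft@featureClass)
}

setMethod("show", "FeatureTable", function(object) {
  tab <- table(object@featureClass)
  cat(sprintf("FeatureTable: %d rows x %d features\n",
              nrow(object@features), ncol(object@features)))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## CorrelationRanking
## ---------------------------------------------------------------------------

#' @rdname correlateFeatures
#' @export
setClass("CorrelationRanking", representation(ranking = "data.frame"))

setValidity("CorrelationRanking", function(object) {
  r <- object@ranking
  msgs <- character(0)
  need <- c("feature", "class", "r", "zeroVariance", "rank")
  if (!all(need %in% colnames(r))) {
    msgs <- c(msgs, "ranking needs feature/class/r/zeroVariance/rank columns")
  } else {
    if (!identical(sort(r$rank), seq_len(nrow(r)))) {
      msgs <- c(msgs, "ranks must be a permutation of 1..n")
    }
    if (any(abs(r$r) > 1 + 1e-12)) msgs <- c(msgs, "|r| must be <= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn correlateFeatures Extract the ranking data.frame (ordered by
#'   rank).
#' @export
setGeneric("rankingTable", function(object) standardGeneric("rankingTable"))

#' @rdname correlateFeatures
#' @export
setMethod("rankingTable", "CorrelationRanking", function(object) {
  object@ranking[order(object@ranking$rank), , drop = FALSE]
})

setMethod("show", "CorrelationRanking", function(object) {
  r <- rankingTable(object)
  cat(sprintf("CorrelationRanking over %d features\n", nrow(r)))
  print(head(r, 5), row.names = FALSE)
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## InteractionNetwork
## ---------------------------------------------------------------------------

#' @rdname InteractionNetwork
#' @export
setClass("InteractionNetwork",
  representation(edges = "data.frame", nodes = "character"))

setValidity("InteractionNetwork", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!all(c("node_a", "node_b", "confidence") %in% colnames(e))) {
    msgs <- c(msgs, "edges needs node_a, node_b, confidence columns")
  } else {
    if (nrow(e) && (min(e$confidence) < 0 || max(e$confidence) > 1)) {
      msgs <- c(msgs, "confidence must lie in [0, 1]")
    }
    if (nrow(e) && any(e$node_a == e$node_b)) {
      msgs <- c(msgs, "self-edges are not allowed")
    }
    bad <- !(e$node_a %in% object@nodes) | !(e$node_b %in% object@nodes)
    if (any(bad)) msgs <- c(msgs, "edge endpoints must be in the node universe")
  }
  if (length(msgs)) msgs else TRUE
})

#' Protein/gene interaction network
#'
#' An undirected edge list with confidence scores in \[0, 1\] over a node
#' universe, mirroring a STRING-style interaction table after identifier
#' harmonization.
#'
#' @param edges data.frame with node_a, node_b, confidence.
#' @param nodes Character node universe.
#' @return An `InteractionNetwork`.
#' @seealso [filterNetwork()], [countInteractors()], [resampleNull()]
#' @export
InteractionNetwork <- function(edges, nodes) {
  new("InteractionNetwork", edges = edges, nodes = nodes)
}

#' @describeIn InteractionNetwork Edge list accessor.
#' @param object An `InteractionNetwork`.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname InteractionNetwork
#' @export
setMethod("networkEdges", "InteractionNetwork", function(object) object@edges)

#' @describeIn InteractionNetwork Node universe accessor.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork
#' @export
setMethod("networkNodes", "InteractionNetwork", function(object) object@nodes)

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## EnrichmentResult
## ---------------------------------------------------------------------------

#' @rdname resampleNull
#' @export
setClass("EnrichmentResult",
  representation(
    observedNInteracting = "integer",
    observedMeanInteractors = "numeric",
    nullNInteracting = "numeric",
    nullMeanInteractors = "numeric",
    percentileN = "numeric",
    percentileMean = "numeric",
    nDraws = "integer",
    seed = "integer",
    querySize = "integer"
  )
)

setValidity("EnrichmentResult", function(object) {
  msgs <- character(0)
  if (object@observedNInteracting < 0L ||
      object@observedNInteracting > object@querySize) {
    msgs <- c(msgs, "observed interacting count must be in [0, query size]")
  }
  for (s in c("percentileN", "percentileMean")) {
    v <- slot(object, s)
    if (v < 0 || v > 100) msgs <- c(msgs, sprintf("%s must be in [0, 100]", s))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult\n")
  cat(sprintf("  observed: %d/%d genes interacting, mean %.3f interactors\n",
              object@observedNInteracting, object@querySize,
              object@observedMeanInteractors))
  cat(sprintf("  percentiles vs %d null draws: n = %.1f, mean = %.1f\n",
              object@nDraws, object@percentileN, object@percentileMean))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## ModelSpec and CvResult
## ---------------------------------------------------------------------------

#' @rdname modelSpec
#' @export
setClass("ModelSpec",
  representation(
    family = "character",
    nFeatures = "integer",
    trees = "integer",
    mtry = "numeric",
    minNodeSize = "integer",
    seed = "integer",
    importanceMode = "character",
    r2Method = "character",
    includeDose = "logical"
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character(0)
  fam <- c("baseline_dose", "linear", "random_forest", "gradient_boosting")
  if (!object@family %in% fam) {
    msgs <- c(msgs, paste("family must be one of", paste(fam, collapse = ", ")))
  }
  if (object@nFeatures < 1L) msgs <- c(msgs, "nFeatures must be >= 1")
  if (!object@importanceMode %in% c("impurity", "permutation")) {
    msgs <- c(msgs, "importanceMode must be 'impurity' or 'permutation'")
  }
  if (!object@r2Method %in% c("pearson", "traditional")) {
    msgs <- c(msgs, "r2Method must be 'pearson' or 'traditional'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model specification
#'
#' Describes one model family and its hyperparameters. Families: a
#' feature-free dose-only baseline (training-set mean viability at each
#' concentration), ordinary least squares, random forest (ranger engine) and
#' gradient boosting (xgboost engine). The tree-count / predictors-per-split /
#' minimal-node-size defaults (500 / 22 / 5) follow the random-forest tuning
#' grid; when 22 exceeds the available feature count, predictors-per-split
#' falls back to the square-root heuristic.
#'
#' @param family One of "baseline_dose", "linear", "random_forest",
#'   "gradient_boosting".
#' @param nFeatures Top-k feature budget for in-fold correlation selection.
#' @param trees Number of trees (random forest) or boosting rounds.
#' @param mtry Predictors per split; `NA` means the default rule.
#' @param minNodeSize Minimal node size.
#' @param seed Model seed (separate from the fold seed).
#' @param importanceMode "impurity" or "permutation".
#' @param r2Method "pearson" (squared Pearson correlation) or "traditional"
#'   (coefficient of determination).
#' @param includeDose Append the raw concentration covariate to the design
#'   (it does not count toward `nFeatures`).
#' @return A `ModelSpec`.
#' @export
#' @examples
#' modelSpec("random_forest", nFeatures = 100)
modelSpec <- function(family = "random_forest", nFeatures = 500L,
                      trees = 500L, mtry = NA_real_, minNodeSize = 5L,
                      seed = 1L, importanceMode = "impurity",
                      r2Method = "pearson", includeDose = TRUE) {
  new("ModelSpec", family = family, nFeatures = as.integer(nFeatures),
      trees = as.integer(trees), mtry = as.numeric(mtry),
      minNodeSize = as.integer(minNodeSize), seed = as.integer(seed),
      importanceMode = importanceMode, r2Method = r2Method,
      includeDose = includeDose)
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s, k=%d, trees=%d, mtry=%s, minNodeSize=%d\n",
              object@family, object@nFeatures, object@trees,
              ifelse(is.na(object@mtry), "auto", object@mtry),
              object@minNodeSize))
  invisible(NULL)
})

#' @rdname crossValidate
#' @export
setClass("CvResult",
  representation(
    predictions = "numeric",
    observed = "numeric",
    rowKeys = "data.frame",
    folds = "integer",
    r2 = "numeric",
    rmse = "numeric",
    selectedFeatures = "list",
    spec = "ModelSpec"
  )
)

setValidity("CvResult", function(object) {
  msgs <- character(0)
  n <- length(object@predictions)
  if (length(object@observed) != n || nrow(object@rowKeys) != n ||
      length(object@folds) != n) {
    msgs <- c(msgs, "prediction count must equal row count")
  }
  if (object@rmse < 0) msgs <- c(msgs, "RMSE must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn crossValidate Out-of-fold predictions, in table row order.
#' @export
setGeneric("oofPredictions", function(object) standardGeneric("oofPredictions"))

#' @rdname crossValidate
#' @export
setMethod("oofPredictions", "CvResult", function(object) object@predictions)

#' @describeIn crossValidate Global metrics as c(r2 = , rmse = ).
#' @export
setGeneric("cvMetrics", function(object) standardGeneric("cvMetrics"))

#' @rdname crossValidate
#' @export
setMethod("cvMetrics", "CvResult", function(object) {
  c(r2 = object@r2, rmse = object@rmse)
})

#' @describeIn crossValidate Per-fold selected feature lists.
#' @export
setGeneric("foldSelections", function(object) standardGeneric("foldSelections"))

#' @rdname crossValidate
#' @export
setMethod("foldSelections", "CvResult", function(object) {
  object@selectedFeatures
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %s over %d rows in %d folds\n", object@spec@family,
              length(object@predictions), length(unique(object@folds))))
  cat(sprintf("  out-of-fold R^2 = %.4f, RMSE = %.4f\n", object@r2,
              object@rmse))
  invisible(NULL)
})
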