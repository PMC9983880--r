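# Design-matrix assembly, univariate correlation screening, top-k selection,
# selection-order curves and selection stability.

#' Assemble the modeling design matrix
#'
#' One row per (cell line, compound, concentration) with an imputed-viability
#' response. Inhibition columns (`act_*`) come from the dense profile at the
#' row's compound and concentration; omics columns are broadcast per cell
#' line. Only cell lines present in every requested omics class are kept —
#' rows for other cell lines are dropped with a log entry, as are rows whose
#' compound has no inhibition profile.
#'
#' @param viability data.frame from [imputeViability()].
#' @param profile A dense [KinaseInhibitionProfile].
#' @param omics A prefixed [OmicsBundle] (see [prefixFeatures()]).
#' @param classes Feature classes to include: subset of
#'   c("act", "exp", "cnv", "prot", "dep").
#' @param includeDose Append the raw concentration covariate (class
#'   "dose"); it never counts toward a selection budget.
#' @return A [FeatureTable].
#' @export
assembleDesign <- function(viability, profile, omics,
                           classes = c("act", "exp"), includeDose = TRUE) {
  stopifnot(is(profile, "KinaseInhibitionProfile"),
            is(omics, "OmicsBundle"))
  classes <- match.arg(classes, c("act", "exp", "cnv", "prot", "dep"),
                       several.ok = TRUE)
  omicsSlots <- c(exp = "expression", cnv = "cnv", prot = "proteomics",
                  dep = "dependency")
  usedOmics <- omicsSlots[intersect(classes, names(omicsSlots))]
  mats <- lapply(usedOmics, function(s) slot(omics, s))
  if (any(vapply(mats, is.null, logical(1)))) {
    stop("a requested omics class is absent from the bundle", call. = FALSE)
  }

  keepLines <- unique(viability$cell_line)
  for (m in mats) keepLines <- intersect(keepLines, rownames(m))
  droppedLines <- setdiff(unique(viability$cell_line), keepLines)
  if (length(droppedLines)) {
    .log("dropping %d cell lines absent from a requested omics class: %s",
         length(droppedLines), paste(droppedLines, collapse = ", "))
  }
  keepCompounds <- intersect(unique(viability$compound), compounds(profile))
  droppedCompounds <- setdiff(unique(viability$compound), keepCompounds)
  if (length(droppedCompounds)) {
    .log("dropping %d compounds without inhibition profiles",
         length(droppedCompounds))
  }
  rows <- viability[viability$cell_line %in% keepLines &
                    viability$compound %in% keepCompounds, , drop = FALSE]
  dIdx <- .doseIndex(rows$concentration, doseGrid(profile))
  if (any(dIdx < 0L)) {
    stop("viability record concentration not on the profile's dose grid",
         call. = FALSE)
  }

  blocks <- list()
  classVec <- character(0)
  if ("act" %in% classes) {
    arr <- intensityTensor(profile)
    cIdx <- match(rows$compound, compounds(profile))
    # Flatten (compound, dose) to a matrix over proteins, then index rows.
    flat <- matrix(arr, nrow = dim(arr)[1] * dim(arr)[2])
    act <- flat[(dIdx - 1L) * dim(arr)[1] + cIdx, , drop = FALSE]
    colnames(act) <- paste0("act_", proteins(profile))
    blocks$act <- act
    classVec <- c(classVec, setNames(rep("act", ncol(act)), colnames(act)))
  }
  for (cls in intersect(classes, names(omicsSlots))) {
    m <- mats[[cls]]
    if (anyNA(m[keepLines, , drop = FALSE])) {
      stop(sprintf(
        "omics class '%s' still contains missing values; impute or drop first",
        cls), call. = FALSE)
    }
    blk <- m[match(rows$cell_line, rownames(m)), , drop = FALSE]
    rownames(blk) <- NULL
    blocks[[cls]] <- blk
    classVec <- c(classVec, setNames(rep(cls, ncol(blk)), colnames(blk)))
  }
  X <- do.call(cbind, blocks)
  if (includeDose) {
    X <- cbind(X, concentration = rows$concentration)
    classVec <- c(classVec, concentration = "dose")
  }
  FeatureTable(features = X,
               rowKeys = data.frame(cell_line = rows$cell_line,
                                    compound = rows$compound,
                                    concentration = rows$concentration,
                                    stringsAsFactors = FALSE),
               response = rows$imputed_viability,
               featureClass = classVec)
}

#' Single-feature Pearson correlations with viability
#'
#' Computes each feature's Pearson correlation with the imputed-viability
#' response and ranks features for selection. Zero-variance features are
#' assigned r = 0 and flagged so the ranking stays a total permutation. The
#' concentration covariate (class "dose") is excluded from screening — it is
#' appended to models separately and never competes for the feature budget.
#'
#' @param table A [FeatureTable] with at least 3 rows.
#' @param signed Rank by signed r instead of |r|; the default ranks by
#'   absolute correlation so strong negative predictors are retained.
#' @return A `CorrelationRanking`.
#' @export
correlateFeatures <- function(table, signed = FALSE) {
  stopifnot(is(table, "FeatureTable"))
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  y <- response(table)
  if (sd(y) == 0) stop("zero-variance response", call. = FALSE)
  cls <- featureClasses(table)
  cols <- colnames(featureMatrix(table))
  cols <- cols[cls[cols] != "dose"]
  X <- featureMatrix(table)[, cols, drop = FALSE]
  sds <- apply(X, 2L, sd)
  r <- rep(0, ncol(X))
  names(r) <- colnames(X)
  nz <- sds > 0
  if (any(nz)) {
    r[nz] <- suppressWarnings(as.vector(cor(X[, nz, drop = FALSE], y)))
  }
  key <- if (signed) -r else -abs(r)
  ord <- order(key, colnames(X))
  ranking <- data.frame(
    feature = colnames(X),
    class = unname(featureClasses(table)[colnames(X)]),
    r = unname(r),
    zeroVariance = !nz,
    rank = NA_integer_,
    stringsAsFactors = FALSE)
  ranking$rank[ord] <- seq_len(nrow(ranking))
  new("CorrelationRanking", ranking = ranking)
}

#' Select the top-k features by correlation rank
#'
#' Features in correlation rank order (|r| descending by default, ties broken
#' by lexicographic feature name) are cut at `k`. Deterministic; the
#' selection for a smaller `k` is always a prefix of that for a larger `k`.
#'
#' @param ranking A `CorrelationRanking`.
#' @param k Number of features, 1 <= k <= number of ranked features.
#' @return Character vector of `k` feature names, in rank order.
#' @export
rankAndSelect <- function(ranking, k) {
  stopifnot(is(ranking, "CorrelationRanking"))
  tab <- rankingTable(ranking)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(tab) ||
      k != round(k)) {
    stop(sprintf("k must be an integer in [1, %d]", nrow(tab)),
         call. = FALSE)
  }
  tab$feature[seq_len(k)]
}

#' Selection-order curves per feature class
#'
#' For each rank cutoff 1..`maxRank`, counts how many selected features come
#' from each class and what percentage of that class has been selected —
#' showing which class dominates the top of the correlation ranking and
#' where the switch to the next class happens.
#'
#' @param ranking A `CorrelationRanking`.
#' @param maxRank Largest cutoff to tabulate (default: all features).
#' @return data.frame with rank, class, count, percent; counts at a cutoff
#'   sum to the cutoff across classes.
#' @export
selectionOrderCurves <- function(ranking, maxRank = NULL) {
  stopifnot(is(ranking, "CorrelationRanking"))
  tab <- rankingTable(ranking)
  if (is.null(maxRank)) maxRank <- nrow(tab)
  stopifnot(maxRank >= 0, maxRank <= nrow(tab))
  classes <- sort(unique(tab$class))
  classSize <- table(tab$class)
  if (maxRank == 0) {
    return(data.frame(rank = integer(0), class = character(0),
                      count = integer(0), percent = numeric(0)))
  }
  out <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    cum <- cumsum(tab$class[seq_len(maxRank)] == cls)
    out[[i]] <- data.frame(
      rank = seq_len(maxRank), class = cls, count = cum,
      percent = 100 * cum / classSize[[cls]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stability of feature selection across folds
#'
#' The fraction of the union of per-fold selections that is present in every
#' fold, plus each feature's fold-inclusion percentage.
#'
#' @param perFoldSelections List (>= 2) of character vectors of selected
#'   features.
#' @return List with `stability` (|intersection| / |union|) and `perFeature`
#'   (data.frame feature, inclusion_percent).
#' @export
selectionStability <- function(perFoldSelections) {
  stopifnot(is.list(perFoldSelections), length(perFoldSelections) >= 2L)
  union <- Reduce(union, perFoldSelections)
  inter <- Reduce(intersect, perFoldSelections)
  counts <- table(unlist(lapply(perFoldSelections, unique)))
  perFeature <- data.frame(
    feature = names(counts),
    inclusion_percent = 100 * as.vector(counts) / length(perFoldSelections),
    stringsAsFactors = FALSE)
  perFeature <- perFeature[order(-perFeature$inclusion_percent,
                                 perFeature$feature), , drop = FALSE]
  rownames(perFeature) <- NULL
  stability <- if (length(union)) length(inter) / length(union) else 1
  list(stability = stability, perFeature = perFeature)
}

#' Pick each compound's maximum-variance dose
#'
#' For single-dose modeling, selects per compound the grid concentration with
#' the highest across-cell-line variance in imputed viability; ties go to
#' the lower concentration. Compounds observed in fewer than two cell lines
#' are excluded with a log entry.
#'
#' @param viability data.frame from [imputeViability()].
#' @return Named numeric vector, compound -> concentration (molar).
#' @export
pickMaxVarianceDose <- function(viability) {
  stopifnot(all(c("cell_line", "compound", "concentration",
                  "imputed_viability") %in% colnames(viability)))
  out <- numeric(0)
  for (j in unique(viability$compound)) {
    sub <- viability[viability$compound == j, , drop = FALSE]
    if (length(unique(sub$cell_line)) < 2L) {
      .log("compound %s has < 2 cell lines; excluded from dose picking", j)
      next
    }
    doses <- sort(unique(sub$concentration))
    vars <- vapply(doses, function(x) {
      var(sub$imputed_viability[sub$concentration == x])
    }, numeric(1))
    out[j] <- doses[which.max(vars)]  # which.max takes the first (lowest) tie
  }
  out
}
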