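# Cleaning rules for sparse inhibition records and baseline omics matrices.

#' Densify sparse inhibition records
#'
#' Builds the dense compound x concentration x protein tensor from a sparse
#' record table. Proteins never recorded for a compound are unaffected by it
#' and receive the default relative intensity of exactly 1. For (compound,
#' protein) pairs that do have records, concentrations absent from the
#' records are left `NA` — they are the single-concentration gaps that
#' [imputeMissingConcentrations()] fills next.
#'
#' @param records data.frame with compound, protein, concentration,
#'   relative_intensity.
#' @param compounds Compound universe (character).
#' @param proteins Protein universe (character).
#' @param doseGrid Molar concentration grid; record concentrations must match
#'   grid members exactly (after decimal canonicalization).
#' @return A [KinaseInhibitionProfile] possibly containing `NA` gap cells.
#' @export
#' @examples
#' rec <- data.frame(compound = "c1", protein = "p1",
#'                   concentration = 1e-6, relative_intensity = 0.3)
#' prof <- densifyInhibition(rec, "c1", c("p1", "p2"), c(1e-7, 1e-6))
#' intensityTensor(prof)
densifyInhibition <- function(records, compounds, proteins, doseGrid) {
  stopifnot(all(c("compound", "protein", "concentration",
                  "relative_intensity") %in% colnames(records)))
  doseGrid <- as.numeric(doseGrid)
  nC <- length(compounds); nD <- length(doseGrid); nP <- length(proteins)
  arr <- array(1, dim = c(nC, nD, nP),
               dimnames = list(compounds, .doseKey(doseGrid), proteins))
  if (nrow(records)) {
    dIdx <- .doseIndex(records$concentration, doseGrid)
    if (any(dIdx < 0L)) {
      bad <- which(dIdx < 0L)[1]
      stop(sprintf(
        "record %d (%s, %s, %g M) has a concentration not on the dose grid",
        bad, records$compound[bad], records$protein[bad],
        records$concentration[bad]), call. = FALSE)
    }
    cIdx <- match(records$compound, compounds)
    pIdx <- match(records$protein, proteins)
    if (anyNA(cIdx) || anyNA(pIdx)) {
      stop("record refers to a compound or protein outside the universe",
           call. = FALSE)
    }
    # Any pair with records is an affected protein: mark its whole series
    # missing, then fill the recorded cells; leftover NAs are the gaps.
    pairs <- unique(cbind(cIdx, pIdx))
    for (d in seq_len(nD)) {
      arr[cbind(pairs[, 1L], d, pairs[, 2L])] <- NA_real_
    }
    arr[cbind(cIdx, dIdx, pIdx)] <- records$relative_intensity
  }
  KinaseInhibitionProfile(arr, doseGrid)
}

#' Fill single-concentration gaps by neighbor averaging
#'
#' Interior missing cells in a (compound, protein) series become the mean of
#' the two nearest concentrations' values; a missing cell at a grid end takes
#' its single nearest neighbor's value. Two adjacent missing cells violate
#' the single-concentration-gap premise and raise an error.
#'
#' @param profile A [KinaseInhibitionProfile] from [densifyInhibition()].
#' @return The profile with no missing cells.
#' @export
imputeMissingConcentrations <- function(profile) {
  stopifnot(is(profile, "KinaseInhibitionProfile"))
  arr <- profile@intensity
  nD <- dim(arr)[2]
  naIdx <- which(is.na(arr), arr.ind = TRUE)
  if (nrow(naIdx) == 0L) return(profile)
  series <- unique(naIdx[, c(1L, 3L), drop = FALSE])
  nFilled <- 0L
  for (i in seq_len(nrow(series))) {
    ci <- series[i, 1L]; pi <- series[i, 2L]
    v <- arr[ci, , pi]
    miss <- which(is.na(v))
    if (any(diff(miss) == 1L)) {
      stop(sprintf(
        "adjacent missing concentrations for compound '%s', protein '%s'",
        dimnames(arr)[[1]][ci], dimnames(arr)[[3]][pi]), call. = FALSE)
    }
    for (m in miss) {
      v[m] <- if (m == 1L) {
        v[2L]
      } else if (m == nD) {
        v[nD - 1L]
      } else {
        (v[m - 1L] + v[m + 1L]) / 2
      }
    }
    arr[ci, , pi] <- v
    nFilled <- nFilled + length(miss)
  }
  .log("filled %d single-concentration gaps", nFilled)
  out <- KinaseInhibitionProfile(arr, profile@doseGrid)
  attr(out, "nFilled") <- nFilled
  out
}

#' Truncate outlier intensities at a global percentile
#'
#' Computes the given percentile (linear-interpolation quantile) over the
#' entire dense tensor — all compounds, concentrations and proteins pooled —
#' and caps every value above it at that threshold, mirroring the single
#' global truncation value applied to real kinobead tables.
#'
#' @param profile A dense [KinaseInhibitionProfile] (no missing cells).
#' @param percentile Percentile in (0, 100\]; default 99.99.
#' @param threshold Optional precomputed threshold (e.g. a percentile taken
#'   over the sparse records before default-one filling); overrides
#'   `percentile`.
#' @return List with `profile` (truncated) and `threshold` (the computed
#'   percentile value).
#' @export
truncateOutliers <- function(profile, percentile = 99.99, threshold = NULL) {
  stopifnot(is(profile, "KinaseInhibitionProfile"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100) {
    stop("percentile must lie in (0, 100]", call. = FALSE)
  }
  arr <- profile@intensity
  if (anyNA(arr)) {
    stop("profile still contains missing cells; impute gaps first",
         call. = FALSE)
  }
  thr <- if (is.null(threshold)) {
    unname(quantile(arr, percentile / 100, type = 7))
  } else {
    threshold
  }
  nTrunc <- sum(arr > thr)
  arr[arr > thr] <- thr
  .log("truncated %d values above the %.2f percentile (%.4g)",
       nTrunc, percentile, thr)
  out <- KinaseInhibitionProfile(arr, profile@doseGrid)
  attr(out, "nTruncated") <- nTrunc
  list(profile = out, threshold = thr)
}

#' Prefix omics feature labels by class
#'
#' Adds a class identifier to every gene/protein label (`exp_`, `cnv_`,
#' `prot_`, `dep_`) so measurements of the same gene from different omics
#' classes are never accidentally combined.
#'
#' @param bundle An [OmicsBundle] with raw labels.
#' @return The bundle with prefixed column names.
#' @export
#' @examples
#' b <- OmicsBundle(expression = matrix(1, 1, 1,
#'                                      dimnames = list("CL1", "TP53")))
#' colnames(omicsMatrix(prefixFeatures(b), "expression"))
prefixFeatures <- function(bundle) {
  stopifnot(is(bundle, "OmicsBundle"))
  prefixes <- c(expression = "exp_", cnv = "cnv_", proteomics = "prot_",
                dependency = "dep_")
  out <- bundle
  for (s in names(prefixes)) {
    m <- slot(bundle, s)
    if (is.null(m)) next
    if (anyDuplicated(colnames(m))) {
      stop(sprintf("duplicate feature label within '%s'", s), call. = FALSE)
    }
    pre <- prefixes[[s]]
    cn <- colnames(m)
    already <- startsWith(cn, pre)
    colnames(m) <- ifelse(already, cn, paste0(pre, cn))
    slot(out, s) <- m
  }
  validObject(out)
  out
}

#' Impute missing proteomics readings
#'
#' A missing reading for a protein becomes the minimum of that protein's
#' observed distribution minus one standard deviation, placing imputed
#' values just below the detection range. Columns with fewer than two
#' observed values (no defined sd) are dropped and logged.
#'
#' @param matrix Cell line x protein matrix with possible `NA` entries.
#' @return The imputed matrix; dropped column names are attached as the
#'   `"droppedColumns"` attribute.
#' @export
imputeProteomics <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (all(is.na(matrix))) stop("all proteomics readings are missing",
                               call. = FALSE)
  nObs <- colSums(!is.na(matrix))
  drop <- colnames(matrix)[nObs < 2L]
  if (length(drop)) {
    .log("dropping %d proteomics columns with < 2 observed values",
         length(drop))
    matrix <- matrix[, nObs >= 2L, drop = FALSE]
  }
  for (p in seq_len(ncol(matrix))) {
    col <- matrix[, p]
    miss <- is.na(col)
    if (!any(miss)) next
    obs <- col[!miss]
    matrix[miss, p] <- min(obs) - sd(obs)
  }
  attr(matrix, "droppedColumns") <- drop
  matrix
}

#' Drop cell lines with incomplete measurements
#'
#' Removes every row (cell line) containing at least one missing entry,
#' mirroring the filter applied to CRISPR-KO dependency matrices.
#'
#' @param matrix Cell line x feature matrix.
#' @return The complete-rows matrix; removed row names are attached as the
#'   `"droppedLines"` attribute.
#' @export
dropIncompleteLines <- function(matrix) {
  stopifnot(is.matrix(matrix))
  keep <- complete.cases(matrix)
  dropped <- rownames(matrix)[!keep]
  if (length(dropped)) {
    .log("dropping %d incomplete cell lines: %s", length(dropped),
         paste(dropped, collapse = ", "))
  }
  out <- matrix[keep, , drop = FALSE]
  attr(out, "droppedLines") <- dropped
  out
}

#' Run the full inhibition preprocessing chain
#'
#' Densify, fill gaps, truncate: the published cleaning order for sparse
#' kinobead records.
#'
#' @inheritParams densifyInhibition
#' @inheritParams truncateOutliers
#' @param percentileScope "dense" computes the truncation percentile over
#'   the densified tensor (default-one cells included); "records" computes
#'   it over the recorded intensities only, before filling.
#' @return List with `profile` and `threshold` as in [truncateOutliers()].
#' @export
preprocessInhibition <- function(records, compounds, proteins, doseGrid,
                                 percentile = 99.99,
                                 percentileScope = c("dense", "records")) {
  percentileScope <- match.arg(percentileScope)
  prof <- densifyInhibition(records, compounds, proteins, doseGrid)
  prof <- imputeMissingConcentrations(prof)
  thr <- if (percentileScope == "records") {
    unname(quantile(records$relative_intensity, percentile / 100, type = 7))
  } else {
    NULL
  }
  truncateOutliers(prof, percentile, threshold = thr)
}
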