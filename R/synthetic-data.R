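# Synthetic study generator: produces every pipeline input with known ground
# truth so each downstream stage can be tested against planted signal.

.cellLineNames <- function(config) sprintf("CL%03d", seq_len(config@nCellLines))
.compoundNames <- function(config) sprintf("CMP%03d", seq_len(config@nCompounds))
.proteinNames <- function(config) sprintf("PRT%03d", seq_len(config@nProteins))
.geneNames <- function(config) sprintf("GEN%04d", seq_len(config@nGenes))

# Per-compound target curves: one slope per compound shared by its targets,
# one potency per (compound, protein). The planted viability signal then has
# an exact four-parameter log-logistic shape (the lower envelope of
# equal-slope logistics is the most potent target's curve), so the
# generator's curve fits are well-posed.
.targetCurves <- function(config) {
  .withSeed(config@seed + 11L, {
    grid <- config@doseGrid
    compoundIds <- .compoundNames(config)
    proteinIds <- .proteinNames(config)
    out <- vector("list", length(compoundIds))
    for (j in seq_along(compoundIds)) {
      slope <- runif(1, 1.0, 2.5)
      tp <- sample(proteinIds, config@targetsPerCompound)
      # Compounds differ broadly in potency (centers spanning beyond the
      # grid on both sides); a compound's targets cluster around its center.
      center <- exp(runif(1, log(min(grid) * 3), log(max(grid) * 3)))
      potency <- center * exp(runif(length(tp), -1, 1))
      out[[j]] <- data.frame(compound = compoundIds[j], protein = tp,
                             slope = slope, potency = potency,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# Sigmoid intensity of a target at concentration x: 0.5 at the potency.
.targetIntensity <- function(x, slope, potency) {
  1 / (1 + exp(slope * (log(x) - log(potency))))
}

# Planted driver-gene sets: deterministic for a given config so the
# dose-response and network generators agree without sharing state.
# Compounds draw their drivers from a shared pool (3x the per-compound set
# size), mirroring recurrent sensitivity pathways: related inhibitors share
# resistance/sensitivity genes rather than each having a private set.
.driverSets <- function(config) {
  .withSeed(config@seed + 31L, {
    genes <- .geneNames(config)
    poolSize <- min(config@nGenes, 3L * config@nDriverGenes)
    pool <- sample(genes, poolSize)
    sets <- lapply(seq_len(config@nCompounds), function(j) {
      sort(sample(pool, config@nDriverGenes))
    })
    names(sets) <- .compoundNames(config)
    sets
  })
}

#' Generate sparse kinase-inhibition records
#'
#' Emulates a kinobead-style supplementary table: only the proteins affected
#' by a compound appear, with relative intensity decreasing along the dose
#' grid following a log-logistic curve per (compound, target). A fraction
#' `gapRate` of interior single-concentration values is withheld (never two
#' adjacent in one series, matching the isolated-gap premise of neighbor
#' imputation), and a fraction `outlierRate` of recorded values is inflated
#' by a factor in (3, 6\].
#'
#' @param config A [syntheticConfig()].
#' @return List with `records` (data.frame compound, protein, concentration,
#'   relative_intensity) and `targets` (data.frame compound, protein, slope,
#'   potency — the planted curve truth).
#' @export
#' @examples
#' gen <- generateInhibitionRecords(syntheticConfig(nCompounds = 3, seed = 2))
#' head(gen$records)
generateInhibitionRecords <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  if (config@gapRate >= 0.5) {
    stop("gapRate >= 0.5 would break the isolated-gap assumption of ",
         "neighbor imputation", call. = FALSE)
  }
  targets <- .targetCurves(config)
  grid <- config@doseGrid
  nD <- length(grid)
  .withSeed(config@seed + 12L, {
    pieces <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      vals <- .targetIntensity(grid, targets$slope[i], targets$potency[i])
      keep <- rep(TRUE, nD)
      if (nD > 2L && config@gapRate > 0) {
        for (k in 2:(nD - 1L)) {
          if (keep[k - 1L] && runif(1) < config@gapRate) keep[k] <- FALSE
        }
      }
      if (config@outlierRate > 0) {
        hit <- runif(nD) < config@outlierRate
        vals[hit] <- vals[hit] * runif(sum(hit), 3, 6)
      }
      pieces[[i]] <- data.frame(
        compound = targets$compound[i], protein = targets$protein[i],
        concentration = grid[keep], relative_intensity = vals[keep],
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, pieces)
    rownames(records) <- NULL
    list(records = records, targets = targets)
  })
}

#' Generate baseline omics matrices
#'
#' Gene expression on the log2(TPM+1) scale (non-negative), gene-level copy
#' number, proteomics log-intensities with planted missing readings, and
#' CRISPR-KO dependency scores with a few planted incomplete cell lines (to
#' exercise [dropIncompleteLines()]). Driver-gene expression is what the
#' dose-response generator later turns into planted sensitivity, so it
#' correlates with sensitivity by construction.
#'
#' @param config A [syntheticConfig()].
#' @param proteomicsMissingRate Fraction of proteomics readings withheld.
#' @param incompleteLineFraction Fraction of cell lines given missing
#'   dependency scores.
#' @return An [OmicsBundle].
#' @export
generateOmics <- function(config, proteomicsMissingRate = 0.15,
                          incompleteLineFraction = 0.05) {
  stopifnot(is(config, "SyntheticConfig"))
  .withSeed(config@seed + 13L, {
    lines <- .cellLineNames(config)
    genes <- .geneNames(config)
    prots <- .proteinNames(config)
    nL <- length(lines); nG <- length(genes); nP <- length(prots)

    mu <- runif(nG, 2, 8)
    expr <- matrix(pmax(0, rnorm(nL * nG, mean = rep(mu, each = nL),
                                 sd = 1.2)),
                   nrow = nL, dimnames = list(lines, genes))
    cnv <- matrix(rnorm(nL * nG, 0, 0.3), nrow = nL,
                  dimnames = list(lines, genes))
    prot <- matrix(rnorm(nL * nP, 6, 1), nrow = nL,
                   dimnames = list(lines, prots))
    if (proteomicsMissingRate > 0) {
      prot[runif(nL * nP) < proteomicsMissingRate] <- NA_real_
    }
    dep <- matrix(rnorm(nL * nG, 0, 0.4), nrow = nL,
                  dimnames = list(lines, genes))
    nBad <- if (incompleteLineFraction > 0) {
      max(1L, floor(incompleteLineFraction * nL))
    } else 0L
    if (nBad > 0) {
      badLines <- sample(nL, nBad)
      for (l in badLines) dep[l, sample(nG, max(1L, nG %/% 20))] <- NA_real_
    }
    OmicsBundle(expression = expr, cnv = cnv, proteomics = prot,
                dependency = dep)
  })
}

# LL.4 fit of one viability series over the dose grid; multi-start nonlinear
# least squares on log-concentration. Returns c(b, c, d, e) or NULL.
.fitLL4 <- function(doses, v) {
  if (sd(v) < 1e-9) {
    # Flat series: c = d = level makes the slope irrelevant; exact fit.
    lev <- unname(v[1])
    return(c(b = 1, c = lev, d = lev, e = exp(median(log(doses)))))
  }
  lx <- log(doses)
  loge0 <- median(lx)
  best <- NULL
  bestSse <- Inf
  for (b0 in c(1, 0.5, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ cc + (dd - cc) / (1 + exp(b * (lx - loge))),
        start = list(b = b0, cc = min(v), dd = max(v), loge = loge0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (sse < bestSse) {
      bestSse <- sse
      best <- coef(fit)
    }
  }
  if (is.null(best)) return(NULL)
  out <- c(b = unname(best["b"]), c = unname(best["cc"]),
           d = unname(best["dd"]), e = exp(unname(best["loge"])))
  if (any(!is.finite(out)) || out["e"] <= 0) return(NULL)
  out
}

#' Generate dose-response parameters with ground truth
#'
#' True viability of cell line l under compound j at concentration x is
#' `V = 1 - s(l,j) * (1 - min_p I(j,p,x))`, the minimum running over the
#' compound's planted targets; sensitivity `s(l,j)` is a logistic function of
#' the cell line's mean driver-gene expression (standardized per compound),
#' keeping viability bounded in \[0, 1\]. Gaussian noise of sd `noiseSd` is
#' added before fitting a four-parameter log-logistic curve per combination;
#' a planted fraction of combinations instead receives an increasing
#' (growth-enhancing) curve to exercise the growth filter.
#'
#' @param config A [syntheticConfig()].
#' @param inhibition Output of [generateInhibitionRecords()] for `config`.
#' @param omics Output of [generateOmics()] for `config`.
#' @param sensitivity Optional override: a scalar or (cell line x compound)
#'   matrix of sensitivities in \[0, 1\], replacing the expression-linked
#'   values (used to probe limiting cases).
#' @return List with `params` (data.frame cell_line, compound, b, c, d, e),
#'   `truth` (a [GroundTruth]) and `dropped` (combinations whose curve fit
#'   failed, logged and omitted from `params`).
#' @export
generateDoseResponse <- function(config, inhibition, omics,
                                 sensitivity = NULL) {
  stopifnot(is(config, "SyntheticConfig"), is(omics, "OmicsBundle"))
  targets <- inhibition$targets
  grid <- config@doseGrid
  lines <- .cellLineNames(config)
  compoundIds <- .compoundNames(config)
  nL <- length(lines); nJ <- length(compoundIds); nD <- length(grid)

  drivers <- .driverSets(config)
  expr <- omicsMatrix(omics, "expression")

  # Sensitivity in [0, 1] via a logistic link on standardized driver-mean
  # expression (per compound).
  if (is.null(sensitivity)) {
    sens <- matrix(NA_real_, nL, nJ, dimnames = list(lines, compoundIds))
    for (j in seq_len(nJ)) {
      # weighted driver expression: the first driver dominates (a marker
      # gene), later drivers modulate — geometric weights
      dg <- drivers[[j]]
      w <- 4^-(seq_along(dg) - 1)
      m <- as.vector(expr[lines, dg, drop = FALSE] %*% (w / sum(w)))
      z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, nL)
      sens[, j] <- plogis(z)
    }
  } else if (is.matrix(sensitivity)) {
    sens <- sensitivity
  } else {
    sens <- matrix(sensitivity, nL, nJ, dimnames = list(lines, compoundIds))
  }

  # Minimum planted-target intensity per (compound, dose).
  minI <- matrix(1, nJ, nD, dimnames = list(compoundIds, NULL))
  for (i in seq_len(nrow(targets))) {
    vals <- .targetIntensity(grid, targets$slope[i], targets$potency[i])
    j <- targets$compound[i]
    minI[j, ] <- pmin(minI[j, ], vals)
  }

  trueV <- array(NA_real_, dim = c(nL, nJ, nD),
                 dimnames = list(lines, compoundIds, .doseKey(grid)))
  for (j in seq_len(nJ)) {
    trueV[, j, ] <- outer(sens[, j], 1 - minI[j, ],
                          function(s, eff) 1 - s * eff)
  }

  .withSeed(config@seed + 17L, {
    combos <- expand.grid(cell_line = lines, compound = compoundIds,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    nCombos <- nrow(combos)
    nGrowth <- floor(config@growthFraction * nCombos)
    growthIdx <- if (nGrowth > 0) sort(sample(nCombos, nGrowth)) else integer(0)

    params <- vector("list", nCombos)
    dropped <- list()
    for (i in seq_len(nCombos)) {
      l <- combos$cell_line[i]; j <- combos$compound[i]
      if (i %in% growthIdx) {
        # Increasing curve: with b < 0 the curve runs from c (low dose) up
        # to d (high dose).
        params[[i]] <- data.frame(
          cell_line = l, compound = j,
          b = -runif(1, 0.5, 1.5), c = 1, d = runif(1, 1.05, 1.2),
          e = exp(runif(1, log(min(grid) * 10), log(max(grid) / 10))),
          stringsAsFactors = FALSE)
        next
      }
      v <- trueV[l, j, ] + rnorm(nD, 0, config@noiseSd)
      fit <- .fitLL4(grid, v)
      if (is.null(fit)) {
        .log("curve fit failed for %s / %s; combination dropped", l, j)
        dropped[[length(dropped) + 1L]] <- data.frame(
          cell_line = l, compound = j, stringsAsFactors = FALSE)
        next
      }
      params[[i]] <- data.frame(cell_line = l, compound = j,
                                b = fit["b"], c = fit["c"], d = fit["d"],
                                e = fit["e"], stringsAsFactors = FALSE)
    }
    paramTab <- do.call(rbind, params[!vapply(params, is.null, logical(1))])
    rownames(paramTab) <- NULL
    droppedTab <- if (length(dropped)) do.call(rbind, dropped) else
      data.frame(cell_line = character(0), compound = character(0))

    targetSets <- split(targets$protein, targets$compound)[compoundIds]
    truth <- GroundTruth(
      targetSets = targetSets, driverGenes = drivers, sensitivity = sens,
      trueViability = trueV, growthCombos = combos[growthIdx, , drop = FALSE])
    list(params = paramTab, truth = truth, dropped = droppedTab)
  })
}

#' Generate a synthetic interaction network
#'
#' Background edges among all node pairs (genes plus proteins) are placed
#' independently with probability `p0`; pairs linking a compound's planted
#' driver genes to its planted target proteins are placed with probability
#' `p0 * enrichmentStrength` instead (capped at 1), planting detectable
#' enrichment when the strength exceeds 1. Confidence scores are uniform on
#' \[0.4, 1\].
#'
#' @param config A [syntheticConfig()].
#' @param p0 Background edge probability.
#' @param enrichmentStrength Multiplier on `p0` for driver-target pairs; 1
#'   yields a null network.
#' @param driverEdgeProb Optional absolute probability for driver-target
#'   pairs, overriding `p0 * enrichmentStrength` (used for degenerate
#'   limits such as forcing every driver edge).
#' @return An [InteractionNetwork] over the gene + protein universe.
#' @export
generateNetwork <- function(config, p0 = 0.02, enrichmentStrength = 1,
                            driverEdgeProb = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  nodes <- c(.geneNames(config), .proteinNames(config))
  targets <- .targetCurves(config)
  drivers <- .driverSets(config)
  targetSets <- split(targets$protein, targets$compound)

  boosted <- unique(do.call(rbind, lapply(names(drivers), function(j) {
    ts <- targetSets[[j]]
    if (is.null(ts)) return(NULL)
    expand.grid(node_a = drivers[[j]], node_b = ts,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })))
  pBoost <- if (is.null(driverEdgeProb)) min(1, p0 * enrichmentStrength) else
    driverEdgeProb

  .withSeed(config@seed + 23L, {
    n <- length(nodes)
    pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairA <- nodes[pairIdx[, 1L]]
    pairB <- nodes[pairIdx[, 2L]]
    # Boosted pairs are gene x protein; genes precede proteins in `nodes`,
    # so node_a = gene, node_b = protein orientation matches upper.tri.
    key <- paste(pairA, pairB, sep = "\r")
    boostKey <- if (is.null(boosted)) character(0) else
      paste(boosted$node_a, boosted$node_b, sep = "\r")
    p <- ifelse(key %in% boostKey, pBoost, p0)
    drawn <- runif(length(p)) < p
    edges <- data.frame(node_a = pairA[drawn], node_b = pairB[drawn],
                        confidence = runif(sum(drawn), 0.4, 1.0),
                        stringsAsFactors = FALSE)
    InteractionNetwork(edges = edges, nodes = nodes)
  })
}

#' Generate a kinase annotation table
#'
#' Classifies each protein in the synthetic universe as a non-kinase or as a
#' well-studied ("light") or understudied ("dark") kinase, mirroring curated
#' kinome annotations. Roughly half the universe is kinase, a third of which
#' is dark.
#'
#' @param config A [syntheticConfig()].
#' @return data.frame with columns protein, is_kinase, class
#'   ("dark kinase" / "light kinase" / "non-kinase").
#' @export
generateKinaseAnnotation <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  .withSeed(config@seed + 29L, {
    prots <- .proteinNames(config)
    isKinase <- runif(length(prots)) < 0.5
    dark <- isKinase & runif(length(prots)) < 1 / 3
    data.frame(
      protein = prots, is_kinase = isKinase,
      class = ifelse(!isKinase, "non-kinase",
                     ifelse(dark, "dark kinase", "light kinase")),
      stringsAsFactors = FALSE)
  })
}

#' Generate every pipeline input for one synthetic study
#'
#' Convenience wrapper running all generators with a shared config.
#'
#' @param config A [syntheticConfig()].
#' @param networkStrength Enrichment strength passed to [generateNetwork()].
#' @param networkP0 Background edge probability for the network.
#' @return List with elements `config`, `inhibition` (records + planted
#'   targets), `omics`, `doseResponse` (params + truth + dropped), `network`
#'   and `annotation`.
#' @export
#' @examples
#' study <- generateSyntheticStudy(syntheticConfig(nCellLines = 5,
#'                                                 nCompounds = 3,
#'                                                 nProteins = 20,
#'                                                 nGenes = 30, seed = 4))
#' names(study)
generateSyntheticStudy <- function(config = syntheticConfig(),
                                   networkStrength = 6, networkP0 = 0.02) {
  inhibition <- generateInhibitionRecords(config)
  omics <- generateOmics(config)
  doseResponse <- generateDoseResponse(config, inhibition, omics)
  network <- generateNetwork(config, p0 = networkP0,
                             enrichmentStrength = networkStrength)
  annotation <- generateKinaseAnnotation(config)
  list(config = config, inhibition = inhibition, omics = omics,
       doseResponse = doseResponse, network = network,
       annotation = annotation)
}

#' Simulate a plate-reader viability experiment
#'
#' Produces raw luminescence wells for a set of (cell line, compound)
#' treatments over a dose grid, with DMSO-only control wells on each plate
#' row, multiplicative per-row gain and optional measurement noise. The
#' generating relative-viability factors are returned so plate normalization
#' can be checked exactly.
#'
#' @param viability data.frame with cell_line, compound, concentration,
#'   viability (the generating relative viability per treated well).
#' @param nControls DMSO control wells per plate row.
#' @param nReplicates Replicate treated wells per condition.
#' @param baseSignal Mean control luminescence.
#' @param noiseSd Multiplicative log-normal noise sd on treated wells (0
#'   gives exact recovery).
#' @param seed Integer seed.
#' @return List with `measurements` (long well table; control wells carry
#'   compound "DMSO" and NA concentration) and `truth` (the input factors).
#' @export
simulatePlateMeasurements <- function(viability, nControls = 4L,
                                      nReplicates = 2L, baseSignal = 1e5,
                                      noiseSd = 0, seed = 1L) {
  stopifnot(all(c("cell_line", "compound", "concentration", "viability") %in%
                colnames(viability)))
  .withSeed(seed, {
    rows <- unique(viability[, c("cell_line", "compound")])
    rows$row_id <- sprintf("row%03d", seq_len(nrow(rows)))
    wells <- list()
    for (i in seq_len(nrow(rows))) {
      gain <- baseSignal * runif(1, 0.7, 1.3)
      sub <- viability[viability$cell_line == rows$cell_line[i] &
                       viability$compound == rows$compound[i], , drop = FALSE]
      ctrl <- data.frame(
        row_id = rows$row_id[i], cell_line = rows$cell_line[i],
        compound = "DMSO", concentration = NA_real_,
        replicate = seq_len(nControls), signal = gain,
        stringsAsFactors = FALSE)
      trt <- do.call(rbind, lapply(seq_len(nReplicates), function(r) {
        noise <- if (noiseSd > 0) exp(rnorm(nrow(sub), 0, noiseSd)) else 1
        data.frame(
          row_id = rows$row_id[i], cell_line = rows$cell_line[i],
          compound = sub$compound, concentration = sub$concentration,
          replicate = r, signal = gain * sub$viability * noise,
          stringsAsFactors = FALSE)
      }))
      wells[[i]] <- rbind(ctrl, trt)
    }
    measurements <- do.call(rbind, wells)
    rownames(measurements) <- NULL
    list(measurements = measurements, truth = viability)
  })
}
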