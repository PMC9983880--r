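# The generator must plant exactly the advertised structure: target-only
# sparse records, expression-linked sensitivity, recoverable LL.4 curves and
# a network with controllable enrichment.

test_that("config validity rejects degenerate study dimensions", {
  expect_error(syntheticConfig(nGenes = 0), "count")
  expect_error(syntheticConfig(doseGrid = c(1e-6, 1e-7)), "increasing")
  expect_error(syntheticConfig(gapRate = 1.5), "rates|\\[0, 1\\]")
  expect_error(generateInhibitionRecords(tinyConfig(gapRate = 0.6)),
               "gapRate")
})

test_that("inhibition records cover exactly the planted target pairs and are deterministic", {
  cfg <- tinyConfig(seed = 11, gapRate = 0, outlierRate = 0)
  gen1 <- generateInhibitionRecords(cfg)
  gen2 <- generateInhibitionRecords(cfg)
  expect_identical(gen1, gen2)

  rec <- gen1$records
  # no injected anomalies: all intensities in (0, 1]
  expect_true(all(rec$relative_intensity > 0 & rec$relative_intensity <= 1))
  pairs <- unique(rec[, c("compound", "protein")])
  expect_identical(nrow(pairs),
                   cfg@nCompounds * cfg@targetsPerCompound)
  # only planted targets appear
  planted <- unique(gen1$targets[, c("compound", "protein")])
  expect_setequal(paste(pairs$compound, pairs$protein),
                  paste(planted$compound, planted$protein))
  # intensities decrease with concentration within each target series
  for (i in sample(nrow(planted), 5)) {
    sub <- rec[rec$compound == planted$compound[i] &
               rec$protein == planted$protein[i], ]
    sub <- sub[order(sub$concentration), ]
    expect_true(all(diff(sub$relative_intensity) < 0))
  }
})

test_that("gap injection withholds only isolated interior concentrations", {
  cfg <- tinyConfig(seed = 3, gapRate = 0.3, outlierRate = 0)
  gen <- generateInhibitionRecords(cfg)
  grid <- cfg@doseGrid
  bySeries <- split(gen$records,
                    paste(gen$records$compound, gen$records$protein))
  sawGap <- FALSE
  for (s in bySeries) {
    present <- sort(match(s$concentration, grid))
    missing <- setdiff(seq_along(grid), present)
    expect_false(any(c(1, length(grid)) %in% missing))  # interior only
    if (length(missing) > 1) expect_true(all(diff(sort(missing)) > 1))
    if (length(missing)) sawGap <- TRUE
  }
  expect_true(sawGap)
})

test_that("omics matrices are deterministic, non-negative where required, and carry planted missingness", {
  cfg <- tinyConfig(seed = 5)
  om1 <- generateOmics(cfg)
  om2 <- generateOmics(cfg)
  expect_identical(om1, om2)
  expr <- omicsMatrix(om1, "expression")
  expect_true(all(expr >= 0))
  expect_false(anyNA(expr))
  expect_gt(sum(is.na(omicsMatrix(om1, "proteomics"))), 0)
  dep <- omicsMatrix(om1, "dependency")
  expect_gt(sum(!complete.cases(dep)), 0)
})

test_that("driver-gene expression correlates with planted sensitivity", {
  cfg <- syntheticConfig(nCellLines = 30, nCompounds = 5, nProteins = 30,
                         nGenes = 60, seed = 9)
  study <- generateSyntheticStudy(cfg)
  truth <- study$doseResponse$truth
  expr <- omicsMatrix(study$omics, "expression")
  for (j in colnames(truth@sensitivity)) {
    dg <- truth@driverGenes[[j]]
    # the dominant (first) driver alone carries most of the signal
    expect_gt(cor(expr[, dg[1]], truth@sensitivity[, j]), 0.5)
    # and the geometrically weighted driver combination nearly all of it
    w <- 4^-(seq_along(dg) - 1)
    m <- as.vector(expr[, dg, drop = FALSE] %*% (w / sum(w)))
    expect_gt(cor(m, truth@sensitivity[, j]), 0.9)
  }
})

test_that("zero sensitivity yields all-one viability and exactly flat fitted curves", {
  cfg <- cleanConfig(seed = 2)
  inh <- generateInhibitionRecords(cfg)
  om <- generateOmics(cfg)
  dr <- generateDoseResponse(cfg, inh, om, sensitivity = 0)
  expect_true(all(dr$truth@trueViability == 1))
  viab <- imputeViability(dr$params, cfg@doseGrid)
  expect_identical(nrow(viab),
                   nrow(dr$params) * length(cfg@doseGrid))
  expect_equal(viab$imputed_viability, rep(1, nrow(viab)))
})

test_that("noise-free full-sensitivity fit recovers a lower asymptote near zero", {
  # single target, potency forced well inside the grid so the top dose
  # fully inhibits
  cfg <- cleanConfig(seed = 13, targetsPerCompound = 1)
  inh <- generateInhibitionRecords(cfg)
  # keep only compounds whose top-dose intensity is essentially 0
  topI <- vapply(seq_len(nrow(inh$targets)), function(i) {
    1 / (1 + exp(inh$targets$slope[i] *
                 (log(max(cfg@doseGrid)) - log(inh$targets$potency[i]))))
  }, numeric(1))
  expect_true(any(topI <= 0.05))  # deterministic under this seed
  om <- generateOmics(cfg)
  dr <- generateDoseResponse(cfg, inh, om, sensitivity = 1)
  hit <- inh$targets$compound[topI <= 0.05]
  fits <- dr$params[dr$params$compound %in% hit, ]
  expect_true(all(abs(fits$c - 0) < 0.05))
})

test_that("dose-response generation is deterministic and marks growth combos", {
  cfg <- tinyConfig(seed = 21, growthFraction = 0.2)
  inh <- generateInhibitionRecords(cfg)
  om <- generateOmics(cfg)
  dr1 <- generateDoseResponse(cfg, inh, om)
  dr2 <- generateDoseResponse(cfg, inh, om)
  expect_identical(dr1$params, dr2$params)
  nGrowth <- floor(0.2 * cfg@nCellLines * cfg@nCompounds)
  expect_identical(nrow(dr1$truth@growthCombos), as.integer(nGrowth))
})

test_that("network enrichment strength controls driver-target edge density", {
  cfg <- tinyConfig(seed = 17)
  # degenerate limit: no background, forced driver edges -> only driver edges
  net <- generateNetwork(cfg, p0 = 0, driverEdgeProb = 1)
  e <- networkEdges(net)
  study <- generateSyntheticStudy(cfg)
  truth <- study$doseResponse$truth
  driverPairs <- unique(do.call(rbind, lapply(names(truth@driverGenes),
    function(j) expand.grid(a = truth@driverGenes[[j]],
                            b = truth@targetSets[[j]],
                            stringsAsFactors = FALSE))))
  expect_identical(nrow(e), nrow(driverPairs))
  expect_setequal(paste(e$node_a, e$node_b),
                  paste(driverPairs$a, driverPairs$b))
  expect_true(all(e$confidence >= 0.4 & e$confidence <= 1))

  # strength 1 is a null network: driver-target edge rate matches background
  cfgBig <- syntheticConfig(nCellLines = 4, nCompounds = 10, nProteins = 60,
                            nGenes = 120, seed = 23)
  netNull <- generateNetwork(cfgBig, p0 = 0.1, enrichmentStrength = 1)
  eN <- networkEdges(netNull)
  nNodes <- length(networkNodes(netNull))
  rate <- nrow(eN) / choose(nNodes, 2)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / choose(nNodes, 2)))
})

test_that("driver interactor count matches the analytic expectation", {
  cfg <- syntheticConfig(nCellLines = 4, nCompounds = 8, nProteins = 40,
                         nGenes = 150, nDriverGenes = 6, seed = 31)
  p0 <- 0.03; strength <- 4
  net <- generateNetwork(cfg, p0 = p0, enrichmentStrength = strength)
  study <- generateSyntheticStudy(cfg)
  truth <- study$doseResponse$truth
  targets <- unique(unlist(truth@targetSets))
  # drivers of one compound vs that compound's targets: per-gene adjacency
  # prob to >=1 of the compound's own t targets is p0*strength each; to the
  # remaining targets p0 each (plus overlaps across compounds, which this
  # conservative bound absorbs in the tolerance)
  j <- names(truth@driverGenes)[1]
  drv <- truth@driverGenes[[j]]
  own <- truth@targetSets[[j]]
  other <- setdiff(targets, own)
  pHit <- 1 - (1 - min(1, p0 * strength))^length(own) *
    (1 - p0)^length(other)
  obs <- countInteractors(drv, targets, net)
  expected <- length(drv) * pHit
  tol <- 3 * sqrt(length(drv) * pHit * (1 - pHit)) + 1
  expect_lt(abs(obs$nInteracting - expected), tol)
})

test_that("fitted curves re-evaluated on the grid match planted truth without noise", {
  cfg <- cleanConfig(seed = 37)
  inh <- generateInhibitionRecords(cfg)
  om <- generateOmics(cfg)
  dr <- generateDoseResponse(cfg, inh, om)
  viab <- imputeViability(dr$params, cfg@doseGrid)
  tv <- dr$truth@trueViability
  truthv <- tv[cbind(match(viab$cell_line, dimnames(tv)[[1]]),
                     match(viab$compound, dimnames(tv)[[2]]),
                     match(sprintf("%.6e", viab$concentration),
                           dimnames(tv)[[3]]))]
  expect_lt(sqrt(mean((viab$imputed_viability - truthv)^2)), 0.02)
})

test_that("plate simulation with zero noise is exactly invertible", {
  truth <- expand.grid(cell_line = c("A", "B"), compound = c("d1", "d2"),
                       concentration = c(1e-7, 1e-6),
                       stringsAsFactors = FALSE)
  truth$viability <- round(runif(nrow(truth), 0.2, 1), 4)
  plate <- simulatePlateMeasurements(truth, noiseSd = 0, seed = 5)
  norm <- normalizePlate(plate$measurements)
  avg <- averageReplicates(norm)
  key <- function(d) paste(d$cell_line, d$compound, d$concentration)
  expect_equal(avg$viability[match(key(truth), key(avg))], truth$viability,
               tolerance = 1e-12)
})
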