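# Cleaning rules: default-one densification, neighbor-mean gap filling,
# global percentile truncation, prefixing and omics imputation — each
# checked against an independent scan oracle.

test_that("densification fills absent pairs with exactly 1 and keeps records verbatim", {
  grid <- c(1e-7, 1e-6, 1e-5)
  empty <- data.frame(compound = character(0), protein = character(0),
                      concentration = numeric(0),
                      relative_intensity = numeric(0))
  prof <- densifyInhibition(empty, c("c1", "c2"), c("p1", "p2"), grid)
  expect_true(all(intensityTensor(prof) == 1))

  rec <- data.frame(compound = "c1", protein = "p1", concentration = 1e-6,
                    relative_intensity = 0.3)
  prof <- densifyInhibition(rec, c("c1", "c2"), c("p1", "p2"), grid)
  arr <- intensityTensor(prof)
  expect_identical(arr["c1", 2, "p1"], 0.3)
  # the rest of the recorded pair's series is a gap, everything else is 1
  expect_true(all(is.na(arr["c1", c(1, 3), "p1"])))
  expect_true(all(arr["c2", , ] == 1) && all(arr["c1", , "p2"] == 1))

  bad <- data.frame(compound = "c1", protein = "p1", concentration = 5e-6,
                    relative_intensity = 0.3)
  expect_error(densifyInhibition(bad, "c1", "p1", grid), "not on the dose grid")
})

test_that("non-one cell count equals the sparse record count on generated data", {
  cfg <- tinyConfig(seed = 19, gapRate = 0)
  gen <- generateInhibitionRecords(cfg)
  prof <- densifyInhibition(gen$records,
                            sort(unique(gen$records$compound)),
                            sprintf("PRT%03d", 1:cfg@nProteins),
                            cfg@doseGrid)
  arr <- intensityTensor(prof)
  expect_identical(sum(!is.na(arr) & arr != 1), nrow(gen$records))
})

test_that("gap imputation averages interior neighbors and copies boundary neighbors", {
  grid <- c(1e-7, 1e-6, 1e-5)
  mk <- function(v) {
    arr <- array(1, dim = c(1, 3, 1),
                 dimnames = list("c1", sprintf("%.6e", grid), "p1"))
    arr[1, , 1] <- v
    KinaseInhibitionProfile(arr, grid)
  }
  out <- imputeMissingConcentrations(mk(c(1.0, NA, 0.6)))
  expect_equal(intensityTensor(out)[1, 2, 1], 0.8)
  out <- imputeMissingConcentrations(mk(c(NA, 0.9, 0.7)))
  expect_equal(intensityTensor(out)[1, 1, 1], 0.9)
  out <- imputeMissingConcentrations(mk(c(0.9, 0.7, NA)))
  expect_equal(intensityTensor(out)[1, 3, 1], 0.7)
  expect_error(imputeMissingConcentrations(mk(c(1, NA, NA))),
               "adjacent missing")
})

test_that("imputed gaps match an independent re-scan on generated profiles", {
  cfg <- tinyConfig(seed = 23, gapRate = 0.2)
  gen <- generateInhibitionRecords(cfg)
  comps <- sort(unique(gen$records$compound))
  prots <- sprintf("PRT%03d", 1:cfg@nProteins)
  raw <- densifyInhibition(gen$records, comps, prots, cfg@doseGrid)
  filled <- imputeMissingConcentrations(raw)
  arrRaw <- intensityTensor(raw)
  arrFill <- intensityTensor(filled)
  expect_false(anyNA(arrFill))
  # brute-force oracle over every missing cell
  naIdx <- which(is.na(arrRaw), arr.ind = TRUE)
  nD <- dim(arrRaw)[2]
  for (r in seq_len(nrow(naIdx))) {
    ci <- naIdx[r, 1]; d <- naIdx[r, 2]; p <- naIdx[r, 3]
    v <- arrRaw[ci, , p]
    expected <- if (d == 1) v[2] else if (d == nD) v[nD - 1] else
      mean(c(v[d - 1], v[d + 1]))
    expect_equal(arrFill[ci, d, p], expected)
  }
})

test_that("truncation threshold and modified-cell count match a quantile oracle", {
  grid <- c(1e-8, 1e-7)
  vals <- 0:100
  arr <- array(1, dim = c(1, 2, 51),
               dimnames = list("c1", sprintf("%.6e", grid),
                               sprintf("p%02d", 1:51)))
  arr[] <- c(vals, 50)  # 0..100 plus one duplicate median value
  prof <- KinaseInhibitionProfile(arr, grid)
  res <- truncateOutliers(prof, percentile = 50)
  oracle <- unname(quantile(c(vals, 50), 0.5, type = 7))
  expect_identical(res$threshold, oracle)
  expect_lte(max(intensityTensor(res$profile)), oracle)

  # no exceedance (max tied, so the interpolated quantile equals it)
  arrSmall <- array(c(runif(18, 0, 0.9), 0.95, 0.95), dim = c(2, 2, 5),
                    dimnames = list(c("a", "b"), sprintf("%.6e", grid),
                                    sprintf("p%d", 1:5)))
  p2 <- KinaseInhibitionProfile(arrSmall, grid)
  res2 <- truncateOutliers(p2, 99.99)
  expect_identical(intensityTensor(res2$profile), arrSmall)
  expect_error(truncateOutliers(p2, 0), "percentile")
  expect_error(truncateOutliers(p2, 101), "percentile")
})

test_that("truncation caps exactly the values above the independently computed quantile", {
  cfg <- tinyConfig(seed = 29, gapRate = 0, outlierRate = 0.1)
  gen <- generateInhibitionRecords(cfg)
  prof <- imputeMissingConcentrations(densifyInhibition(
    gen$records, sort(unique(gen$records$compound)),
    sprintf("PRT%03d", 1:cfg@nProteins), cfg@doseGrid))
  arr <- intensityTensor(prof)
  res <- truncateOutliers(prof, 99)
  thr <- unname(quantile(arr, 0.99, type = 7))
  expect_equal(res$threshold, thr)
  expect_identical(sum(intensityTensor(res$profile) != arr),
                   sum(arr > thr))
})

test_that("preprocessing chain is idempotent and preserves sub-threshold rank order", {
  cfg <- tinyConfig(seed = 31, gapRate = 0.1, outlierRate = 0.05)
  gen <- generateInhibitionRecords(cfg)
  comps <- sort(unique(gen$records$compound))
  prots <- sprintf("PRT%03d", 1:cfg@nProteins)
  res <- preprocessInhibition(gen$records, comps, prots, cfg@doseGrid,
                              percentile = 99)
  # idempotence on its own output
  res2 <- truncateOutliers(imputeMissingConcentrations(res$profile), 99)
  expect_equal(intensityTensor(res2$profile), intensityTensor(res$profile))
  # rank order at or below the threshold is unchanged
  arrBefore <- intensityTensor(imputeMissingConcentrations(
    densifyInhibition(gen$records, comps, prots, cfg@doseGrid)))
  below <- arrBefore <= res$threshold
  expect_identical(order(arrBefore[below]),
                   order(intensityTensor(res$profile)[below]))
})

test_that("feature prefixing separates classes and rejects within-class duplicates", {
  m <- function(cols) matrix(1, 1, length(cols),
                             dimnames = list("CL1", cols))
  b <- OmicsBundle(expression = m("TP53"), cnv = m("TP53"))
  pb <- prefixFeatures(b)
  expect_identical(colnames(omicsMatrix(pb, "expression")), "exp_TP53")
  expect_identical(colnames(omicsMatrix(pb, "cnv")), "cnv_TP53")
  # empty bundle passes through
  expect_identical(prefixFeatures(OmicsBundle()), OmicsBundle())
  # g genes per 4 classes -> 4g unique names
  g <- sprintf("G%02d", 1:7)
  full <- OmicsBundle(expression = m(g), cnv = m(g), proteomics = m(g),
                      dependency = m(g))
  pf <- prefixFeatures(full)
  all4 <- unlist(lapply(c("expression", "cnv", "proteomics", "dependency"),
                        function(s) colnames(omicsMatrix(pf, s))))
  expect_identical(length(unique(all4)), 28L)
  expect_error(prefixFeatures(OmicsBundle(expression = m(c("A", "A")))),
               "duplicate")
})

test_that("proteomics imputation uses min minus one sd, per protein", {
  m <- matrix(c(2, 4, NA, 1, 1, 1), nrow = 3,
              dimnames = list(c("L1", "L2", "L3"), c("pA", "pB")))
  out <- imputeProteomics(m)
  expect_equal(out["L3", "pA"], 2 - sd(c(2, 4)))
  expect_identical(out[, "pB"], m[, "pB"])  # untouched when complete
  # generated matrix: every filled value sits at or below the column minimum
  cfg <- tinyConfig(seed = 41)
  prot <- omicsMatrix(generateOmics(cfg), "proteomics")
  filled <- imputeProteomics(prot)
  for (p in colnames(filled)) {
    obs <- prot[, p][!is.na(prot[, p])]
    if (length(obs) < 2) next
    imputed <- filled[is.na(prot[, p]), p]
    if (length(imputed)) expect_true(all(imputed <= min(obs)))
  }
  expect_error(imputeProteomics(matrix(NA_real_, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("x", "y")))),
               "all proteomics")
})

test_that("proteomics columns with under two observations are dropped", {
  m <- matrix(c(1, NA, NA, 2, 3, 4), nrow = 3,
              dimnames = list(c("L1", "L2", "L3"), c("sparse", "full")))
  out <- imputeProteomics(m)
  expect_identical(colnames(out), "full")
  expect_identical(attr(out, "droppedColumns"), "sparse")
})

test_that("incomplete cell lines are removed and identified", {
  m <- matrix(1, 4, 3, dimnames = list(sprintf("L%d", 1:4),
                                       sprintf("g%d", 1:3)))
  expect_identical(dropIncompleteLines(m)[, ], m[, ])
  m2 <- m
  m2["L2", 2] <- NA
  out <- dropIncompleteLines(m2)
  expect_identical(rownames(out), c("L1", "L3", "L4"))
  expect_identical(attr(out, "droppedLines"), "L2")
  # planted count on generated dependency scores
  dep <- omicsMatrix(generateOmics(tinyConfig(seed = 43)), "dependency")
  k <- sum(!complete.cases(dep))
  expect_identical(nrow(dropIncompleteLines(dep)), nrow(dep) - k)
})
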