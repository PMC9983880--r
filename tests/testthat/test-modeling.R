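# Fold construction, the dose-only baseline, metrics, the cross-validation
# engine, importance tagging and ablations — on tiny studies; full-size
# signal-recovery runs live in the acceptance suite.

test_that("grouped folds are balanced, deterministic and leak-free", {
  combos <- expand.grid(cell_line = sprintf("L%d", 1:5),
                        compound = sprintf("d%d", 1:4),
                        stringsAsFactors = FALSE)
  f1 <- makeGroupFolds(combos, K = 10, seed = 4)
  f2 <- makeGroupFolds(combos, K = 10, seed = 4)
  expect_identical(f1, f2)
  expect_identical(unname(as.vector(table(f1$fold))), rep(2L, 10))
  expect_error(makeGroupFolds(combos[1:5, ], K = 10), "exceeds")

  # every combination appears in exactly one fold
  expect_identical(anyDuplicated(paste(f1$cell_line, f1$compound)), 0L)

  # rows replicated across concentrations inherit a single fold
  rows <- combos[rep(1:20, each = 8), ]
  byCombo <- tapply(f1$fold[match(paste(rows$cell_line, rows$compound),
                                  paste(f1$cell_line, f1$compound))],
                    paste(rows$cell_line, rows$compound),
                    function(x) length(unique(x)))
  expect_true(all(byCombo == 1))
})

test_that("the dose-only baseline predicts per-dose training means", {
  conc <- c(1e-6, 1e-6, 1e-7, 1e-7)
  resp <- c(0.4, 0.6, 0.9, 1.1)
  m <- baselineDoseModel(conc, resp)
  expect_equal(predictBaselineDose(m, c(1e-6, 1e-7)), c(0.5, 1.0))
  expect_error(predictBaselineDose(m, 1e-5), "unseen")
  # brute-force group means on a generated table
  dat <- tinyStudyTable()
  conc <- rowKeys(dat$table)$concentration
  y <- response(dat$table)
  m2 <- baselineDoseModel(conc, y)
  means <- tapply(y, sprintf("%.6e", conc), mean)
  got <- predictBaselineDose(m2, conc)
  expect_equal(got, as.vector(means[sprintf("%.6e", conc)]))
})

test_that("evaluatePredictions matches brute-force formulas under both conventions", {
  obs <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(unname(evaluatePredictions(obs, obs)), c(1, 0))
  shifted <- evaluatePredictions(obs + 0.1, obs)
  expect_equal(unname(shifted["r2"]), 1)
  expect_equal(unname(shifted["rmse"]), 0.1)
  set.seed(31)
  for (i in 1:20) {
    p <- rnorm(15); o <- rnorm(15)
    m <- evaluatePredictions(p, o)
    expect_equal(unname(m["r2"]), cor(p, o)^2, tolerance = 1e-12)
    expect_equal(unname(m["rmse"]), sqrt(mean((p - o)^2)),
                 tolerance = 1e-12)
    t <- evaluatePredictions(p, o, r2Method = "traditional")
    expect_equal(unname(t["r2"]),
                 1 - sum((o - p)^2) / sum((o - mean(o))^2),
                 tolerance = 1e-12)
  }
  expect_warning(evaluatePredictions(rep(1, 4), obs), "zero-variance")
})

test_that("cross-validated baseline ignores features and never leaks", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 4, seed = 2)
  b1 <- crossValidate(dat$table, modelSpec("baseline_dose", nFeatures = 1),
                      folds)
  b2 <- crossValidate(dat$table, modelSpec("baseline_dose", nFeatures = 50),
                      folds)
  expect_identical(oofPredictions(b1), oofPredictions(b2))
  # leakage scan: each row's prediction equals the mean of the OTHER folds'
  # responses at that dose
  keys <- rowKeys(dat$table)
  comboFold <- b1@folds
  y <- response(dat$table)
  for (i in sample(nrow(dat$table), 20)) {
    trainRows <- comboFold != comboFold[i] &
      sprintf("%.6e", keys$concentration) ==
        sprintf("%.6e", keys$concentration[i])
    expect_equal(oofPredictions(b1)[i], mean(y[trainRows]))
  }
})

test_that("a linear model recovers a perfectly recoverable single-feature signal", {
  dat <- tinyStudyTable()
  ft <- dat$table
  # response rewritten as an exact copy of one inhibition feature
  target <- paste0("act_",
                   dat$study$doseResponse$truth@targetSets[[1]][1])
  ftCopy <- FeatureTable(featureMatrix(ft), rowKeys(ft),
                         featureMatrix(ft)[, target],
                         featureClasses(ft))
  folds <- makeGroupFolds(rowKeys(ft), K = 4, seed = 3)
  res <- crossValidate(ftCopy, modelSpec("linear", nFeatures = 1), folds)
  expect_gte(cvMetrics(res)["r2"], 0.999)
})

test_that("cross-validation retains per-fold selections computed on training rows only", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 5)
  res <- crossValidate(dat$table,
                       modelSpec("random_forest", nFeatures = 10,
                                 trees = 50L), folds)
  sel <- foldSelections(res)
  expect_identical(length(sel), 3L)
  expect_true(all(vapply(sel, length, integer(1)) == 10L))
  # oracle: recompute the fold-1 selection from its training rows
  rowFold <- res@folds
  train <- kinoviab:::.subsetRows(dat$table, which(rowFold != 1L))
  expect_identical(sel[["1"]],
                   rankAndSelect(correlateFeatures(train), 10))
})

test_that("out-of-fold predictions are deterministic given both seeds", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 5)
  spec <- modelSpec("random_forest", nFeatures = 15, trees = 60L, seed = 9)
  r1 <- crossValidate(dat$table, spec, folds)
  r2 <- crossValidate(dat$table, spec, folds)
  expect_identical(oofPredictions(r1), oofPredictions(r2))
})

test_that("per-group metrics equal looped global evaluations", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 7)
  res <- crossValidate(dat$table, modelSpec("baseline_dose", 1), folds)
  for (by in c("compound", "cell_line")) {
    tab <- subsetMetrics(res, by)
    g <- rowKeys(dat$table)[[by]]
    for (i in seq_len(nrow(tab))) {
      idx <- which(g == tab$group[i])
      m <- suppressWarnings(evaluatePredictions(
        oofPredictions(res)[idx], response(dat$table)[idx]))
      expect_equal(tab$r2[i], unname(m["r2"]))
      expect_equal(tab$rmse[i], unname(m["rmse"]))
    }
  }
  # perfect predictions propagate to every group (R^2 = 1 wherever the
  # squared correlation is defined, i.e. the group response varies)
  perfect <- res
  perfect@predictions <- perfect@observed
  tab <- subsetMetrics(perfect, "compound")
  expect_true(all(tab$rmse == 0))
  varies <- vapply(tab$group, function(grp) {
    sd(response(dat$table)[rowKeys(dat$table)$compound == grp]) > 0
  }, logical(1))
  expect_true(all(abs(tab$r2[varies] - 1) < 1e-8))
})

test_that("a singleton sweep grid reproduces a plain cross-validation run", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 11)
  spec <- modelSpec("random_forest", nFeatures = 12, trees = 40L, seed = 2)
  sw <- hyperparameterSweep(dat$table, folds, grid = list(trees = 40L),
                            baseSpec = spec)
  expect_identical(nrow(sw), 1L)
  direct <- crossValidate(dat$table, spec, folds)
  expect_equal(sw$r2, direct@r2)
  expect_equal(sw$rmse, direct@rmse)
  expect_error(hyperparameterSweep(dat$table, folds,
                                   grid = list(depth = 3)), "unknown grid")
})

test_that("importance extraction tags classes and surfaces a dominant predictor", {
  # independent features so the signal carrier is unambiguous
  set.seed(41)
  n <- 300
  X <- matrix(rnorm(n * 8), n,
              dimnames = list(NULL, paste0("act_PRT", sprintf("%03d", 1:8))))
  y <- X[, 5]
  ft <- FeatureTable(X, data.frame(cell_line = "L", compound = "c",
                                   concentration = rep(1e-6, n)),
                     y, setNames(rep("act", 8), colnames(X)))
  fm <- fitFinalModel(ft, k = 8,
                      spec = modelSpec("random_forest", nFeatures = 8,
                                       trees = 200L))
  imp <- featureImportance(fm)
  expect_identical(imp$feature[1], colnames(X)[5])

  # class tags on a full study model
  dat <- tinyStudyTable()
  fm2 <- fitFinalModel(dat$table, k = 20,
                       spec = modelSpec("random_forest", nFeatures = 20,
                                        trees = 60L))
  imp2 <- featureImportance(fm2, dat$study$annotation)
  expect_true(all(imp2$tag[startsWith(imp2$feature, "exp_")] ==
                  "expression"))
  actTags <- imp2$tag[startsWith(imp2$feature, "act_")]
  expect_true(all(actTags %in% c("dark kinase", "light kinase",
                                 "non-kinase")))
  # families without importance support refuse
  bl <- list(model = NULL, spec = modelSpec("baseline_dose", 1))
  expect_error(featureImportance(bl), "does not support")
})

test_that("ablations honor class restrictions and the kinase subset", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 13)
  spec <- modelSpec("random_forest", trees = 60L)
  # inhibition-only equals inhibition+expression at k where selection can
  # only pick inhibition (expression columns flattened to a constant)
  flat <- featureMatrix(dat$table)
  flat[, featureClasses(dat$table)[colnames(flat)] == "exp"] <- 0.5
  ftFlat <- FeatureTable(flat, rowKeys(dat$table), response(dat$table),
                         featureClasses(dat$table))
  both <- ablationRun(ftFlat, folds, classes = c("act", "exp"),
                      kList = 5, baseSpec = spec)
  actOnly <- ablationRun(ftFlat, folds, classes = "act",
                         kList = 5, baseSpec = spec)
  expect_equal(both$r2, actOnly$r2, tolerance = 1e-12)

  kin <- ablationRun(dat$table, folds, classes = c("act", "exp"),
                     kList = 10, baseSpec = spec, kinaseOnly = TRUE,
                     annotation = dat$study$annotation)
  expect_identical(nrow(kin), 1L)
  expect_error(ablationRun(dat$table, folds, classes = "act", kList = 5,
                           baseSpec = spec, kinaseOnly = TRUE),
               "annotation")

  # single-dose restriction shrinks the row set to one dose per compound
  sd <- ablationRun(dat$table, folds, classes = c("act", "exp"),
                    kList = 10, baseSpec = spec, singleDose = TRUE)
  expect_identical(nrow(sd), 1L)
})

test_that("shuffling held-out responses cannot change predictions", {
  dat <- tinyStudyTable()
  folds <- makeGroupFolds(rowKeys(dat$table), K = 3, seed = 17)
  spec <- modelSpec("random_forest", nFeatures = 10, trees = 40L)
  res <- crossValidate(dat$table, spec, folds)
  # corrupt one fold's responses and refit: predictions for OTHER folds of
  # the unchanged training data must be identical where training sets agree
  y <- response(dat$table)
  fold1Rows <- res@folds == 1L
  yShuf <- y
  yShuf[fold1Rows] <- sample(y[fold1Rows])
  ftShuf <- FeatureTable(featureMatrix(dat$table), rowKeys(dat$table),
                         yShuf, featureClasses(dat$table))
  resShuf <- crossValidate(ftShuf, spec, folds)
  # fold 1 is held out in its own iteration: its predictions depend only on
  # the other folds, which are unchanged
  expect_identical(oofPredictions(resShuf)[fold1Rows],
                   oofPredictions(res)[fold1Rows])
})
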