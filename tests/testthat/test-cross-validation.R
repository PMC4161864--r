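strongPanel <- function(seed = 61, n = 12) {
  sim <- simulatePanelCohort(simulationDesign(
    nFeatures = 80, nControls = n, nPatients = n,
    effectSize = 3, seed = seed))
  subsetToPanel(normalizeSamples(sim$experiment))
}

test_that("LOOCV accounts for every sample exactly once", {
  xp <- strongPanel()
  cv <- suppressWarnings(loocv(xp, "pca_lda", grid = 1:3))
  pr <- predictions(cv)
  expect_equal(nrow(pr), ncol(xp))
  expect_setequal(pr$sampleId, colnames(xp))
  expect_equal(sort(pr$fold), seq_len(ncol(xp)))
  # reported confusion matches a recount of the stored predictions
  expect_equal(unname(cvAccuracy(cv)),
               mean(pr$predicted == pr$trueLabel))
  cf <- confusionCounts(cv)
  expect_equal(unname(cf["TP"] + cf["FN"]),
               sum(sampleLabels(xp) == "patient"))
})

test_that("ties in the accuracy trace go to the smallest grid value", {
  xp <- strongPanel(seed = 62)
  cv <- suppressWarnings(loocv(xp, "pca_lda", grid = 1:4))
  tr <- cv@trace
  best <- max(tr$accuracy)
  expect_equal(optimalHyperparameter(cv),
               min(tr$hyperparameter[tr$accuracy == best]))

  cvl <- loocv(xp, "lasso", grid = c(0.2, 0.4, 0.6))
  trl <- cvl@trace
  bestl <- max(trl$accuracy)
  expect_equal(optimalHyperparameter(cvl),
               min(trl$hyperparameter[trl$accuracy == bestl]))
})

test_that("a single fold re-run in isolation reproduces its prediction", {
  xp <- strongPanel(seed = 63)
  M <- ncol(xp)
  dec <- suppressWarnings(pcaDecompose(xp))
  cv <- suppressWarnings(loocv(xp, "pca_lda", grid = 1:3))
  k <- optimalHyperparameter(cv)
  for (j in c(1L, M %/% 2L, M)) {
    pr <- suppressWarnings(
      pcaLdaPredict(xp, setdiff(seq_len(M), j), j, k, decomposition = dec))
    expect_identical(pr$score, predictions(cv)$score[j])
    expect_identical(as.character(pr$predicted),
                     as.character(predictions(cv)$predicted[j]))
  }
  cvl <- loocv(xp, "lasso")
  s <- optimalHyperparameter(cvl)
  for (j in c(1L, M)) {
    out <- lassoPathPredict(xp, setdiff(seq_len(M), j), j, s)
    expect_equal(out$predictions$score, predictions(cvl)$score[j],
                 tolerance = 1e-12)
    expect_setequal(out$selected, foldSelections(cvl)[[j]])
  }
})

test_that("a strong planted panel yields high LOOCV accuracy", {
  xp <- strongPanel(seed = 64)
  expect_gte(cvAccuracy(suppressWarnings(loocv(xp, "pca_lda"))), 0.9)
  expect_gte(cvAccuracy(loocv(xp, "lasso")), 0.9)
})

test_that("fixed-panel runs record an identical selection in all folds", {
  sim <- simulatePanelCohort(simulationDesign(
    nFeatures = 80, nControls = 10, nPatients = 10,
    effectSize = 2, missingPanelIds = udbPanel()[1:2], seed = 65))
  res <- suppressWarnings(runDataset(
    sim$experiment, featureMode = "fixed_panel", method = "pca_lda",
    grid = 1:3))
  sels <- foldSelections(res$cv)
  expect_true(all(vapply(sels, function(s)
    setequal(s, udbPanel()[3:12]), TRUE)))
  expect_equal(stabilityScore(res$trace), 1)
})

test_that("pca_fe mode selects the requested count, label-free", {
  sim <- simulateCohort(simulationDesign(nFeatures = 300, seed = 66))
  res <- suppressWarnings(
    runDataset(sim$experiment, featureMode = "pca_fe",
               method = "pca_lda", targetCount = 10, grid = 1:3))
  expect_length(selectedFeatures(res$selection), 10L)
  expect_gte(length(intersect(selectedFeatures(res$selection),
                              sim$outliers)), 9L)
  expect_s4_class(res$cv, "CVResult")
})

test_that("lasso_native folds generally disagree and S < 1", {
  sim <- simulateCohort(simulationDesign(nFeatures = 200, seed = 67))
  res <- runDataset(sim$experiment, featureMode = "lasso_native")
  S <- stabilityScore(res$trace)
  expect_lt(S, 1)
  expect_gte(S, 1 / ncol(sim$experiment))
})

test_that("normalization timing after_fe normalizes the reduced matrix", {
  sim <- simulatePanelCohort(simulationDesign(
    nFeatures = 80, nControls = 8, nPatients = 8,
    effectSize = 2, seed = 68))
  res <- suppressWarnings(runDataset(
    sim$experiment, featureMode = "fixed_panel", method = "pca_lda",
    config = normalizationConfig("after_fe"), grid = 1:2))
  expect_s4_class(res$cv, "CVResult")
  resNone <- suppressWarnings(runDataset(
    sim$experiment, featureMode = "fixed_panel", method = "svm",
    config = normalizationConfig("none")))
  expect_s4_class(resNone$cv, "CVResult")
})

test_that("per-fold feature extraction is stable on the planted design", {
  sim <- simulateCohort(simulationDesign(nFeatures = 200, seed = 69))
  me <- normalizeSamples(sim$experiment)
  dec <- pcaDecompose(me)
  d <- deltaForCount(dec, 2, 10)
  tr <- loocvFeatureSelections(me, 2, delta = d)
  expect_equal(tr@M, ncol(me))
  expect_gte(stabilityScore(tr), 0.9)
})
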