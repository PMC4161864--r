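# a small well-separated panel cohort reused across classifier tests
separatedCohort <- function(effect = 4, n = 10, seed = 101,
                            nFeatures = 60) {
  sim <- simulatePanelCohort(simulationDesign(
    nFeatures = nFeatures, nControls = n, nPatients = n,
    effectSize = effect, seed = seed))
  subsetToPanel(normalizeSamples(sim$experiment))
}

test_that("PCA-LDA classifies a held-out patient on separated data", {
  xp <- separatedCohort(effect = 3)
  M <- ncol(xp)
  patIdx <- which(sampleLabels(xp) == "patient")[1]
  pr <- suppressWarnings(
    pcaLdaPredict(xp, setdiff(seq_len(M), patIdx), patIdx, k = 1))
  expect_equal(as.character(pr$predicted), "patient")
  expect_gt(pr$score, 0.5)
})

test_that("PCA-LDA is calibrated under label permutation", {
  me <- makeMe(30L, 12L, seed = 17L)
  M <- ncol(me)
  withr::with_seed(18, {
    accs <- replicate(30, {
      lab <- sample(as.integer(sampleLabels(me)) - 1L)
      sh <- MirnaExperiment(exprsValues(me), labels = lab)
      cv <- suppressWarnings(loocv(sh, "pca_lda", grid = 2))
      cvAccuracy(cv)
    })
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * max(se, 0.02))
})

test_that("PCA-LDA respects the k bounds and the boundary runs", {
  xp <- separatedCohort(n = 5)
  M <- ncol(xp)
  expect_error(suppressWarnings(
    pcaLdaPredict(xp, seq_len(M - 1), M, k = M - 1)), "k must")
  pr <- suppressWarnings(
    pcaLdaPredict(xp, seq_len(M - 1), M, k = M - 2))
  expect_s3_class(pr, "data.frame")
})

test_that("PCA-LDA is invariant to rotation of the miRNA feature space", {
  me <- makeMe(20L, 10L, seed = 19L)
  withr::with_seed(20, Q <- qr.Q(qr(matrix(rnorm(400), 20, 20))))
  rot <- MirnaExperiment(Q %*% exprsValues(me),
                         labels = sampleLabels(me),
                         featureIds = rownames(me))
  for (k in c(1, 4, 8)) {
    a <- suppressWarnings(pcaLdaPredict(me, 1:9, 10, k = k))
    b <- suppressWarnings(pcaLdaPredict(rot, 1:9, 10, k = k))
    expect_equal(a$score, b$score, tolerance = 1e-6)
  }
})

test_that("the SVM separates well-separated clouds and memorizes", {
  xp <- separatedCohort(effect = 4)
  M <- ncol(xp)
  test <- c(1, M)  # one control, one patient
  pr <- svmPredict(xp, setdiff(seq_len(M), test), test)
  expect_equal(as.character(pr$predicted),
               as.character(sampleLabels(xp))[test])
  # score orientation: patient scores above control scores
  expect_gt(pr$score[2], pr$score[1])

  # memorization: predicting a training point returns its label
  prIn <- svmPredict(xp, setdiff(seq_len(M), 2), 2)
  expect_equal(as.character(prIn$predicted), "control")
})

test_that("class rebalancing lets the minority class be predicted", {
  sim <- simulatePanelCohort(simulationDesign(
    nFeatures = 60, nControls = 45, nPatients = 9,
    effectSize = 3, seed = 23))
  xp <- subsetToPanel(normalizeSamples(sim$experiment))
  lab <- sampleLabels(xp)
  # hold out a balanced test grid: 4 patients + 4 controls
  test <- c(which(lab == "patient")[1:4], which(lab == "control")[1:4])
  pr <- svmPredict(xp, setdiff(seq_len(ncol(xp)), test), test)
  expect_setequal(unique(as.character(pr$predicted)),
                  c("control", "patient"))
  expect_gte(mean(as.character(pr$predicted) == as.character(lab[test])),
             0.75)
})

test_that("lasso discrimination applies the strict 1.5 cut", {
  xp <- separatedCohort(effect = 4)
  M <- ncol(xp)
  # s = 0: empty model; balanced training means a predicted value of
  # exactly 1.5 for every sample -> control by the strict-inequality rule
  lab <- sampleLabels(xp)
  test <- c(which(lab == "control")[1], which(lab == "patient")[1])
  out0 <- lassoPathPredict(xp, setdiff(seq_len(M), test), test, s = 0)
  expect_equal(unname(out0$predictions$score), c(1.5, 1.5))
  expect_equal(as.character(out0$predictions$predicted),
               c("control", "control"))
  expect_length(out0$selected, 0L)

  out1 <- lassoPathPredict(xp, setdiff(seq_len(M), test), test, s = 1)
  expect_equal(as.character(out1$predictions$predicted),
               c("control", "patient"))
  expect_error(lassoPathPredict(xp, setdiff(seq_len(M), test), test, 2),
               "\\[0, 1\\]")
})

test_that("a single informative feature is found and used by the lasso", {
  withr::with_seed(29, {
    v <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(sprintf("m%02d", 1:20),
                                sprintf("s%02d", 1:30)))
    v[7, 16:30] <- v[7, 16:30] + 6
  })
  me <- MirnaExperiment(v, labels = rep(c(0, 1), each = 15))
  out <- lassoPathPredict(me, 1:28, 29:30, s = 1)
  expect_true("m07" %in% out$selected)
  expect_equal(as.character(out$predictions$predicted),
               c("patient", "patient"))
})

test_that("no classifier reads the held-out label", {
  xp <- separatedCohort(effect = 1.5, n = 8, seed = 37)
  M <- ncol(xp)
  j <- 3L
  flipped <- sampleLabels(xp)
  flipped[j] <- ifelse(flipped[j] == "control", "patient", "control")
  poisoned <- MirnaExperiment(exprsValues(xp), labels =
                                as.character(flipped))
  tr <- setdiff(seq_len(M), j)
  a1 <- suppressWarnings(pcaLdaPredict(xp, tr, j, k = 2))
  b1 <- suppressWarnings(pcaLdaPredict(poisoned, tr, j, k = 2))
  expect_identical(a1$score, b1$score)
  a2 <- svmPredict(xp, tr, j); b2 <- svmPredict(poisoned, tr, j)
  expect_identical(a2$score, b2$score)
  a3 <- lassoPathPredict(xp, tr, j, 0.5)
  b3 <- lassoPathPredict(poisoned, tr, j, 0.5)
  expect_identical(a3$predictions$score, b3$predictions$score)
})
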