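#' @include pca-fe.R lars.R
NULL

.checkSplit <- function(M, trainIdx, testIdx) {
  trainIdx <- as.integer(trainIdx); testIdx <- as.integer(testIdx)
  if (length(intersect(trainIdx, testIdx)))
    stop("train and test indices must be disjoint", call. = FALSE)
  if (!setequal(c(trainIdx, testIdx), seq_len(M)))
    stop("train and test indices must partition the samples", call. = FALSE)
  list(train = trainIdx, test = testIdx)
}

.predFrame <- function(sampleIds, predicted, score) {
  data.frame(sampleId = sampleIds,
             predicted = factor(predicted, levels = c("control", "patient")),
             score = as.numeric(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Ridge-regularized two-class linear discriminant: fallback when the
# pooled within-class scatter is singular (k close to the training size
# or collinear PC scores). Equal priors; ridge 1e-8 * trace / k.
.ridgeLda <- function(xtr, ytr, xte) {
  k <- ncol(xtr)
  m0 <- colMeans(xtr[ytr == "control", , drop = FALSE])
  m1 <- colMeans(xtr[ytr == "patient", , drop = FALSE])
  n0 <- sum(ytr == "control"); n1 <- sum(ytr == "patient")
  S <- ((n0 - 1) * stats::cov(xtr[ytr == "control", , drop = FALSE]) +
        (n1 - 1) * stats::cov(xtr[ytr == "patient", , drop = FALSE])) /
    (n0 + n1 - 2)
  S <- S + diag(1e-8 * sum(diag(S)) / k + 1e-12, k)
  wv <- solve(S, m1 - m0)
  z <- as.numeric(xte %*% wv - sum((m0 + m1) / 2 * wv))
  stats::plogis(z)
}

#' Semi-supervised PCA-based linear discriminant classification
#'
#' Discriminates patients from controls using the first `k` sample
#' principal component scores. PCA is computed on *all* samples — the
#' unlabeled test samples shape the projection, making the procedure
#' semi-supervised — after which a linear discriminant is fitted on the
#' training samples' scores only and applied to the held-out samples.
#' Labels of the test samples are never read.
#'
#' The discriminant uses equal class priors (`MASS::lda`); if the
#' within-class scatter is singular, a ridge-regularized discriminant
#' (ridge `1e-8 * trace / k`) is substituted and a message emitted. The
#' returned score is the posterior probability of the patient class, so
#' larger means more patient-like.
#'
#' @param x a [MirnaExperiment-class] (already restricted to the feature
#'   set under evaluation and normalized per the cohort's config).
#' @param trainIdx,testIdx integer column indices partitioning the
#'   samples; both classes must appear in the training part.
#' @param k number of leading PCs, `1 <= k <= M - 2`.
#' @param decomposition optionally a precomputed [pcaDecompose()] of `x`
#'   (it depends only on the features, so LOOCV can reuse it).
#' @return A data.frame with `sampleId`, `predicted`, `score` for the
#'   test samples.
#' @export
pcaLdaPredict <- function(x, trainIdx, testIdx, k, decomposition = NULL) {
  idx <- .checkSplit(ncol(x), trainIdx, testIdx)
  lab <- sampleLabels(x)
  if (length(unique(lab[idx$train])) < 2L)
    stop("both classes must be present in the training set", call. = FALSE)
  M <- ncol(x)
  k <- as.integer(k)
  if (k < 1L || k > M - 2L)
    stop("k must satisfy 1 <= k <= M - 2", call. = FALSE)
  if (is.null(decomposition)) decomposition <- pcaDecompose(x)
  emb <- t(sampleScores(decomposition))[, seq_len(k), drop = FALSE]
  xtr <- emb[idx$train, , drop = FALSE]
  ytr <- lab[idx$train]
  xte <- emb[idx$test, , drop = FALSE]
  post <- tryCatch({
    fit <- suppressWarnings(
      MASS::lda(x = xtr, grouping = ytr, prior = c(0.5, 0.5)))
    pr <- predict(fit, xte)
    as.numeric(pr$posterior[, "patient"])
  }, error = function(e) {
    message("singular within-class scatter; ridge discriminant used (",
            conditionMessage(e), ")")
    .ridgeLda(xtr, ytr, xte)
  })
  .predFrame(colnames(x)[idx$test],
             ifelse(post > 0.5, "patient", "control"), post)
}

#' Gaussian-kernel SVM classification with class rebalancing
#'
#' Support vector classification with a radial (Gaussian) kernel at the
#' conventional defaults (`gamma = 1/p`, `cost = 1`), except that class
#' weights are set inversely proportional to the training class
#' frequencies so controls and patients carry equal total weight even in
#' unbalanced cohorts. The decision value, oriented so that larger means
#' more patient-like, is returned as the score.
#'
#' @inheritParams pcaLdaPredict
#' @return A data.frame with `sampleId`, `predicted`, `score`.
#' @export
svmPredict <- function(x, trainIdx, testIdx) {
  idx <- .checkSplit(ncol(x), trainIdx, testIdx)
  lab <- sampleLabels(x)
  ytr <- droplevels(lab[idx$train])
  if (nlevels(ytr) < 2L)
    stop("both classes must be present in the training set", call. = FALSE)
  xtr <- t(exprsValues(x))[idx$train, , drop = FALSE]
  xte <- t(exprsValues(x))[idx$test, , drop = FALSE]
  cnt <- table(ytr)
  wts <- sum(cnt) / (2 * cnt)
  fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                    class.weights = setNames(as.numeric(wts), names(cnt)))
  pr <- predict(fit, xte, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # decision values are oriented toward the first class in the attribute
  # name ("a/b": positive favours a); flip so larger = patient
  dvName <- colnames(attr(pr, "decision.values"))[1L]
  if (startsWith(dvName, "control")) dv <- -dv
  .predFrame(colnames(x)[idx$test], as.character(pr), dv)
}

#' Lasso-path discrimination with the 1.5 cut
#'
#' Classifies by linear lasso regression on a numeric response coding
#' healthy controls as 1 and patients as 2 (deliberately a regression,
#' not a logistic model). The LARS-lasso path is fitted on the training
#' samples ([larsPath()]) and evaluated at path fraction `s`; held-out
#' samples with predicted value strictly larger than 1.5 are called
#' patients, all others controls (a prediction of exactly 1.5 — e.g. the
#' empty model on balanced classes — is a control). The features with
#' nonzero coefficients at `s` are returned for selection-stability
#' bookkeeping.
#'
#' @inheritParams pcaLdaPredict
#' @param s path fraction in `[0, 1]` (see [predictLarsPath()]).
#' @return A list: `predictions` (data.frame with `sampleId`,
#'   `predicted`, `score` = the predicted numeric value) and `selected`
#'   (character vector of features with nonzero coefficients at `s`).
#' @export
lassoPathPredict <- function(x, trainIdx, testIdx, s) {
  idx <- .checkSplit(ncol(x), trainIdx, testIdx)
  if (length(s) != 1L || s < 0 || s > 1)
    stop("s must be a single fraction in [0, 1]", call. = FALSE)
  lab <- sampleLabels(x)
  if (length(unique(lab[idx$train])) < 2L)
    stop("both classes must be present in the training set", call. = FALSE)
  ytr <- ifelse(lab[idx$train] == "patient", 2, 1)
  xtr <- t(exprsValues(x))[idx$train, , drop = FALSE]
  xte <- t(exprsValues(x))[idx$test, , drop = FALSE]
  fit <- larsPath(xtr, ytr)
  pr <- predictLarsPath(fit, xte, s)
  val <- pr$fit[, 1L]
  list(predictions = .predFrame(colnames(x)[idx$test],
                                ifelse(val > 1.5, "patient", "control"),
                                val),
       selected = colnames(pr$coefficients)[abs(pr$coefficients[1L, ]) > 1e-10])
}
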