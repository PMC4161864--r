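#' @include classifiers.R
NULL

#' CVResult: leave-one-out cross-validation bookkeeping
#'
#' One LOOCV run of a discrimination method: the held-out prediction of
#' every fold at the optimal hyperparameter, the accuracy trace over the
#' hyperparameter grid, the per-fold selected feature sets (when the
#' method selects features inside folds), and the confusion counts at
#' the optimum (patient = positive class).
#'
#' @slot method `"pca_lda"`, `"svm"` or `"lasso"`.
#' @slot predictions data.frame: `sampleId`, `fold`, `trueLabel`,
#'   `predicted`, `score`; one row per sample, each held out exactly once.
#' @slot trace data.frame: `hyperparameter`, `accuracy`, one row per
#'   grid value (a single `NA` row for the grid-free SVM).
#' @slot optimal the grid value maximizing LOOCV accuracy (ties broken
#'   toward the smallest value); `NA` for SVM.
#' @slot foldSelections list of length `M` of character vectors.
#' @slot confusion named integer: `TP`, `FN`, `TN`, `FP`.
#' @aliases CVResult-class predictions foldSelections
#'   optimalHyperparameter
#' @exportClass CVResult
setClass("CVResult",
         representation(method = "character", predictions = "data.frame",
                        trace = "data.frame", optimal = "numeric",
                        foldSelections = "list", confusion = "integer"))

#' @rdname CVResult-class
setMethod("predictions", "CVResult", function(x) x@predictions)

#' @rdname CVResult-class
setMethod("foldSelections", "CVResult", function(x) x@foldSelections)

#' @rdname CVResult-class
setMethod("optimalHyperparameter", "CVResult", function(x) x@optimal)

#' @rdname CVResult-class
#' @param x a `CVResult` (or, for `confusionCounts`, factors of true and
#'   predicted labels via the default method).
#' @param ... unused.
setMethod("confusionCounts", "CVResult", function(x, ...) x@confusion)

#' @rdname CVResult-class
#' @export
cvAccuracy <- function(x) {
  stopifnot(is(x, "CVResult"))
  unname(sum(x@confusion[c("TP", "TN")]) / sum(x@confusion))
}

setMethod("show", "CVResult", function(object) {
  cf <- object@confusion
  cat("CVResult (", object@method, "): ", sum(cf), " LOOCV folds\n",
      sep = "")
  if (!is.na(object@optimal))
    cat("  optimal hyperparameter:", object@optimal, "\n")
  cat(sprintf("  accuracy %.3f  (TP %d, FN %d, TN %d, FP %d)\n",
              cvAccuracy(object), cf["TP"], cf["FN"], cf["TN"], cf["FP"]))
  invisible(NULL)
})

.confusion <- function(true, predicted) {
  c(TP = sum(true == "patient" & predicted == "patient"),
    FN = sum(true == "patient" & predicted == "control"),
    TN = sum(true == "control" & predicted == "control"),
    FP = sum(true == "control" & predicted == "patient"))
}

.cvResult <- function(method, sampleIds, trueLab, predicted, score,
                      trace, optimal, foldSelections) {
  preds <- data.frame(sampleId = sampleIds, fold = seq_along(sampleIds),
                      trueLabel = factor(trueLab,
                                         levels = c("control", "patient")),
                      predicted = factor(predicted,
                                         levels = c("control", "patient")),
                      score = as.numeric(score), stringsAsFactors = FALSE)
  new("CVResult", method = method, predictions = preds, trace = trace,
      optimal = as.numeric(optimal), foldSelections = foldSelections,
      confusion = .confusion(preds$trueLabel, preds$predicted))
}

#' Leave-one-out cross-validation with a hyperparameter grid
#'
#' Runs LOOCV (one fold per sample) for one discrimination method over a
#' hyperparameter grid, reporting predictions, confusion counts and the
#' optimal grid value. Optimality is judged on the same LOOCV
#' predictions that are reported — no nested cross-validation — so the
#' accuracy at the optimum is optimistically biased; this mirrors the
#' standard "optimal k / optimal s" reporting convention of the analyses
#' this package reproduces (see the vignette).
#'
#' For `"pca_lda"` the grid is over `k`, the number of leading PCs
#' (default `1:min(10, M - 2)`), with the semi-supervised PCA computed
#' once on all samples. For `"lasso"` the grid is over the path fraction
#' `s` (default `0, 0.01, ..., 1`), with one path fit per fold and the
#' per-fold feature sets recorded at the optimal `s`. The SVM has no
#' grid. Ties in accuracy are broken toward the smallest grid value.
#'
#' @param x a [MirnaExperiment-class] object, already restricted to the
#'   feature set under evaluation and normalized per cohort config.
#' @param method `"pca_lda"`, `"svm"` or `"lasso"`.
#' @param grid numeric hyperparameter grid (ignored for `"svm"`).
#' @return A [CVResult-class] object.
#' @examples
#' sim <- simulatePanelCohort(simulationDesign(
#'   nFeatures = 100, nControls = 10, nPatients = 10,
#'   effectSize = 3, seed = 11))
#' cv <- loocv(normalizeSamples(sim$experiment), "pca_lda", grid = 1:4)
#' cvAccuracy(cv)
#' @export
loocv <- function(x, method = c("pca_lda", "svm", "lasso"), grid = NULL) {
  method <- match.arg(method)
  M <- ncol(x)
  lab <- as.character(sampleLabels(x))
  if (min(table(lab)) < 2L)
    stop("each class needs at least 2 samples for LOOCV", call. = FALSE)
  sampleIds <- colnames(x)

  if (method == "svm") {
    predicted <- character(M); score <- numeric(M)
    for (j in seq_len(M)) {
      pr <- svmPredict(x, setdiff(seq_len(M), j), j)
      predicted[j] <- as.character(pr$predicted); score[j] <- pr$score
    }
    trace <- data.frame(hyperparameter = NA_real_,
                        accuracy = mean(predicted == lab))
    return(.cvResult("svm", sampleIds, lab, predicted, score, trace,
                     NA_real_, replicate(M, character(0),
                                         simplify = FALSE)))
  }

  if (method == "pca_lda") {
    if (is.null(grid)) grid <- seq_len(min(10L, M - 2L))
    grid <- sort(unique(as.integer(grid)))
    if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
    dec <- pcaDecompose(x)
    predLab <- matrix(NA_character_, M, length(grid))
    predScore <- matrix(NA_real_, M, length(grid))
    for (j in seq_len(M)) {
      for (g in seq_along(grid)) {
        pr <- pcaLdaPredict(x, setdiff(seq_len(M), j), j, k = grid[g],
                            decomposition = dec)
        predLab[j, g] <- as.character(pr$predicted)
        predScore[j, g] <- pr$score
      }
    }
    acc <- colMeans(predLab == lab)
    best <- which.max(acc)               # first max = smallest grid value
    trace <- data.frame(hyperparameter = grid, accuracy = acc)
    return(.cvResult("pca_lda", sampleIds, lab, predLab[, best],
                     predScore[, best], trace, grid[best],
                     replicate(M, character(0), simplify = FALSE)))
  }

  # lasso: one path per fold, all fractions evaluated from that path
  if (is.null(grid)) grid <- seq(0, 100) / 100
  grid <- sort(unique(as.numeric(grid)))
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  if (any(grid < 0 | grid > 1))
    stop("lasso grid values must lie in [0, 1]", call. = FALSE)
  v <- t(exprsValues(x))
  fits <- vector("list", M)
  predVal <- matrix(NA_real_, M, length(grid))
  for (j in seq_len(M)) {
    tr <- setdiff(seq_len(M), j)
    fits[[j]] <- larsPath(v[tr, , drop = FALSE],
                          ifelse(lab[tr] == "patient", 2, 1))
    predVal[j, ] <- predictLarsPath(fits[[j]], v[j, , drop = FALSE],
                                    grid)$fit[1L, ]
  }
  predLab <- ifelse(predVal > 1.5, "patient", "control")
  acc <- colMeans(predLab == lab)
  best <- which.max(acc)
  sel <- lapply(fits, function(f) {
    cf <- .larsCoefAt(f, grid[best])$beta[1L, ]
    names(cf)[abs(cf) > 1e-10]
  })
  trace <- data.frame(hyperparameter = grid, accuracy = acc)
  .cvResult("lasso", sampleIds, lab, predLab[, best], predVal[, best],
            trace, grid[best], sel)
}

#' Per-fold unsupervised feature extraction under LOOCV
#'
#' Re-runs PCA-based unsupervised feature extraction once per LOOCV fold
#' (on the `M - 1` retained samples, at a fixed threshold
#' \eqn{\Delta}) and records the selected set of each fold — the raw
#' material of the stability statistic [stabilityScore()]. Selection is
#' label-free, so this measures sensitivity of the selection to the
#' removal of single samples, not to labels.
#'
#' @param x a [MirnaExperiment-class] object (normalized as configured).
#' @param K embedding dimension (see [selectOutliers()]).
#' @param delta fixed threshold applied in every fold; alternatively
#'   give `targetCount` to re-derive a per-fold \eqn{\Delta} keeping the
#'   selection count fixed.
#' @param targetCount optional fixed selection count per fold.
#' @param standardize as in [selectOutliers()].
#' @return A [SelectionTrace-class] with `M` folds.
#' @export
loocvFeatureSelections <- function(x, K = 2L, delta = NULL,
                                   targetCount = NULL,
                                   standardize = FALSE) {
  if (is.null(delta) && is.null(targetCount))
    stop("give either a fixed delta or a targetCount", call. = FALSE)
  M <- ncol(x)
  folds <- vector("list", M)
  for (j in seq_len(M)) {
    dec <- pcaDecompose(x[, setdiff(seq_len(M), j)])
    dj <- if (is.null(delta))
      deltaForCount(dec, K, targetCount, standardize) else delta
    folds[[j]] <- selectedFeatures(selectOutliers(dec, K, dj, standardize))
  }
  selectionTrace(folds)
}

#' Run one cohort end to end
#'
#' Applies a cohort's normalization configuration, a feature-definition
#' mode and a classifier, under LOOCV:
#' \describe{
#'   \item{`fixed_panel`}{restrict to the fixed biomarker panel
#'     ([subsetToPanel()]); no per-fold selection, so the recorded
#'     selection is identical in all folds and its stability is 1 by
#'     construction.}
#'   \item{`pca_fe`}{unsupervised outlier selection
#'     ([selectOutliers()]) performed once on all samples (it is
#'     label-free), then classification on the selected miRNAs. Set
#'     `stabilityFolds = TRUE` to additionally re-select per fold at the
#'     fixed \eqn{\Delta} for the stability statistic.}
#'   \item{`lasso_native`}{the lasso performs its own per-fold
#'     selection; no external feature step.}
#' }
#' Normalization timing follows `config$timing`: `before_fe` normalizes
#' the full matrix before the feature step, `after_fe` normalizes the
#' reduced matrix afterwards, `none` skips normalization. Features
#' listed in `config$excludedFeatures` are removed first.
#'
#' @param x a [MirnaExperiment-class] object (raw).
#' @param featureMode `"fixed_panel"`, `"pca_fe"` or `"lasso_native"`.
#' @param method classifier passed to [loocv()]; `lasso_native` forces
#'   `"lasso"`.
#' @param panel panel for `fixed_panel` (default [udbPanel()]).
#' @param config a [normalizationConfig()].
#' @param K,delta,targetCount,standardize feature-extraction settings
#'   for `pca_fe` (give `delta` or `targetCount`).
#' @param grid hyperparameter grid passed to [loocv()].
#' @param stabilityFolds logical: also compute the per-fold selection
#'   trace (per-fold FE for `pca_fe`; for the other modes the trace is
#'   derived from the LOOCV run itself).
#' @return A list: `cv` ([CVResult-class]), `selection`
#'   ([FESelection-class] or `NULL`), `trace` ([SelectionTrace-class]
#'   or `NULL`).
#' @export
runDataset <- function(x,
                       featureMode = c("fixed_panel", "pca_fe",
                                       "lasso_native"),
                       method = c("pca_lda", "svm", "lasso"),
                       panel = udbPanel(),
                       config = normalizationConfig(),
                       K = 2L, delta = NULL, targetCount = NULL,
                       standardize = FALSE, grid = NULL,
                       stabilityFolds = FALSE) {
  featureMode <- match.arg(featureMode)
  method <- if (featureMode == "lasso_native") "lasso" else
    match.arg(method)
  x <- excludeFeatures(x, config$excludedFeatures)
  normFirst <- config$timing == "before_fe"
  normAfter <- config$timing == "after_fe"
  if (normFirst) x <- normalizeSamples(x)

  selection <- NULL
  trace <- NULL
  if (featureMode == "fixed_panel") {
    xf <- subsetToPanel(x, panel)
  } else if (featureMode == "pca_fe") {
    dec <- pcaDecompose(x)
    d <- if (is.null(delta)) {
      if (is.null(targetCount))
        stop("pca_fe needs delta or targetCount", call. = FALSE)
      deltaForCount(dec, K, targetCount, standardize)
    } else delta
    selection <- selectOutliers(dec, K, d, standardize)
    if (length(selectedFeatures(selection)) < 2L)
      stop("feature extraction selected fewer than 2 miRNAs",
           call. = FALSE)
    xf <- x[selectedFeatures(selection), ]
    if (stabilityFolds)
      trace <- loocvFeatureSelections(x, K, delta = d,
                                      standardize = standardize)
  } else {
    xf <- x
  }
  if (normAfter) xf <- normalizeSamples(xf)

  cv <- loocv(xf, method, grid)
  if (featureMode == "fixed_panel")
    cv@foldSelections <- replicate(ncol(xf), rownames(xf),
                                   simplify = FALSE)
  if (is.null(trace) && featureMode %in% c("fixed_panel", "lasso_native"))
    trace <- selectionTrace(cv@foldSelections)
  list(cv = cv, selection = selection, trace = trace)
}
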