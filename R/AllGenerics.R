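#' @include mirUDB-package.R
NULL

#' Sample class labels of an experiment
#'
#' @param x a [MirnaExperiment-class] object.
#' @return A factor of length `ncol(x)` with levels `control`, `patient`.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname PCADecomposition-class
#' @param x a `PCADecomposition` object.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("sampleEigenvectors", function(x) standardGeneric("sampleEigenvectors"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("mirnaScores", function(x) standardGeneric("mirnaScores"))

#' @rdname PCADecomposition-class
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname FESelection-class
#' @param x an `FESelection` object.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname FESelection-class
#' @export
setGeneric("outlierNorms", function(x) standardGeneric("outlierNorms"))

#' @rdname SelectionTrace-class
#' @param x a `SelectionTrace` or `CVResult` object.
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' Selection-stability statistic over cross-validation folds
#'
#' The stability of a feature-extraction procedure run once per
#' leave-one-out fold is summarised as the mean selection frequency of
#' the features that were ever selected,
#' \deqn{S = \frac{\sum_{i : F_i > 0} F_i}{M \hat M},}
#' where \eqn{F_i} counts in how many of the \eqn{M} folds feature
#' \eqn{i} was selected and \eqn{\hat M} is the number of features with
#' \eqn{F_i > 0}. \eqn{S = 1} if and only if every ever-selected feature
#' was selected in all folds (a fixed panel); a single one-off selection
#' gives the lower bound \eqn{1/M}. Larger values indicate more stable
#' feature extraction.
#'
#' @param x a [SelectionTrace-class] or [CVResult-class] object.
#' @return A single number in `(0, 1]`.
#' @examples
#' tr <- selectionTrace(list(c("a", "b"), "a", c("a", "c")))
#' stabilityScore(tr)  # F = (3, 1, 1), M = 3, Mhat = 3 -> 5/9
#' @export
setGeneric("stabilityScore", function(x) standardGeneric("stabilityScore"))

#' @rdname CVResult-class
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname CVResult-class
#' @export
setGeneric("foldSelections", function(x) standardGeneric("foldSelections"))

#' @rdname CVResult-class
#' @export
setGeneric("optimalHyperparameter", function(x) standardGeneric("optimalHyperparameter"))

#' @rdname CVResult-class
#' @export
setGeneric("confusionCounts", function(x, ...) standardGeneric("confusionCounts"))
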