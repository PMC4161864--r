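#' @include MirnaExperiment-class.R
NULL

#' PCADecomposition: the dual PCA embedding of miRNAs and samples
#'
#' Holds the result of solving the sample-space (\eqn{M \times M})
#' eigenproblem of an expression matrix \eqn{X} (\eqn{N} miRNAs
#' \eqn{\times} \eqn{M} samples, \eqn{M < N} in the usual regime):
#' eigenvalues \eqn{\lambda_k} of \eqn{X^\top X / N} in nonincreasing
#' order, orthonormal sample-space eigenvectors \eqn{u_k}, the miRNA
#' principal component scores \eqn{x_{ik} = (X u_k)_i} (the vectors
#' \eqn{v_k = X u_k}), and the sample principal component scores
#' \eqn{x_{kj} = \sqrt{\lambda_k}\, u_{kj}}. Both embeddings derive from
#' the single factorization, so keeping all \eqn{M} components
#' reconstructs \eqn{X} exactly: \eqn{X = \sum_k (X u_k) u_k^\top}.
#'
#' Each eigenvector is oriented so that its largest-magnitude entry is
#' positive, removing the sign indeterminacy of the eigenproblem.
#'
#' @slot eigenvalues numeric, length `M`, nonincreasing, nonnegative.
#' @slot sampleEigvecs `M x M` matrix, column `k` = \eqn{u_k}.
#' @slot mirnaScores `N x M` matrix of miRNA PC scores.
#' @slot sampleScores `M x M` matrix, entry `[k, j]` = sample PC score
#'   \eqn{x_{kj}}.
#' @slot featureIds,sampleIds identifier vectors.
#' @seealso [pcaDecompose()], [selectOutliers()]
#' @aliases PCADecomposition-class eigenvalues sampleEigenvectors
#'   mirnaScores sampleScores
#' @exportClass PCADecomposition
setClass("PCADecomposition",
         representation(eigenvalues = "numeric",
                        sampleEigvecs = "matrix",
                        mirnaScores = "matrix",
                        sampleScores = "matrix",
                        featureIds = "character",
                        sampleIds = "character"))

setValidity("PCADecomposition", function(object) {
  M <- length(object@eigenvalues)
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be nonnegative")
  if (!all(dim(object@sampleEigvecs) == M))
    msg <- c(msg, "sampleEigvecs must be M x M")
  if (ncol(object@mirnaScores) != M)
    msg <- c(msg, "mirnaScores must have M columns")
  if (length(msg)) msg else TRUE
})

#' @rdname PCADecomposition-class
setMethod("eigenvalues", "PCADecomposition", function(x) x@eigenvalues)

#' @rdname PCADecomposition-class
setMethod("sampleEigenvectors", "PCADecomposition",
          function(x) x@sampleEigvecs)

#' @rdname PCADecomposition-class
setMethod("mirnaScores", "PCADecomposition", function(x) x@mirnaScores)

#' @rdname PCADecomposition-class
setMethod("sampleScores", "PCADecomposition", function(x) x@sampleScores)

setMethod("show", "PCADecomposition", function(object) {
  ev <- object@eigenvalues
  cat("PCADecomposition:", length(object@featureIds), "miRNAs,",
      length(ev), "components\n")
  cat("  leading eigenvalues:",
      paste(signif(head(ev, 5L), 4L), collapse = ", "), "\n")
  invisible(NULL)
})

#' PCA via the sample-space eigenproblem
#'
#' Computes the PCA of an expression matrix by diagonalizing the
#' \eqn{M \times M} Gram matrix \eqn{X^\top X / N} — the natural
#' formulation when samples are far fewer than miRNAs — and derives both
#' embeddings from it: miRNA PC scores \eqn{X u_k} (which drive
#' unsupervised feature extraction) and sample PC scores
#' \eqn{\sqrt{\lambda_k}\, u_{kj}} (which drive PCA-based LDA). No label
#' information enters the decomposition.
#'
#' @param x a [MirnaExperiment-class] object, or a numeric
#'   feature-by-sample matrix. Apply [normalizeSamples()] first when the
#'   cohort's configuration calls for normalization before feature
#'   extraction.
#' @return A [PCADecomposition-class] object.
#' @examples
#' sim <- simulateCohort(simulationDesign(nFeatures = 60, seed = 3))
#' dec <- pcaDecompose(normalizeSamples(sim$experiment))
#' head(eigenvalues(dec))
#' @export
pcaDecompose <- function(x) {
  v <- if (is(x, "MirnaExperiment")) exprsValues(x) else as.matrix(x)
  N <- nrow(v); M <- ncol(v)
  if (M < 2L) stop("at least 2 samples required", call. = FALSE)
  if (M >= N)
    warning("more samples than miRNAs (M >= N); the sample-space ",
            "eigenproblem is still valid but unusual for this analysis",
            call. = FALSE)
  ee <- eigen(crossprod(v) / N, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)
  U <- ee$vectors
  # orient each eigenvector so its largest-magnitude entry is positive
  for (k in seq_len(M)) {
    piv <- which.max(abs(U[, k]))
    if (U[piv, k] < 0) U[, k] <- -U[, k]
  }
  scores <- v %*% U
  sampScores <- sweep(t(U), 1L, sqrt(lambda), "*")
  dimnames(U) <- list(colnames(v), paste0("PC", seq_len(M)))
  dimnames(scores) <- list(rownames(v), paste0("PC", seq_len(M)))
  dimnames(sampScores) <- list(paste0("PC", seq_len(M)), colnames(v))
  new("PCADecomposition", eigenvalues = lambda, sampleEigvecs = U,
      mirnaScores = scores, sampleScores = sampScores,
      featureIds = rownames(v), sampleIds = colnames(v))
}

#' FESelection: an unsupervised outlier-based feature selection
#'
#' The features retained by PCA-based unsupervised feature extraction:
#' the miRNAs whose outlyingness norm in the first `K` dimensions of the
#' miRNA PC-score embedding strictly exceeds the threshold \eqn{\Delta}.
#'
#' @slot selectedIds character, the selected miRNA identifiers.
#' @slot K integer, embedding dimension used (typically 2).
#' @slot delta numeric threshold \eqn{\Delta}.
#' @slot norms named numeric, per-miRNA outlyingness (reported for every
#'   miRNA so the 2-D embedding can be plotted and \eqn{\Delta} chosen).
#' @slot standardized logical; whether the score coordinates were scaled
#'   to unit variance across miRNAs before taking norms.
#' @aliases FESelection-class selectedFeatures outlierNorms
#' @exportClass FESelection
setClass("FESelection",
         representation(selectedIds = "character", K = "integer",
                        delta = "numeric", norms = "numeric",
                        standardized = "logical"))

#' @rdname FESelection-class
setMethod("selectedFeatures", "FESelection", function(x) x@selectedIds)

#' @rdname FESelection-class
setMethod("outlierNorms", "FESelection", function(x) x@norms)

setMethod("show", "FESelection", function(object) {
  cat("FESelection:", length(object@selectedIds), "of",
      length(object@norms), "miRNAs (K =", object@K,
      ", delta =", signif(object@delta, 4L),
      if (object@standardized) ", standardized norms" else "", ")\n")
  invisible(NULL)
})

.feNorms <- function(dec, K, standardize) {
  M <- length(dec@eigenvalues)
  if (K < 1L || K >= M)
    stop("K must satisfy 1 <= K < M (number of samples)", call. = FALSE)
  sc <- dec@mirnaScores[, seq_len(K), drop = FALSE]
  if (standardize)
    sc <- sweep(sc, 2L, apply(sc, 2L, sd), "/")
  setNames(sqrt(rowSums(sc^2)), dec@featureIds)
}

#' Unsupervised outlier feature selection in PC-score space
#'
#' Selects the miRNAs lying far from the origin in the low
#' \eqn{K}-dimensional miRNA PC-score embedding: feature \eqn{i} is
#' selected when its Euclidean norm over the first \eqn{K} score
#' coordinates strictly exceeds \eqn{\Delta}. Such outliers dominate the
#' eigenvectors by construction, so discarding the remaining miRNAs
#' approximately preserves the sample embedding used for diagnosis.
#' Selection is label-free. By default the raw score coordinates are
#' used (so \eqn{\Delta} is on the scale of the data); `standardize`
#' rescales each coordinate to unit variance across miRNAs first, making
#' \eqn{\Delta} comparable across cohorts.
#'
#' @param dec a [PCADecomposition-class].
#' @param K embedding dimension, `1 <= K < M`; 2 is the typical choice.
#' @param delta threshold \eqn{\Delta \ge 0}; features with norm exactly
#'   equal to \eqn{\Delta} are excluded (strict inequality).
#' @param standardize logical, see above.
#' @return An [FESelection-class] object with norms for all miRNAs.
#' @seealso [deltaForCount()] for a reproducible way to choose
#'   \eqn{\Delta}.
#' @export
selectOutliers <- function(dec, K = 2L, delta, standardize = FALSE) {
  stopifnot(is(dec, "PCADecomposition"), delta >= 0)
  norms <- .feNorms(dec, as.integer(K), standardize)
  new("FESelection", selectedIds = names(norms)[norms > delta],
      K = as.integer(K), delta = as.numeric(delta), norms = norms,
      standardized = standardize)
}

#' Threshold giving a target selection count
#'
#' The threshold \eqn{\Delta} is classically chosen by visual inspection
#' of the 2-D miRNA embedding so that the bulk of the outliers are
#' included; this helper makes that choice reproducible by returning the
#' \eqn{\Delta} that selects exactly `targetCount` miRNAs: the midpoint
#' between the `targetCount`-th and the next largest norm (or half the
#' smallest norm when every miRNA is requested). With tied norms at the
#' boundary the realized count can differ from the target.
#'
#' @param dec a [PCADecomposition-class].
#' @param K embedding dimension as in [selectOutliers()].
#' @param targetCount desired number of selected miRNAs, `1..N`.
#' @param standardize as in [selectOutliers()].
#' @return A threshold value \eqn{\Delta}.
#' @export
deltaForCount <- function(dec, K = 2L, targetCount, standardize = FALSE) {
  norms <- .feNorms(dec, as.integer(K), standardize)
  N <- length(norms)
  targetCount <- as.integer(targetCount)
  if (targetCount < 1L || targetCount > N)
    stop("targetCount must lie in 1..N", call. = FALSE)
  sorted <- sort(norms, decreasing = TRUE)
  if (targetCount == N) return(unname(sorted[N] / 2))
  unname((sorted[targetCount] + sorted[targetCount + 1L]) / 2)
}
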