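#' @include AllGenerics.R cross-validation.R
NULL

#' SelectionTrace: per-fold feature selections
#'
#' Records which miRNAs a feature-extraction procedure selected in each
#' of the \eqn{M} leave-one-out folds. Derived quantities: the selection
#' counts \eqn{F_i} (number of folds in which miRNA \eqn{i} was
#' selected) and \eqn{\hat M}, the number of miRNAs ever selected —
#' the ingredients of the stability statistic [stabilityScore()].
#'
#' @param folds a list of character vectors, one per fold (duplicates
#'   within a fold are collapsed).
#' @return `selectionTrace()` returns a validated `SelectionTrace`.
#' @aliases SelectionTrace-class selectionCounts
#' @examples
#' tr <- selectionTrace(list(c("a", "b"), "a", c("a", "c")))
#' selectionCounts(tr)
#' @export selectionTrace
#' @exportClass SelectionTrace
setClass("SelectionTrace",
         representation(folds = "list", M = "integer"))

selectionTrace <- function(folds) {
  if (!is.list(folds) || length(folds) == 0L)
    stop("folds must be a non-empty list of character vectors",
         call. = FALSE)
  folds <- lapply(folds, function(f) unique(as.character(f)))
  new("SelectionTrace", folds = folds, M = length(folds))
}

#' @rdname SelectionTrace-class
setMethod("selectionCounts", "SelectionTrace", function(x) {
  all <- unlist(x@folds, use.names = FALSE)
  if (length(all) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(all)
  setNames(as.integer(tab), names(tab))
})

setMethod("show", "SelectionTrace", function(object) {
  Fi <- selectionCounts(object)
  cat("SelectionTrace:", object@M, "folds,", length(Fi),
      "distinct features ever selected\n")
  if (length(Fi))
    cat(sprintf("  stability S = %.4f\n", stabilityScore(object)))
  invisible(NULL)
})

#' @rdname stabilityScore
setMethod("stabilityScore", "SelectionTrace", function(x) {
  Fi <- selectionCounts(x)
  if (length(Fi) == 0L)
    stop("stability is undefined: no feature was ever selected",
         call. = FALSE)
  if (any(Fi > x@M))
    stop("selection counts exceed the number of folds", call. = FALSE)
  sum(Fi) / (x@M * length(Fi))
})

#' @rdname stabilityScore
setMethod("stabilityScore", "CVResult", function(x)
  stabilityScore(selectionTrace(foldSelections(x))))

#' Per-miRNA significance screen: Welch t-tests with BH adjustment
#'
#' Tests each miRNA for a mean expression difference between patients
#' and healthy controls with a two-sided Welch (unequal-variance)
#' t-test, adjusts the p-values by the Benjamini-Hochberg step-up
#' criterion across all miRNAs, and flags those with adjusted
#' \eqn{p < 0.05} as significantly differentially expressed. miRNAs with
#' zero variance in both groups cannot be tested; they receive
#' \eqn{p = 1} when the group means are equal and \eqn{p = 0} otherwise,
#' and are flagged `degenerate`.
#'
#' @param x a [MirnaExperiment-class] with at least 2 samples per class.
#' @return A data.frame (one row per miRNA, input order):
#'   `featureId`, `meanControl`, `meanPatient`, `p`, `padj`,
#'   `significant`, `degenerate`. The summary counts
#'   (significant / not significant) are attached as
#'   `attr(result, "counts")` and available via [significanceCounts()].
#' @export
perFeatureTests <- function(x) {
  lab <- sampleLabels(x)
  if (min(table(lab)) < 2L)
    stop("at least 2 samples per class are required", call. = FALSE)
  v <- exprsValues(x)
  ctrl <- v[, lab == "control", drop = FALSE]
  pat <- v[, lab == "patient", drop = FALSE]
  n <- nrow(v)
  p <- numeric(n); degenerate <- logical(n)
  m0 <- rowMeans(ctrl); m1 <- rowMeans(pat)
  for (i in seq_len(n)) {
    if (var(ctrl[i, ]) + var(pat[i, ]) == 0) {
      degenerate[i] <- TRUE
      p[i] <- if (m0[i] == m1[i]) 1 else 0
    } else {
      p[i] <- t.test(pat[i, ], ctrl[i, ])$p.value
    }
  }
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(featureId = rownames(v), meanControl = m0,
                    meanPatient = m1, p = p, padj = padj,
                    significant = padj < 0.05, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(significant = sum(out$significant),
                           not_significant = sum(!out$significant))
  out
}

#' @rdname perFeatureTests
#' @param tab a result of `perFeatureTests()`.
#' @return `significanceCounts()` returns the named count vector.
#' @export
significanceCounts <- function(tab) attr(tab, "counts")

#' Benjamini-Hochberg step-up adjustment
#'
#' The false-discovery-rate adjustment applied across miRNAs by
#' [perFeatureTests()], exposed directly: the step-up procedure with
#' cumulative-minimum enforcement of monotonicity.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, same order as `p`.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")
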