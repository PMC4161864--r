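#' @include AllGenerics.R
NULL

#' MirnaExperiment: a labelled miRNA expression matrix
#'
#' `MirnaExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with a binary case/control design: the single assay `"exprs"` holds
#' the miRNA-by-sample expression matrix \eqn{X} (entries \eqn{x_{ij}},
#' the expression of miRNA \eqn{i} in sample \eqn{j}) and
#' `colData(x)$label` holds the group of each sample as a factor with
#' levels `control` and `patient`.
#'
#' Validity requires at least 2 features and 4 samples, both classes
#' present, unique non-empty feature and sample identifiers, and a fully
#' finite matrix (missing expression values must be resolved upstream;
#' they are never carried as `NA`).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param labels sample group assignment, parallel to the columns:
#'   a factor or character vector with values `control`/`patient`, or a
#'   binary vector with 0 = control, 1 = patient. A named vector is
#'   matched against the column names.
#' @param featureIds,sampleIds optional identifier vectors overriding
#'   `dimnames(values)`.
#'
#' @return `MirnaExperiment()` returns a validated `MirnaExperiment`.
#' @examples
#' x <- matrix(rnorm(40), 5, 8,
#'             dimnames = list(paste0("hsa-miR-", 1:5), paste0("s", 1:8)))
#' me <- MirnaExperiment(x, labels = rep(c(0, 1), each = 4))
#' sampleLabels(me)
#' @aliases MirnaExperiment MirnaExperiment-class
#' @export MirnaExperiment
#' @exportClass MirnaExperiment
setClass("MirnaExperiment", contains = "SummarizedExperiment")

.normalizeLabels <- function(labels, sampleIds) {
  if (!is.null(names(labels)) && !is.null(sampleIds)) {
    missing <- setdiff(sampleIds, names(labels))
    if (length(missing) > 0L)
      stop("no label provided for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    labels <- labels[sampleIds]
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0 (control) or 1 (patient)", call. = FALSE)
    labels <- ifelse(labels == 1, "patient", "control")
  }
  if (!all(labels %in% c("control", "patient")))
    stop("labels must be 'control'/'patient' (or 0/1)", call. = FALSE)
  factor(labels, levels = c("control", "patient"))
}

MirnaExperiment <- function(values, labels, featureIds = rownames(values),
                            sampleIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(featureIds))
    stop("feature identifiers are required (rownames or featureIds)",
         call. = FALSE)
  if (is.null(sampleIds))
    sampleIds <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(featureIds, sampleIds)
  labels <- .normalizeLabels(labels, sampleIds)
  if (length(labels) != ncol(values))
    stop("length(labels) must equal the number of samples", call. = FALSE)
  se <- SummarizedExperiment(
    assays = SimpleList(exprs = values),
    colData = DataFrame(label = labels, row.names = sampleIds))
  new("MirnaExperiment", se)
}

setValidity("MirnaExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    return("assay 'exprs' is missing")
  v <- assay(object, "exprs")
  if (nrow(v) < 2L) msg <- c(msg, "at least 2 features (miRNAs) required")
  if (ncol(v) < 4L) msg <- c(msg, "at least 4 samples required")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "feature identifiers must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (!all(is.finite(v)))
    msg <- c(msg, "expression values must all be finite (no NA/NaN/Inf)")
  lab <- colData(object)$label
  if (is.null(lab) || !is.factor(lab) ||
      !identical(levels(lab), c("control", "patient"))) {
    msg <- c(msg, "colData(x)$label must be a factor with levels control, patient")
  } else if (nlevels(droplevels(lab)) < 2L) {
    msg <- c(msg, "both label classes (control and patient) must be present")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MirnaExperiment
#' @param x a `MirnaExperiment`.
#' @export
setMethod("sampleLabels", "MirnaExperiment", function(x) colData(x)$label)

#' Expression matrix of a MirnaExperiment
#'
#' Convenience accessor for `assay(x, "exprs")`.
#'
#' @param x a [MirnaExperiment-class] object.
#' @return The numeric feature-by-sample matrix.
#' @export
exprsValues <- function(x) assay(x, "exprs")

setMethod("show", "MirnaExperiment", function(object) {
  lab <- sampleLabels(object)
  cat("MirnaExperiment:", nrow(object), "miRNAs x", ncol(object), "samples\n")
  cat("  controls:", sum(lab == "control"),
      " patients:", sum(lab == "patient"), "\n")
  miss <- metadata(object)$missingPanelMembers
  if (!is.null(miss) && length(miss))
    cat("  missing panel members:", paste(miss, collapse = ", "), "\n")
  invisible(NULL)
})
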