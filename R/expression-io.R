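#' @include MirnaExperiment-class.R
NULL

#' The 12-miRNA universal disease biomarker panel
#'
#' The fixed blood miRNA panel evaluated across disease cohorts: a
#' combined set of 12 miRNAs intended to separate patients of many
#' different diseases from healthy controls without per-disease
#' reselection. Cohorts profiled on platforms that lack some panel
#' members simply use the members present (see [subsetToPanel()]).
#'
#' @return Character vector of 12 miRNA identifiers, in panel order.
#' @examples
#' udbPanel()
#' @export
udbPanel <- function() {
  c("hsa-miR-425", "hsa-miR-15b", "hsa-miR-185", "hsa-miR-92a",
    "hsa-miR-140-3p", "hsa-miR-320a", "hsa-miR-486-5p", "hsa-miR-16",
    "hsa-miR-191", "hsa-miR-106b", "hsa-miR-19b", "hsa-miR-30d")
}

.checkPanel <- function(panel) {
  if (!is.character(panel) || length(panel) == 0L)
    stop("panel must be a non-empty character vector of miRNA ids",
         call. = FALSE)
  if (anyDuplicated(panel))
    stop("panel identifiers must be unique", call. = FALSE)
  panel
}

#' Read a tab-delimited expression table
#'
#' Reads the series-matrix-style dialect used for public miRNA cohorts:
#' a header row of sample identifiers, a first column of miRNA
#' identifiers ("hsa-miR-..."), and tab-separated numeric cells. Every
#' cell must parse as a finite number; missing or malformed entries are
#' an error (with row/column coordinates), never silently carried as
#' `NA`. Row and column order are preserved exactly as in the file.
#'
#' @param path path to the tab-delimited file.
#' @param labels sample-to-group assignment, as for [MirnaExperiment()];
#'   typically a named vector read from a sidecar label file or a
#'   dataset config ([readDatasetConfig()]). Every sample in the file
#'   must have a label.
#' @return A [MirnaExperiment-class] object.
#' @seealso [writeExpressionTable()]
#' @examples
#' tsv <- system.file("extdata", "example_cohort.tsv", package = "mirUDB")
#' cfg <- readDatasetConfig(
#'   system.file("extdata", "example_cohort.yaml", package = "mirUDB"))
#' me <- readExpressionTable(tsv, labels = cfg$labels)
#' me
#' @export
readExpressionTable <- function(path, labels) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression table must have a feature-id column plus >= 1 sample",
         call. = FALSE)
  featureIds <- raw[[1L]]
  sampleIds <- colnames(raw)[-1L]
  dup <- unique(featureIds[duplicated(featureIds)])
  if (length(dup))
    stop("duplicate feature identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  values <- matrix(NA_real_, nrow = length(featureIds),
                   ncol = length(sampleIds),
                   dimnames = list(featureIds, sampleIds))
  for (j in seq_along(sampleIds)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(!is.finite(col))
    if (length(bad))
      stop(sprintf(
        "non-numeric or missing cell at row %d ('%s'), column '%s' in %s",
        bad[1L], featureIds[bad[1L]], sampleIds[j], path), call. = FALSE)
    values[, j] <- col
  }
  MirnaExperiment(values, labels = labels)
}

#' Write an expression table
#'
#' Writes the same tab-delimited dialect read by
#' [readExpressionTable()], preserving values to full double precision
#' so that a write/read round trip is an identity.
#'
#' @param x a [MirnaExperiment-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  v <- exprsValues(x)
  cells <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  out <- cbind(ID = rownames(v), cells)
  colnames(out) <- c("ID", colnames(v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample z-score normalization
#'
#' Normalizes each sample (column) to zero mean and unit variance across
#' the miRNAs it contains, the normalization applied per cohort before
#' or after feature extraction depending on the dataset configuration.
#' The sample variance uses the \eqn{n-1} divisor.
#'
#' @param x a [MirnaExperiment-class] object whose columns all have
#'   nonzero variance.
#' @return A [MirnaExperiment-class] with every column at mean 0 and
#'   variance 1. Idempotent to numerical tolerance.
#' @examples
#' x <- matrix(rnorm(40, 5, 2), 5, 8,
#'             dimnames = list(paste0("m", 1:5), paste0("s", 1:8)))
#' me <- MirnaExperiment(x, labels = rep(c(0, 1), each = 4))
#' colMeans(exprsValues(normalizeSamples(me)))
#' @export
normalizeSamples <- function(x) {
  v <- exprsValues(x)
  sds <- apply(v, 2L, sd)
  if (any(sds == 0))
    stop("constant expression in sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  v <- scale(v, center = TRUE, scale = TRUE)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  assays(x)[["exprs"]] <- v
  x
}

#' Remove listed miRNAs from an experiment
#'
#' Drops the rows whose identifier appears in `ids` — used for the
#' per-cohort exclusion of miRNAs with abnormally large values, which
#' would otherwise dominate the per-sample normalization and the PCA.
#' Identifiers absent from the matrix are ignored with a warning.
#'
#' @param x a [MirnaExperiment-class] object.
#' @param ids character vector of miRNA identifiers to remove.
#' @return The experiment without the listed rows.
#' @export
excludeFeatures <- function(x, ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L) return(x)
  absent <- setdiff(ids, rownames(x))
  if (length(absent))
    warning("excluded id(s) not present: ", paste(absent, collapse = ", "),
            call. = FALSE)
  keep <- setdiff(rownames(x), ids)
  if (length(keep) < 2L)
    stop("exclusion would leave fewer than 2 features", call. = FALSE)
  x[keep, ]
}

#' Restrict an experiment to a fixed biomarker panel
#'
#' Keeps exactly the panel members present in the experiment, in panel
#' order. Panel members missing from the cohort's platform are dropped
#' from the discrimination and recorded in
#' `metadata(result)$missingPanelMembers`.
#'
#' @param x a [MirnaExperiment-class] object.
#' @param panel character vector of panel miRNA identifiers
#'   (default [udbPanel()]).
#' @return The experiment restricted to the panel rows, with the missing
#'   members listed in its metadata.
#' @export
subsetToPanel <- function(x, panel = udbPanel()) {
  panel <- .checkPanel(panel)
  present <- panel[panel %in% rownames(x)]
  if (length(present) == 0L)
    stop("no panel member is present in the experiment", call. = FALSE)
  out <- x[present, ]
  metadata(out)$missingPanelMembers <- setdiff(panel, present)
  out
}

#' Per-dataset normalization configuration
#'
#' Each cohort in a meta-analysis carries its own normalization recipe:
#' whether per-sample z-scoring is applied before feature extraction,
#' after it, or not at all for a given method, and which miRNAs with
#' abnormally large values are excluded up front (an explicit list; no
#' automatic detector is applied).
#'
#' @param timing one of `"before_fe"`, `"after_fe"`, `"none"`.
#' @param excludedFeatures character vector of miRNA ids removed before
#'   any analysis (may be empty).
#' @return A `NormalizationConfig` list with components `timing` and
#'   `excludedFeatures`.
#' @export
normalizationConfig <- function(timing = c("before_fe", "after_fe", "none"),
                                excludedFeatures = character()) {
  timing <- match.arg(timing)
  structure(list(timing = timing,
                 excludedFeatures = as.character(excludedFeatures)),
            class = "NormalizationConfig")
}

#' Read a per-dataset YAML/JSON configuration
#'
#' Reads a dataset description of the form
#' \preformatted{
#' label_map:            # sample id -> control / patient
#'   GSM1: control
#'   GSM2: patient
#' normalization:
#'   timing: before_fe   # or after_fe / none; may be a per-method map
#' excluded_features: [hsa-miR-486-5p]
#' }
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return A list with `labels` (named character vector),
#'   `config` (a default [normalizationConfig()]) and, when
#'   `normalization$timing` is a per-method map, `timingByMethod`.
#' @export
readDatasetConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$label_map))
    stop("config must contain a label_map section", call. = FALSE)
  labels <- unlist(cfg$label_map)
  excl <- as.character(unlist(cfg$excluded_features))
  timing <- cfg$normalization$timing
  timingByMethod <- NULL
  if (is.list(timing)) {
    timingByMethod <- lapply(timing, function(t)
      normalizationConfig(t, excl)$timing)
    timing <- "before_fe"
  }
  if (is.null(timing)) timing <- "before_fe"
  list(labels = labels,
       config = normalizationConfig(timing, excl),
       timingByMethod = timingByMethod)
}
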