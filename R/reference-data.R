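#' Published benchmark performance of the seven validation cohorts
#'
#' The previously reported per-disease performance of the 12-miRNA
#' universal panel and its competitors on seven public blood miRNA
#' cohorts (GEO: GSE46579 Alzheimer's disease, GSE37472 carcinoma,
#' GSE49823 coronary artery disease, GSE43329 nasopharyngeal carcinoma,
#' GSE50013 hepatocellular carcinoma, GSE41922 breast cancer, GSE49665
#' acute myeloid leukemia), bundled as package constants so that
#' mean-row arithmetic and report layouts can be checked without any
#' download. Values are as printed at 3 decimals.
#'
#' Methods: `panel_pca_lda` / `panel_svm` — the fixed 12-miRNA panel
#' classified by semi-supervised PCA-based LDA / SVM; `lasso` —
#' lasso-path discrimination with its own per-fold selection (the
#' `optimal_s` column gives the cross-validated path fraction);
#' `fe_pca_lda` / `fe_svm` — miRNAs selected by PCA-based unsupervised
#' FE (the `n_selected` column) classified by PCA-based LDA / SVM.
#'
#' @param method optionally restrict to one method.
#' @return A data.frame: `method`, `disease`, `accuracy`, `sensitivity`,
#'   `specificity`, and where applicable `optimal_s` or `n_selected`.
#' @examples
#' ref <- referencePerformance("panel_pca_lda")
#' round(mean(ref$accuracy), 3)
#' @export
referencePerformance <- function(method = NULL) {
  disease <- c("AD", "Carcinoma", "CAD", "NPC", "HCC", "BC", "AML")
  tab <- rbind(
    data.frame(method = "panel_pca_lda", disease = disease,
               accuracy    = c(0.829, 0.768, 0.846, 0.740, 0.700, 0.870, 0.784),
               sensitivity = c(0.833, 0.730, 0.846, 0.806, 0.700, 0.813, 0.769),
               specificity = c(0.818, 0.800, 0.846, 0.632, 0.700, 0.955, 0.846),
               optimal_s = NA_real_, n_selected = NA_integer_),
    data.frame(method = "panel_svm", disease = disease,
               accuracy    = c(0.914, 0.786, 0.769, 0.720, 0.725, 0.852, 0.938),
               sensitivity = c(0.917, 0.867, 0.769, 0.806, 0.550, 0.813, 0.981),
               specificity = c(0.909, 0.692, 0.769, 0.579, 0.900, 0.909, 0.769),
               optimal_s = NA_real_, n_selected = NA_integer_),
    data.frame(method = "lasso", disease = disease,
               accuracy    = c(0.928, 0.818, 0.884, 0.900, 0.825, 0.925, 0.985),
               sensitivity = c(0.979, 0.867, 0.769, 0.935, 0.650, 0.906, 1.000),
               specificity = c(0.818, 0.760, 1.000, 0.842, 1.000, 0.955, 0.923),
               optimal_s = c(0.09, 0.9, 0.24, 1, 0.03, 0.46, 0.64),
               n_selected = NA_integer_),
    data.frame(method = "fe_pca_lda", disease = disease,
               accuracy    = c(0.886, 0.857, 0.885, 0.720, 0.650, 1.000, 0.862),
               sensitivity = c(0.917, 0.846, 0.923, 0.806, 0.600, 1.000, 0.846),
               specificity = c(0.818, 0.867, 0.846, 0.579, 0.700, 1.000, 0.923),
               optimal_s = NA_real_,
               n_selected = c(22L, 36L, 16L, 28L, 8L, 18L, 11L)),
    data.frame(method = "fe_svm", disease = disease,
               accuracy    = c(0.843, 0.786, 0.807, 0.720, 0.770, 0.963, 0.969),
               sensitivity = c(0.833, 0.807, 0.615, 0.774, 0.550, 1.000, 1.000),
               specificity = c(0.864, 0.767, 1.000, 0.632, 0.850, 0.938, 0.846),
               optimal_s = NA_real_,
               n_selected = c(22L, 36L, 16L, 28L, 8L, 18L, 11L)))
  rownames(tab) <- NULL
  if (!is.null(method)) {
    stopifnot(method %in% tab$method)
    tab <- tab[tab$method == method, ]
    rownames(tab) <- NULL
  }
  tab
}

#' Published per-disease significance counts
#'
#' Reported numbers of miRNAs with a significant
#' (Benjamini-Hochberg-adjusted Welch t-test, \eqn{p < 0.05})
#' expression difference between patients and healthy controls in each
#' of the seven validation cohorts — the screen produced by
#' [perFeatureTests()]. Notably, two cohorts (CAD, HCC) have no
#' individually significant miRNA at all, which is why selection by
#' per-miRNA significance is not a workable alternative to a fixed
#' panel or unsupervised FE there.
#'
#' @return A data.frame: `disease`, `significant`, `not_significant`.
#' @export
referenceSignificanceCounts <- function() {
  data.frame(
    disease = c("AD", "Carcinoma", "CAD", "NPC", "HCC", "BC", "AML"),
    significant = c(4L, 7L, 0L, 264L, 0L, 86L, 6L),
    not_significant = c(498L, 558L, 746L, 622L, 255L, 188L, 122L))
}

#' Per-cohort exclusion lists for abnormally large miRNAs
#'
#' The explicit per-cohort lists of miRNAs excluded before analysis
#' because of abnormally large values (no automatic detector is used):
#' hsa-miR-486-5p in the AD cohort, hsa-miR-223 and hsa-miR-338 in the
#' CAD cohort, hsa-miR-451 in the NPC cohort.
#'
#' @return A named list of character vectors, one per disease code.
#' @export
referenceExclusions <- function() {
  list(AD = "hsa-miR-486-5p",
       Carcinoma = character(),
       CAD = c("hsa-miR-223", "hsa-miR-338"),
       NPC = "hsa-miR-451",
       HCC = character(),
       BC = character(),
       AML = character())
}
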