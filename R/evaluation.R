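#' @include cross-validation.R
NULL

#' @rdname CVResult-class
#' @param true,predicted factors (or characters) of true and predicted
#'   labels with values `control`/`patient`.
#' @export
setMethod("confusionCounts", "factor", function(x, predicted, ...)
  .confusion(as.character(x), as.character(predicted)))

#' ROC area under the curve by the rank statistic
#'
#' AUC computed as the Mann-Whitney probability that a random patient
#' scores higher than a random control, with tied scores receiving half
#' credit. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric decision values, larger = more patient-like.
#' @param labels parallel labels (`control`/`patient`, factor or
#'   character, or 0/1).
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
rocAuc <- function(scores, labels) {
  lab <- .normalizeLabels(labels, NULL)
  n1 <- sum(lab == "patient"); n0 <- sum(lab == "control")
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[lab == "patient"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.twoByTwo <- function(conf) {
  matrix(as.numeric(conf[c("TP", "FN", "FP", "TN")]), nrow = 2,
         dimnames = list(predicted = c("patient", "control"),
                         truth = c("patient", "control")))
}

#' Summarize one LOOCV run into an evaluation report row
#'
#' Computes, from the confusion counts (patient = positive class):
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`; the two-sided Fisher exact p of the 2x2 table (summing
#' the hypergeometric probabilities of tables no more probable than the
#' observed one); the sample odds ratio `TP*TN/(FN*FP)` (infinite or
#' zero with an empty cell, `NA` when undetermined) together with its
#' Haldane-Anscombe `+0.5`-corrected version; and, when per-sample
#' scores are supplied, the ROC AUC ([rocAuc()]). A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param x a [CVResult-class], or a named confusion vector
#'   (`TP`, `FN`, `TN`, `FP`) as returned by [confusionCounts()].
#' @param scores,labels per-sample decision values and true labels for
#'   the AUC (taken from the CVResult automatically).
#' @param method,dataset identifier strings carried into the row.
#' @return A one-row data.frame: `dataset`, `method`, `accuracy`,
#'   `sensitivity`, `specificity`, `fisher_p`, `odds_ratio`,
#'   `odds_ratio_haldane`, `auc`.
#' @examples
#' summarizeEvaluation(c(TP = 44, FN = 4, TN = 18, FP = 4))
#' @export
summarizeEvaluation <- function(x, scores = NULL, labels = NULL,
                                method = NA_character_,
                                dataset = NA_character_) {
  if (is(x, "CVResult")) {
    pr <- predictions(x)
    if (is.null(scores)) { scores <- pr$score; labels <- pr$trueLabel }
    if (is.na(method)) method <- x@method
    conf <- confusionCounts(x)
  } else {
    conf <- x
    if (!all(c("TP", "FN", "TN", "FP") %in% names(conf)))
      stop("confusion counts must be named TP, FN, TN, FP", call. = FALSE)
  }
  conf <- conf[c("TP", "FN", "TN", "FP")]
  if (any(conf < 0) || sum(conf) < 1)
    stop("confusion counts must be nonnegative with a positive total",
         call. = FALSE)
  npos <- conf["TP"] + conf["FN"]; nneg <- conf["TN"] + conf["FP"]
  div <- function(a, b) if (b == 0) NA_real_ else unname(a / b)
  orRaw <- {
    num <- conf["TP"] * conf["TN"]; den <- conf["FN"] * conf["FP"]
    if (den == 0) { if (num == 0) NA_real_ else Inf } else unname(num / den)
  }
  orHA <- unname(((conf["TP"] + 0.5) * (conf["TN"] + 0.5)) /
                   ((conf["FN"] + 0.5) * (conf["FP"] + 0.5)))
  fp <- fisher.test(.twoByTwo(conf))$p.value
  auc <- if (is.null(scores)) NA_real_ else rocAuc(scores, labels)
  data.frame(dataset = dataset, method = method,
             accuracy = div(conf["TP"] + conf["TN"], sum(conf)),
             sensitivity = div(conf["TP"], npos),
             specificity = div(conf["TN"], nneg),
             fisher_p = fp, odds_ratio = orRaw,
             odds_ratio_haldane = orHA, auc = auc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unweighted mean row over per-disease reports
#'
#' Appends to (or returns for) a stack of per-disease evaluation rows
#' the unweighted mean of each numeric metric — the "Mean" row of the
#' per-disease performance tables. Raw precision is retained; rendering
#' to 3 decimals happens in [renderPerformanceTable()].
#'
#' @param reports a data.frame of rows from [summarizeEvaluation()] (or
#'   any data.frame with numeric metric columns).
#' @param metrics columns to average.
#' @return A one-row data.frame with `dataset = "Mean"`.
#' @export
aggregateReports <- function(reports,
                             metrics = c("accuracy", "sensitivity",
                                         "specificity", "auc")) {
  if (nrow(reports) == 0L) stop("no reports to aggregate", call. = FALSE)
  metrics <- intersect(metrics, colnames(reports))
  out <- data.frame(dataset = "Mean",
                    method = if (length(unique(reports$method)) == 1L)
                      reports$method[1L] else NA_character_,
                    stringsAsFactors = FALSE)
  for (m in metrics) out[[m]] <- mean(reports[[m]])
  out
}

#' Render a per-disease performance table
#'
#' Formats per-disease evaluation rows plus their unweighted mean row,
#' metrics rounded to 3 decimals, in the layout of the published
#' per-disease accuracy/sensitivity/specificity tables.
#'
#' @param reports as in [aggregateReports()]; empty input yields an
#'   empty table with headers only.
#' @param metrics columns to keep.
#' @return A data.frame of character-formatted rows.
#' @export
renderPerformanceTable <- function(reports,
                                   metrics = c("accuracy", "sensitivity",
                                               "specificity")) {
  metrics <- intersect(metrics, colnames(reports))
  if (nrow(reports) == 0L) {
    out <- data.frame(matrix(character(0), 0, 2L + length(metrics)))
    colnames(out) <- c("dataset", "method", metrics)
    return(out)
  }
  full <- rbind(reports[, c("dataset", "method", metrics)],
                aggregateReports(reports, metrics)[, c("dataset",
                                                       "method", metrics)])
  for (m in metrics) full[[m]] <- sprintf("%.3f", full[[m]])
  rownames(full) <- NULL
  full
}

#' Render a stability table
#'
#' One row per (dataset, feature-extraction method) with the stability
#' statistic `S` — the tabular form of the stability comparison between
#' a fixed panel (always 1), PCA-based unsupervised FE and lasso.
#'
#' @param datasets,methods,S parallel vectors.
#' @return A data.frame with `S` rounded to 3 decimals for display and
#'   the raw value in `S_raw`.
#' @export
renderStabilityTable <- function(datasets, methods, S) {
  stopifnot(length(datasets) == length(methods),
            length(methods) == length(S))
  data.frame(dataset = datasets, method = methods,
             S = sprintf("%.3f", S), S_raw = as.numeric(S),
             stringsAsFactors = FALSE)
}
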