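#' @include expression-io.R
NULL

#' Design of a synthetic two-group miRNA cohort
#'
#' Describes a simulated case/control blood miRNA cohort with the
#' statistical structure the downstream analysis assumes: a small set of
#' group-informative miRNAs, heterogeneous per-miRNA baselines, blocks
#' of miRNAs correlated through a shared latent factor, and a few
#' miRNAs with strongly inflated variance (the natural targets of
#' unsupervised PCA-based feature extraction).
#'
#' Defaults emulate the public cohorts the analysis is aimed at:
#' a few hundred profiled miRNAs, two groups of 20-25 samples,
#' around ten informative miRNAs, and correlation blocks of 20
#' features at loading 0.7.
#'
#' @param nFeatures number of miRNAs.
#' @param nControls,nPatients samples per group.
#' @param nInformative number of group-informative miRNAs (the first
#'   `nInformative` features).
#' @param effectSize patient-minus-control mean shift of informative
#'   miRNAs, in units of the per-feature noise SD.
#' @param correlationBlockSize number of consecutive features sharing
#'   one latent factor; `<= 1` disables blocks.
#' @param factorLoading loading of the shared factor, in `[0, 1)`.
#' @param noiseSd SD of the independent per-feature Gaussian noise.
#' @param nOutlierVariance number of features (the last ones) with
#'   inflated variance.
#' @param outlierVarianceFactor multiplier (> 1) applied to the noise
#'   variance of the outlier features.
#' @param missingPanelIds feature identifiers to omit from the output
#'   matrix, emulating panel members absent from a platform.
#' @param seed integer seed; the generator is deterministic given the
#'   design and leaves the global RNG state untouched.
#' @return A `SimulationDesign` list.
#' @seealso [simulateCohort()], [simulatePanelCohort()]
#' @export
simulationDesign <- function(nFeatures = 500L,
                             nControls = 20L,
                             nPatients = 20L,
                             nInformative = 10L,
                             effectSize = 1,
                             correlationBlockSize = 20L,
                             factorLoading = 0.7,
                             noiseSd = 1,
                             nOutlierVariance = 10L,
                             outlierVarianceFactor = 25,
                             missingPanelIds = character(),
                             seed = 1L) {
  d <- list(nFeatures = as.integer(nFeatures),
            nControls = as.integer(nControls),
            nPatients = as.integer(nPatients),
            nInformative = as.integer(nInformative),
            effectSize = effectSize,
            correlationBlockSize = as.integer(correlationBlockSize),
            factorLoading = factorLoading,
            noiseSd = noiseSd,
            nOutlierVariance = as.integer(nOutlierVariance),
            outlierVarianceFactor = outlierVarianceFactor,
            missingPanelIds = as.character(missingPanelIds),
            seed = as.integer(seed))
  .validateDesign(d)
  structure(d, class = "SimulationDesign")
}

.validateDesign <- function(d) {
  stopifnot(d$nFeatures >= 2L, d$nControls >= 2L, d$nPatients >= 2L)
  if (d$nInformative > d$nFeatures)
    stop("nInformative must not exceed nFeatures", call. = FALSE)
  if (d$nOutlierVariance > d$nFeatures)
    stop("nOutlierVariance must not exceed nFeatures", call. = FALSE)
  if (d$nInformative + d$nOutlierVariance > d$nFeatures)
    stop("informative and outlier-variance features must not overlap",
         call. = FALSE)
  if (d$factorLoading < 0 || d$factorLoading >= 1)
    stop("factorLoading must lie in [0, 1)", call. = FALSE)
  if (d$noiseSd <= 0) stop("noiseSd must be positive", call. = FALSE)
  if (d$outlierVarianceFactor <= 1)
    stop("outlierVarianceFactor must exceed 1", call. = FALSE)
  invisible(d)
}

# Core sampler. informativeIdx selects which features receive the group
# shift; featureIds allows panel members to be planted under their own
# names. Outlier-variance features are the last nOutlierVariance and are
# kept out of the correlation blocks; their variance inflation is
# carried by one shared latent component with per-feature signed
# amplitude, so they form a co-varying outlier family (the structure
# PCA-based FE targets) rather than isotropic noise.
.simulate <- function(d, featureIds, informativeIdx) {
  n <- d$nControls + d$nPatients
  labels <- rep(c("control", "patient"), c(d$nControls, d$nPatients))
  sampleIds <- c(sprintf("ctrl_%02d", seq_len(d$nControls)),
                 sprintf("pat_%02d", seq_len(d$nPatients)))
  outlierIdx <- if (d$nOutlierVariance > 0L)
    (d$nFeatures - d$nOutlierVariance + 1L):d$nFeatures else integer()

  withr::with_seed(d$seed, {
    baseline <- rnorm(d$nFeatures, mean = 0, sd = 1)
    values <- baseline + matrix(rnorm(d$nFeatures * n, sd = d$noiseSd),
                                d$nFeatures, n)
    if (length(outlierIdx)) {
      amp <- sample(c(-1, 1), length(outlierIdx), replace = TRUE) *
        d$noiseSd * sqrt(d$outlierVarianceFactor - 1)
      g <- rnorm(n)
      values[outlierIdx, ] <- values[outlierIdx, ] + outer(amp, g)
    }
    if (d$correlationBlockSize > 1L) {
      blocked <- setdiff(seq_len(d$nFeatures), outlierIdx)
      block <- ceiling(seq_along(blocked) / d$correlationBlockSize)
      latent <- matrix(rnorm(max(block) * n), max(block), n)
      values[blocked, ] <- values[blocked, ] +
        d$factorLoading * latent[block, , drop = FALSE]
    }
    shift <- d$effectSize * d$noiseSd
    if (length(informativeIdx) && shift != 0)
      values[informativeIdx, labels == "patient"] <-
        values[informativeIdx, labels == "patient"] + shift
  })

  dimnames(values) <- list(featureIds, sampleIds)
  keep <- !(featureIds %in% d$missingPanelIds)
  me <- MirnaExperiment(values[keep, , drop = FALSE], labels = labels)
  list(experiment = me,
       informative = intersect(featureIds[informativeIdx],
                               rownames(me)),
       outliers = intersect(featureIds[outlierIdx], rownames(me)))
}

#' Simulate a two-group miRNA cohort
#'
#' Draws an expression matrix under the generative model
#' \eqn{x_{ij} = b_i + \ell z_{B(i),j} + \delta_i 1[j \in patients] +
#' \epsilon_{ij}}: per-feature baseline \eqn{b_i \sim N(0, 1)}
#' (heterogeneous miRNA scale), a shared standard-normal latent factor
#' per correlation block with loading \eqn{\ell}, a patient mean shift
#' for the informative features, and independent Gaussian noise. The
#' variance-outlier features additionally load, with per-feature random
#' sign and amplitude \eqn{\sqrt{(f - 1)}\,\sigma}, on one shared latent
#' component, inflating their marginal variance by the design factor
#' \eqn{f} while keeping them a co-varying family — the low-dimensional
#' outlier structure that PCA-based feature extraction targets. They
#' stay outside the correlation blocks. Ground truth
#' is returned alongside the matrix, never encoded in the identifiers'
#' position being "known" to downstream code.
#'
#' @param design a [simulationDesign()].
#' @return A list: `experiment` ([MirnaExperiment-class]),
#'   `informative` (ids of group-informative features) and `outliers`
#'   (ids of inflated-variance features).
#' @examples
#' sim <- simulateCohort(simulationDesign(nFeatures = 50, seed = 7))
#' sim$experiment
#' @export
simulateCohort <- function(design) {
  .validateDesign(design)
  featureIds <- sprintf("hsa-miR-sim-%04d", seq_len(design$nFeatures))
  informativeIdx <- seq_len(design$nInformative)
  .simulate(design, featureIds, informativeIdx)
}

#' Simulate a cohort carrying a discriminative fixed panel
#'
#' As [simulateCohort()], but the members of a fixed biomarker panel are
#' planted as the informative features (under their own identifiers), so
#' the premise of a universal panel — the same named miRNAs carry the
#' group signal in every cohort — holds by construction.
#' `missingPanelIds` in the design removes those members from the output,
#' emulating platforms that do not profile the full panel.
#'
#' @param design a [simulationDesign()]; `nInformative` is ignored, the
#'   panel defines the informative set.
#' @param panel character vector of panel identifiers
#'   (default [udbPanel()]).
#' @return As [simulateCohort()].
#' @export
simulatePanelCohort <- function(design, panel = udbPanel()) {
  panel <- .checkPanel(panel)
  if (length(panel) + design$nOutlierVariance > design$nFeatures)
    stop("nFeatures too small to host the panel and the outlier features",
         call. = FALSE)
  featureIds <- sprintf("hsa-miR-sim-%04d", seq_len(design$nFeatures))
  featureIds[seq_along(panel)] <- panel
  .simulate(design, featureIds, seq_along(panel))
}
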