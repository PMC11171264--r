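#' @import methods
NULL

#' Otsu split of an intensity distribution
#'
#' Result of histogram-based Otsu thresholding: the threshold maximising the
#' between-class variance \eqn{\sigma_B^2(t) = \omega_0 \omega_1 (\mu_0-\mu_1)^2},
#' with the class probabilities and class means at the chosen threshold.
#'
#' @slot threshold numeric(1), intensity units; strictly inside the observed range.
#' @slot omega0,omega1 class probabilities below/above the threshold (sum to 1).
#' @slot mu0,mu1 class means below/above the threshold.
#' @slot betweenVar between-class variance at the threshold.
#' @slot nBins number of histogram bins used.
#' @slot binRange the (1st, 99th) percentile range spanned by the bins.
#'
#' @export
setClass("OtsuSplit",
  representation(
    threshold = "numeric", omega0 = "numeric", omega1 = "numeric",
    mu0 = "numeric", mu1 = "numeric", betweenVar = "numeric",
    nBins = "integer", binRange = "numeric"
  )
)

setValidity("OtsuSplit", function(object) {
  msg <- character()
  if (abs(object@omega0 + object@omega1 - 1) > 1e-9)
    msg <- c(msg, "class probabilities must sum to 1")
  if (length(object@threshold) != 1L)
    msg <- c(msg, "threshold must be a scalar")  # NA allowed for failed gates
  if (length(msg)) msg else TRUE
})

#' Two-component Gaussian mixture in log-intensity space
#'
#' A 2-component Gaussian mixture fitted to log foreground intensities by
#' MAP-EM with a symmetric Dirichlet weight prior. Components are sorted so
#' that \code{means[1] <= means[2]}.
#'
#' @slot weights,means,sds length-2 numeric; mixture weights (sum 1), component
#'   means and standard deviations in log-intensity space.
#' @slot nIter integer, EM iterations used.
#' @slot converged logical, whether the objective change fell below tolerance.
#' @slot objective numeric vector, per-iteration penalised log-likelihood trace
#'   (non-decreasing).
#'
#' @export
setClass("LogMixture",
  representation(
    weights = "numeric", means = "numeric", sds = "numeric",
    nIter = "integer", converged = "logical", objective = "numeric"
  )
)

setValidity("LogMixture", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1")
  if (any(object@sds <= 0)) msg <- c(msg, "component sds must be positive")
  if (object@means[1] > object@means[2])
    msg <- c(msg, "components must be sorted by mean")
  if (length(msg)) msg else TRUE
})

#' Fitted two-phase marker gate for one slide and marker
#'
#' The full two-phase threshold: an Otsu split separating background (T0) from
#' foreground (T1), a two-component Gaussian mixture on log(T1), and the final
#' positivity threshold at the weighted-density intersection of the two
#' components. The final threshold is stored on the linear intensity scale
#' (exp of the log-space root); a cell is positive iff its intensity exceeds
#' the Otsu split and its log intensity is at or above the intersection.
#'
#' @slot slideId,marker,compartment character identifiers.
#' @slot otsu an [OtsuSplit-class], fitted on the log intensities.
#' @slot mixture a [LogMixture-class].
#' @slot logThreshold intersection threshold in log-intensity space.
#' @slot finalThreshold the same threshold on the linear scale.
#' @slot positiveComponent index (always 2 after sorting) of the higher-mean,
#'   positive component.
#' @slot fallbackUsed logical; TRUE when no density intersection existed inside
#'   the open interval between the component means and the closest-density
#'   point was used instead.
#' @slot foregroundUnimodal logical; TRUE when the fitted foreground mixture
#'   was not genuinely bimodal (Ashman's D below 2) so the two components
#'   describe one population: the gate then thresholds at the Otsu boundary
#'   and the whole foreground is positive.
#' @slot failed logical; TRUE when gating failed (all cells called negative).
#' @slot failureReason character; empty when \code{failed} is FALSE.
#' @slot nCells,nForeground,nDroppedNonpositive integer bookkeeping.
#'
#' @export
setClass("MarkerGate",
  representation(
    slideId = "character", marker = "character", compartment = "character",
    otsu = "OtsuSplit", mixture = "LogMixture",
    logThreshold = "numeric", finalThreshold = "numeric",
    positiveComponent = "integer", fallbackUsed = "logical",
    foregroundUnimodal = "logical",
    failed = "logical", failureReason = "character",
    nCells = "integer", nForeground = "integer",
    nDroppedNonpositive = "integer"
  )
)

#' Per-slide spatial band model
#'
#' The spatial model of one slide: the PCA depth axis oriented from the
#' epidermis into the tumor, the estimated thickness (maximum depth extent of
#' the tumor boundary along that axis), the thirds cutoffs, a depth raster
#' built by a distance transform from the superficial tumor boundary, the
#' per-band areas, and the invasive-margin polyline.
#'
#' @slot slideId character.
#' @slot depthAxis unit 2-vector pointing from the epidermis into the tumor.
#' @slot origin point on the epidermis-facing tumor boundary at minimal depth
#'   projection.
#' @slot thicknessUm estimated thickness in micrometres.
#' @slot cutoffsUm depth cutoffs (T/3, 2T/3) in micrometres.
#' @slot rasterRes raster resolution in micrometres per pixel.
#' @slot rasterOrigin (x, y) of the centre of pixel (1, 1).
#' @slot depthRaster matrix of per-pixel depths (µm); NA outside the tumor.
#' @slot bandRaster integer matrix; 1 superficial, 2 middle, 3 invasive, NA
#'   outside.
#' @slot bandAreasMm2 named numeric(3), band areas in mm^2.
#' @slot tumorAreaMm2 polygon area of the tumor annotation in mm^2.
#' @slot margin two-column matrix, the invasive-margin polyline (µm).
#' @slot superficialBoundary two-column matrix, the epidermis-facing boundary
#'   points used as the distance-transform source.
#'
#' @export
setClass("BandGeometry",
  representation(
    slideId = "character", depthAxis = "numeric", origin = "numeric",
    thicknessUm = "numeric", cutoffsUm = "numeric",
    rasterRes = "numeric", rasterOrigin = "numeric",
    depthRaster = "matrix", bandRaster = "matrix",
    bandAreasMm2 = "numeric", tumorAreaMm2 = "numeric",
    margin = "matrix", superficialBoundary = "matrix"
  )
)

setValidity("BandGeometry", function(object) {
  msg <- character()
  cu <- object@cutoffsUm
  if (!(0 < cu[1] && cu[1] < cu[2] && cu[2] < object@thicknessUm + 1e-9))
    msg <- c(msg, "cutoffs must satisfy 0 < T/3 < 2T/3 < T")
  if (any(object@bandAreasMm2 <= 0))
    msg <- c(msg, "band areas must be positive")
  if (abs(sqrt(sum(object@depthAxis^2)) - 1) > 1e-9)
    msg <- c(msg, "depthAxis must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' Fitted Cox proportional-hazards model with concordance summaries
#'
#' Wraps a Breslow-ties Cox fit: per-covariate coefficients, hazard ratios with
#' Wald 95% confidence intervals and two-sided p-values, plus Harrell's
#' concordance — apparent, with a bootstrap percentile CI, and (optionally)
#' leave-one-out cross-validated with a bootstrap CI over the pooled
#' out-of-fold linear predictors.
#'
#' @slot modelId character label.
#' @slot table data.frame with columns term, beta, se, hr, lower, upper, p.
#' @slot logLik log partial likelihood at the optimum.
#' @slot n,nEvents integers.
#' @slot concordance apparent Harrell's C.
#' @slot concordanceCI bootstrap percentile 95% CI for the apparent C
#'   (NA when not computed).
#' @slot loocvC,loocvCI LOOCV concordance and its bootstrap CI (NA when not
#'   computed).
#' @slot tiesMethod character, "breslow" or "efron".
#' @slot converged logical.
#'
#' @export
setClass("CoxModelResult",
  representation(
    modelId = "character", table = "data.frame", logLik = "numeric",
    n = "integer", nEvents = "integer",
    concordance = "numeric", concordanceCI = "numeric",
    loocvC = "numeric", loocvCI = "numeric",
    tiesMethod = "character", converged = "logical"
  )
)

setValidity("CoxModelResult", function(object) {
  msg <- character()
  tab <- object@table
  if (nrow(tab) && any(!is.na(tab$lower) & !is.na(tab$upper) &
                       (tab$lower > tab$hr | tab$hr > tab$upper)))
    msg <- c(msg, "CI must bracket the hazard ratio")
  if (object@nEvents > object@n) msg <- c(msg, "nEvents cannot exceed n")
  if (!is.na(object@concordance) &&
      (object@concordance < 0 || object@concordance > 1))
    msg <- c(msg, "concordance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
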