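#' @name accessors
#' @title Accessors for melbands result objects
#'
#' @description Small accessor layer over the S4 result classes so downstream
#' code never touches slots directly.
#'
#' @param object a melbands S4 object.
#' @return The accessed component (see the individual generics).
NULL

#' @describeIn accessors Final positivity threshold of a [MarkerGate-class],
#'   linear intensity scale.
#' @export
setGeneric("finalThreshold", function(object) standardGeneric("finalThreshold"))

#' @rdname accessors
#' @export
setMethod("finalThreshold", "MarkerGate", function(object) object@finalThreshold)

#' @describeIn accessors Whether the closest-density fallback replaced a true
#'   intersection.
#' @export
setGeneric("fallbackUsed", function(object) standardGeneric("fallbackUsed"))

#' @rdname accessors
#' @export
setMethod("fallbackUsed", "MarkerGate", function(object) object@fallbackUsed)

#' @describeIn accessors Estimated tumor thickness in millimetres (the
#'   "Estimated Thickness (mm)" prognostic factor).
#' @export
setGeneric("thicknessMm", function(object) standardGeneric("thicknessMm"))

#' @rdname accessors
#' @export
setMethod("thicknessMm", "BandGeometry", function(object) object@thicknessUm / 1000)

#' @describeIn accessors Named band areas in mm^2 (superficial, middle,
#'   invasive).
#' @export
setGeneric("bandAreas", function(object) standardGeneric("bandAreas"))

#' @rdname accessors
#' @export
setMethod("bandAreas", "BandGeometry", function(object) object@bandAreasMm2)

#' @describeIn accessors Invasive-margin polyline (two-column matrix, µm): the
#'   deep-facing portion of the tumor boundary at depth >= 2T/3.
#' @export
setGeneric("invasiveMargin", function(object) standardGeneric("invasiveMargin"))

#' @rdname accessors
#' @export
setMethod("invasiveMargin", "BandGeometry", function(object) object@margin)

#' @describeIn accessors Per-covariate result table of a [CoxModelResult-class]
#'   (term, beta, se, hr, lower, upper, p).
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setMethod("resultTable", "CoxModelResult", function(object) object@table)

#' @describeIn accessors Apparent Harrell's concordance of a fitted model.
#' @export
setGeneric("concordanceIndex", function(object) standardGeneric("concordanceIndex"))

#' @rdname accessors
#' @export
setMethod("concordanceIndex", "CoxModelResult", function(object) object@concordance)

setMethod("show", "OtsuSplit", function(object) {
  cat(sprintf(
    "OtsuSplit: t* = %.6g  (omega0 = %.3f, omega1 = %.3f, sigmaB^2 = %.4g, %d bins)\n",
    object@threshold, object@omega0, object@omega1, object@betweenVar, object@nBins))
})

setMethod("show", "LogMixture", function(object) {
  cat("LogMixture (log-intensity space)\n")
  cat(sprintf("  weights: %.3f / %.3f\n", object@weights[1], object@weights[2]))
  cat(sprintf("  means:   %.4g / %.4g\n", object@means[1], object@means[2]))
  cat(sprintf("  sds:     %.4g / %.4g\n", object@sds[1], object@sds[2]))
  cat(sprintf("  EM: %d iterations, %s\n", object@nIter,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "MarkerGate", function(object) {
  cat(sprintf("MarkerGate: %s / %s (%s mean)\n",
              object@slideId, object@marker, object@compartment))
  if (object@failed) {
    cat("  FAILED:", object@failureReason, "- all cells called negative\n")
    return(invisible(NULL))
  }
  cat(sprintf("  Otsu split: %.6g (log), %.6g (linear); foreground n = %d of %d\n",
              object@otsu@threshold, exp(object@otsu@threshold),
              object@nForeground, object@nCells))
  cat(sprintf("  final threshold: %.6g (linear), %.4g (log)%s%s\n",
              object@finalThreshold, object@logThreshold,
              if (object@fallbackUsed) "  [closest-density fallback]" else "",
              if (object@foregroundUnimodal) "  [unimodal foreground: Otsu boundary]" else ""))
})

setMethod("show", "BandGeometry", function(object) {
  cat(sprintf("BandGeometry: %s\n", object@slideId))
  cat(sprintf("  depth axis: (%.3f, %.3f); estimated thickness %.3f mm\n",
              object@depthAxis[1], object@depthAxis[2], object@thicknessUm / 1000))
  cat(sprintf("  band areas (mm^2): superficial %.3f, middle %.3f, invasive %.3f\n",
              object@bandAreasMm2["superficial"], object@bandAreasMm2["middle"],
              object@bandAreasMm2["invasive"]))
  cat(sprintf("  raster: %.0f um/px; invasive margin: %d vertices\n",
              object@rasterRes, nrow(object@margin)))
})

setMethod("show", "CoxModelResult", function(object) {
  cat(sprintf("CoxModelResult: %s (n = %d, events = %d, ties = %s)\n",
              object@modelId, object@n, object@nEvents, object@tiesMethod))
  tab <- object@table
  if (nrow(tab)) {
    out <- data.frame(
      term = tab$term,
      HR = sprintf("%.3f", tab$hr),
      `95% CI` = sprintf("(%.3f, %.3f)", tab$lower, tab$upper),
      p = signif(tab$p, 3), check.names = FALSE)
    print(out, row.names = FALSE)
  }
  if (!is.na(object@concordance)) {
    ci <- object@concordanceCI
    cat(sprintf("  C-index: %.3f%s\n", object@concordance,
                if (!anyNA(ci)) sprintf(" (%.3f, %.3f)", ci[1], ci[2]) else ""))
  }
  if (!is.na(object@loocvC)) {
    ci <- object@loocvCI
    cat(sprintf("  LOOCV C-index: %.3f%s\n", object@loocvC,
                if (!anyNA(ci)) sprintf(" (%.3f, %.3f)", ci[1], ci[2]) else ""))
  }
})
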