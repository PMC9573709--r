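#' @rdname SubbandSet-class
#' @param x a \code{SubbandSet}.
#' @export
setGeneric("lowBand", function(x) standardGeneric("lowBand"))

#' @rdname SubbandSet-class
#' @param scale scale index (1 = finest); omit for the full list.
#' @export
setGeneric("highBands", function(x, scale) standardGeneric("highBands"))

#' Number of decomposition scales
#' @param x an \code{NSSTConfig} or \code{SubbandSet}.
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' Frames of a focal stack
#' @param x a \code{FocalStack}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Per-frame labels
#' @param x a \code{FocalStack} or \code{FocusCurve}.
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' Raw (unnormalised) scores of a focus curve
#' @param x a \code{FocusCurve}.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' Min-max normalised scores of a focus curve
#' @param x a \code{FocusCurve}.
#' @export
setGeneric("normScores", function(x) standardGeneric("normScores"))

#' @rdname SubbandSet-class
setMethod("lowBand", "SubbandSet", function(x) x@low)

#' @rdname SubbandSet-class
setMethod("highBands", "SubbandSet", function(x, scale) {
  if (missing(scale)) return(x@high)
  stopifnot(scale >= 1L, scale <= length(x@high))
  x@high[[scale]]
})

#' @rdname nScales
setMethod("nScales", "NSSTConfig", function(x) x@nScales)
#' @rdname nScales
setMethod("nScales", "SubbandSet", function(x) x@config@nScales)

#' @rdname frames
setMethod("frames", "FocalStack", function(x) x@frames)
#' @rdname frameLabels
setMethod("frameLabels", "FocalStack", function(x) x@labels)
#' @rdname frameLabels
setMethod("frameLabels", "FocusCurve", function(x) x@frameLabels)
#' @rdname rawScores
setMethod("rawScores", "FocusCurve", function(x) x@raw)
#' @rdname normScores
setMethod("normScores", "FocusCurve", function(x) x@normalized)

#' @describeIn FocalStack-class number of frames.
#' @param x a \code{FocalStack}.
#' @export
setMethod("length", "FocalStack", function(x) length(x@frames))

setMethod("show", "NSSTConfig", function(object) {
  cat("NSSTConfig:", object@nScales, "scales, directions",
      paste(object@directionsPerScale, collapse = "/"),
      sprintf("(%s pyramid, shear filter size %d)\n",
              object@pyramidFilterId, object@shearFilterSize))
})

setMethod("show", "SubbandSet", function(object) {
  d <- dim(object@low)
  cat(sprintf("SubbandSet: %dx%d, 1 low + %d high band(s) over %d scale(s)\n",
              d[1], d[2], sum(lengths(object@high)), length(object@high)))
})

setMethod("show", "FocalStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FocalStack: %d frames of %dx%d [%s ... %s]\n",
              length(object@frames), d[1], d[2],
              object@labels[1L], object@labels[length(object@labels)]))
})

setMethod("show", "FocusCurve", function(object) {
  cat(sprintf("FocusCurve (%s): %d frames%s\n", object@measure,
              length(object@raw),
              if (object@constant) ", constant" else
                sprintf(", argmax at frame %d",
                        which.max(object@normalized))))
})

setMethod("show", "NarrowWidthResult", function(object) {
  cat(sprintf(
    "NarrowWidth: alpha(0.4) = %.4f, beta(0.8) = %.4f, ratio = %.4f%s\n",
    object@alpha, object@beta, object@ratio,
    if (object@truncated) " (truncated at frame range)" else ""))
})

setMethod("show", "CurveDiagnostics", function(object) {
  cat(sprintf(
    "CurveDiagnostics: argmax frame %d, %d local maxima (%s), secondary peak %.3f\n",
    object@argmaxFrame, object@nLocalMaxima,
    if (object@isUnimodal) "unimodal" else "not unimodal",
    object@maxSecondaryPeak))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown: EL = %.4g, EH = %.4g, h = %.6g\n",
              object@EL, object@EH, object@h))
  cat("  per-scale SV:", format(object@SV, digits = 4), "\n")
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: %s (density %g, seed %d, %s)\n", object@kind,
              object@density, object@seed, object@mode))
})

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:", object@kind, "\n")
})
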