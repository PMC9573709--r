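#' @import methods
NULL

.isPow2 <- function(x) x >= 1 & bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

#' Configuration of the non-subsampled shearlet transform
#'
#' Describes a shift-invariant shearlet decomposition: the number of pyramid
#' scales, the number of directional wedges per scale (a power of two), the
#' nominal support of the directional filters, and the identifier of the
#' radial transition profile used by the pyramid windows.
#'
#' Scale 1 is the finest (highest-frequency) band; the residual after
#' \code{nScales} pyramid levels is the low-frequency sub-band.
#'
#' @slot nScales integer, number of high-frequency scales (k of the pyramid).
#' @slot directionsPerScale integer vector of length \code{nScales}; each
#'   entry a power of two \eqn{\ge 2}.
#' @slot shearFilterSize integer, nominal directional-filter support in
#'   pixels; recorded in the configuration for provenance (the frequency-domain
#'   bank defines its windows on the full FFT grid).
#' @slot pyramidFilterId character, \code{"maxflat"} (maximally-flat
#'   polynomial transition) or \code{"cosine"} (raised-cosine transition).
#'
#' @seealso [nsstConfig()], [nsstDecompose()]
#' @export
setClass("NSSTConfig", representation(
  nScales = "integer",
  directionsPerScale = "integer",
  shearFilterSize = "integer",
  pyramidFilterId = "character"
))

setValidity("NSSTConfig", function(object) {
  msg <- character()
  if (length(object@nScales) != 1L || object@nScales < 1L)
    msg <- c(msg, "nScales must be a single integer >= 1")
  if (length(object@directionsPerScale) != object@nScales)
    msg <- c(msg, "directionsPerScale must have one entry per scale")
  if (!all(object@directionsPerScale >= 2L) ||
      !all(.isPow2(object@directionsPerScale)))
    msg <- c(msg, "each directions count must be a power of two >= 2")
  if (length(object@shearFilterSize) != 1L || object@shearFilterSize < 1L)
    msg <- c(msg, "shearFilterSize must be a positive integer")
  if (!object@pyramidFilterId %in% c("maxflat", "cosine"))
    msg <- c(msg, "pyramidFilterId must be 'maxflat' or 'cosine'")
  if (length(msg)) msg else TRUE
})

#' Create an NSST configuration
#'
#' @param nScales number of high-frequency scales (default 3).
#' @param directionsPerScale integer vector of directional wedges per scale,
#'   powers of two (default 4 per scale).
#' @param shearFilterSize nominal directional filter support (default 32).
#' @param pyramidFilterId radial transition profile, \code{"maxflat"} or
#'   \code{"cosine"}.
#' @return An [NSSTConfig-class] object.
#' @examples
#' nsstConfig(nScales = 2, directionsPerScale = c(8, 4))
#' @export
nsstConfig <- function(nScales = 3L, directionsPerScale = rep(4L, nScales),
                       shearFilterSize = 32L, pyramidFilterId = "maxflat") {
  new("NSSTConfig",
      nScales = as.integer(nScales),
      directionsPerScale = as.integer(directionsPerScale),
      shearFilterSize = as.integer(shearFilterSize),
      pyramidFilterId = pyramidFilterId)
}

#' Shearlet sub-band coefficients of one image
#'
#' Output of [nsstDecompose()]: one low-frequency sub-band plus, per scale, a
#' list of directional high-frequency sub-bands. Because the transform is
#' non-subsampled, every coefficient array has exactly the input image's
#' shape.
#'
#' @slot low numeric matrix, the low-frequency sub-band.
#' @slot high list of length \code{nScales(config)}; element k is a list of
#'   directional coefficient matrices at scale k (scale 1 = finest).
#' @slot config the [NSSTConfig-class] that produced the decomposition.
#' @seealso [nsstDecompose()], [nsstReconstruct()], [lowBand()], [highBands()]
#' @export
setClass("SubbandSet", representation(
  low = "matrix",
  high = "list",
  config = "NSSTConfig"
))

setValidity("SubbandSet", function(object) {
  msg <- character()
  d <- dim(object@low)
  if (length(object@high) != object@config@nScales)
    msg <- c(msg, "number of high-frequency scales must equal config nScales")
  for (k in seq_along(object@high)) {
    bands <- object@high[[k]]
    if (length(bands) != object@config@directionsPerScale[k])
      msg <- c(msg, sprintf("scale %d must hold %d directional sub-bands",
                            k, object@config@directionsPerScale[k]))
    for (b in bands)
      if (!identical(dim(b), d))
        msg <- c(msg, "all sub-bands must share the input image's shape")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' An ordered focal stack
#'
#' A defocus--focus--defocus sequence of grayscale frames, all of identical
#' size, each a numeric matrix with intensities in [0, 1].
#'
#' @slot frames list of numeric matrices.
#' @slot labels character vector of per-frame identifiers (file names or
#'   frame tags).
#' @seealso [focalStack()], [loadStack()], [makeStack()], [scoreStack()]
#' @export
setClass("FocalStack", representation(
  frames = "list",
  labels = "character"
))

setValidity("FocalStack", function(object) {
  msg <- character()
  n <- length(object@frames)
  if (n < 3L)
    msg <- c(msg, "a focal stack needs at least 3 frames")
  if (length(object@labels) != n)
    msg <- c(msg, "one label per frame is required")
  if (n) {
    d <- dim(object@frames[[1L]])
    for (i in seq_len(n)) {
      f <- object@frames[[i]]
      if (!is.matrix(f) || !is.numeric(f)) {
        msg <- c(msg, sprintf("frame %d ('%s') is not a numeric matrix",
                              i, object@labels[i]))
      } else if (!identical(dim(f), d)) {
        msg <- c(msg, sprintf(
          "frame %d ('%s') has shape %dx%d, expected %dx%d",
          i, object@labels[i], nrow(f), ncol(f), d[1], d[2]))
      }
    }
  }
  if (length(msg)) msg else TRUE
}
)

#' Construct a focal stack from frames
#'
#' @param frames list of numeric matrices of identical shape (>= 3).
#' @param labels optional per-frame identifiers; defaults to
#'   \code{frame_01 ...}.
#' @return A [FocalStack-class].
#' @export
focalStack <- function(frames, labels = NULL) {
  if (is.null(labels))
    labels <- sprintf("frame_%02d", seq_along(frames))
  new("FocalStack", frames = frames, labels = as.character(labels))
}

#' A focus curve for one stack and one measure
#'
#' Per-frame sharpness scores in acquisition order, both raw and min--max
#' normalised to [0, 1]. A raw curve with zero range is flagged constant and
#' normalises to all zeros.
#'
#' @slot raw numeric vector of raw scores, one per frame.
#' @slot normalized numeric vector, \code{(raw - min) / (max - min)}; all 0
#'   when the raw curve is constant.
#' @slot frameLabels character vector of frame identifiers.
#' @slot measure character, the measure identifier that produced the scores.
#' @slot constant logical, TRUE when the raw curve has zero range.
#' @seealso [scoreStack()], [narrowWidth()], [diagnoseCurve()]
#' @export
setClass("FocusCurve", representation(
  raw = "numeric",
  normalized = "numeric",
  frameLabels = "character",
  measure = "character",
  constant = "logical"
))

setValidity("FocusCurve", function(object) {
  msg <- character()
  n <- length(object@raw)
  if (length(object@normalized) != n || length(object@frameLabels) != n)
    msg <- c(msg, "raw, normalized and frameLabels must have equal length")
  if (n && !object@constant) {
    if (any(object@normalized < -1e-12 | object@normalized > 1 + 1e-12))
      msg <- c(msg, "normalized values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Narrow-width statistic of a focus curve
#'
#' Widths (in fractional frame indices, by linear interpolation) of the
#' normalised focus curve's level sets at 0.4 (\code{alpha}) and 0.8
#' (\code{beta}) around the peak, and their ratio \code{beta/alpha}. A ratio
#' closer to 1 means a steeper, more discriminative curve; for a unimodal
#' curve the 0.8-level set nests inside the 0.4-level set, so the ratio lies
#' in (0, 1].
#'
#' @slot alpha numeric, level-set width at 0.4.
#' @slot beta numeric, level-set width at 0.8.
#' @slot ratio numeric, \code{beta / alpha}.
#' @slot truncated logical, TRUE when a level was never crossed inside the
#'   frame range and the width was clipped to the observed range.
#' @seealso [narrowWidth()]
#' @export
setClass("NarrowWidthResult", representation(
  alpha = "numeric",
  beta = "numeric",
  ratio = "numeric",
  truncated = "logical"
))

#' Unimodality diagnostics of a focus curve
#'
#' @slot argmaxFrame integer, 1-based index of the global maximum (first
#'   frame of a tied plateau).
#' @slot nLocalMaxima integer, count of local maxima of the normalised curve
#'   (plateaus collapse to their leftmost frame; endpoints count only when
#'   strictly above their single neighbour; 0 for a constant curve).
#' @slot isUnimodal logical, TRUE iff exactly one local maximum.
#' @slot maxSecondaryPeak numeric, height (normalised) of the tallest
#'   non-global local maximum, 0 if none.
#' @seealso [diagnoseCurve()]
#' @export
setClass("CurveDiagnostics", representation(
  argmaxFrame = "integer",
  nLocalMaxima = "integer",
  isUnimodal = "logical",
  maxSecondaryPeak = "numeric"
))

#' Energy breakdown of the shearlet sharpness score
#'
#' Intermediate quantities of the sharpness evaluation: the low-frequency
#' energy EL (variance of the low sub-band), the per-scale summed directional
#' variances SV, the per-scale weighted energies EkH = SV_k / 2^k, the
#' weighted total high-frequency energy EH, and the final score
#' h = EH / EL.
#'
#' @slot EL numeric, low-frequency energy.
#' @slot SV numeric vector, per-scale sum over directions of sub-band
#'   variances (scale 1 = finest).
#' @slot EkH numeric vector, \code{SV / 2^k}.
#' @slot EH numeric, \code{s * EkH[1] + (1 - s) * sum(EkH[-1]) / w}.
#' @slot h numeric, \code{EH / max(EL, epsilon)}; 0 for a featureless image.
#' @seealso [nsstEnergyBreakdown()], [nsstSharpness()]
#' @export
setClass("EnergyBreakdown", representation(
  EL = "numeric",
  SV = "numeric",
  EkH = "numeric",
  EH = "numeric",
  h = "numeric"
))

#' Parameters of the shearlet sharpness score
#'
#' @slot s weight on the finest high-frequency energy, in [0, 1]
#'   (default 0.8).
#' @slot w divisor applied to the summed coarser-scale energies
#'   (default 3).
#' @slot epsilon positive guard for the low-frequency denominator
#'   (default 1e-12); a featureless image scores 0 rather than 0/0.
#' @slot nsst the [NSSTConfig-class] used for decomposition.
#' @export
setClass("NSSTSharpnessParams", representation(
  s = "numeric",
  w = "numeric",
  epsilon = "numeric",
  nsst = "NSSTConfig"
))

setValidity("NSSTSharpnessParams", function(object) {
  msg <- character()
  if (object@s < 0 || object@s > 1) msg <- c(msg, "s must lie in [0, 1]")
  if (object@w <= 0) msg <- c(msg, "w must be positive")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Create sharpness-score parameters
#'
#' Defaults are the operating point of the method: s = 0.8 puts the dominant
#' weight on the finest (most defocus-sensitive) scale, and the coarser-scale
#' sum is divided by w = 3.
#'
#' @param s weight on the finest-scale energy.
#' @param w divisor for the coarser-scale energy sum.
#' @param epsilon denominator guard.
#' @param nsst an [NSSTConfig-class].
#' @return An [NSSTSharpnessParams-class].
#' @examples
#' nsstSharpnessParams()
#' @export
nsstSharpnessParams <- function(s = 0.8, w = 3, epsilon = 1e-12,
                                nsst = nsstConfig()) {
  new("NSSTSharpnessParams", s = as.numeric(s), w = as.numeric(w),
      epsilon = as.numeric(epsilon), nsst = nsst)
}

#' Declarative description of a noise injection
#'
#' @slot kind \code{"gaussian"}, \code{"salt_pepper"} or \code{"poisson"}.
#' @slot density for salt_pepper the fraction of corrupted pixels (default
#'   0.1); for gaussian the variance of additive zero-mean noise on the
#'   [0, 1] scale (default 0.01); unused for poisson.
#' @slot seed integer seed making the injection reproducible.
#' @slot mode salt-and-pepper corruption convention: \code{"exact"} corrupts
#'   exactly \code{round(density * MN)} pixels, \code{"bernoulli"} corrupts
#'   each pixel independently with probability \code{density}.
#' @slot quantLevels Poisson quantisation: each pixel becomes a Poisson draw
#'   of mean \code{pixel * quantLevels} scaled back (default 255).
#' @seealso [addNoise()]
#' @export
setClass("NoiseSpec", representation(
  kind = "character",
  density = "numeric",
  seed = "integer",
  mode = "character",
  quantLevels = "numeric"
))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("gaussian", "salt_pepper", "poisson"))
    msg <- c(msg, "kind must be gaussian, salt_pepper or poisson")
  if (object@density < 0 || object@density > 1)
    msg <- c(msg, "density must lie in [0, 1]")
  if (!object@mode %in% c("exact", "bernoulli"))
    msg <- c(msg, "mode must be 'exact' or 'bernoulli'")
  if (object@quantLevels < 1)
    msg <- c(msg, "quantLevels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a noise specification
#'
#' @param kind noise family: \code{"gaussian"}, \code{"salt_pepper"},
#'   \code{"poisson"}.
#' @param density noise level; see [NoiseSpec-class].
#' @param seed integer seed.
#' @param mode salt-and-pepper convention, \code{"exact"} (default) or
#'   \code{"bernoulli"}.
#' @param quantLevels Poisson quantisation levels (default 255).
#' @return A [NoiseSpec-class].
#' @examples
#' noiseSpec("salt_pepper", density = 0.1, seed = 7)
#' @export
noiseSpec <- function(kind, density = if (kind == "gaussian") 0.01 else 0.1,
                      seed = 1L, mode = "exact", quantLevels = 255) {
  new("NoiseSpec", kind = kind, density = as.numeric(density),
      seed = as.integer(seed), mode = mode,
      quantLevels = as.numeric(quantLevels))
}

#' Declarative description of a denoising pre-filter
#'
#' @slot kind \code{"none"}, \code{"bilateral"} or \code{"guided"}.
#' @slot spatialSigma bilateral spatial Gaussian sigma in pixels (default 3).
#' @slot rangeSigma bilateral range Gaussian sigma in intensity units
#'   (default 0.1).
#' @slot radius guided-filter window radius in pixels (default 4).
#' @slot regularization guided-filter edge-awareness regulariser
#'   (default 0.01).
#' @seealso [denoise()]
#' @export
setClass("FilterSpec", representation(
  kind = "character",
  spatialSigma = "numeric",
  rangeSigma = "numeric",
  radius = "integer",
  regularization = "numeric"
))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "bilateral", "guided"))
    msg <- c(msg, "kind must be none, bilateral or guided")
  if (object@kind == "bilateral" &&
      (object@spatialSigma <= 0 || object@rangeSigma <= 0))
    msg <- c(msg, "bilateral sigmas must be positive")
  if (object@kind == "guided" &&
      (object@radius < 1L || object@regularization <= 0))
    msg <- c(msg, "guided radius must be >= 1 and regularization positive")
  if (length(msg)) msg else TRUE
})

#' Create a filter specification
#'
#' @param kind \code{"none"}, \code{"bilateral"} or \code{"guided"}.
#' @param spatialSigma,rangeSigma bilateral-filter sigmas.
#' @param radius,regularization guided-filter parameters.
#' @return A [FilterSpec-class].
#' @examples
#' filterSpec("bilateral")
#' @export
filterSpec <- function(kind = "none", spatialSigma = 3, rangeSigma = 0.1,
                       radius = 4L, regularization = 0.01) {
  new("FilterSpec", kind = kind, spatialSigma = as.numeric(spatialSigma),
      rangeSigma = as.numeric(rangeSigma), radius = as.integer(radius),
      regularization = as.numeric(regularization))
}

#' Specification of a synthetic cell phantom
#'
#' Describes the in-focus scene the stack generator renders: sparse, bright,
#' quasi-circular cell-like objects with granular interior texture on a
#' near-uniform background with mild low-frequency shading — the image
#' statistics of sparse sediment cells in a microscope field.
#'
#' @slot height,width image size in pixels (default 256 x 256).
#' @slot nCells number of cells (default 12).
#' @slot radiusRange numeric(2), min/max cell radius in pixels (default
#'   6--14).
#' @slot cellContrast cell brightness above background (default 0.35).
#' @slot backgroundLevel background intensity (default 0.55).
#' @slot textureAmplitude amplitude of intra-cell granular texture
#'   (default 0.08).
#' @slot seed integer seed; the phantom is a pure function of the spec.
#' @seealso [makePhantom()]
#' @export
setClass("PhantomSpec", representation(
  height = "integer", width = "integer", nCells = "integer",
  radiusRange = "numeric", cellContrast = "numeric",
  backgroundLevel = "numeric", textureAmplitude = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@height < 32L || object@width < 32L)
    msg <- c(msg, "phantom must be at least 32 x 32")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (length(object@radiusRange) != 2L ||
      any(object@radiusRange <= 0) ||
      object@radiusRange[1] > object@radiusRange[2])
    msg <- c(msg, "radiusRange must be positive and ordered")
  hi <- object@backgroundLevel + object@cellContrast + object@textureAmplitude
  lo <- object@backgroundLevel - object@textureAmplitude - 0.05
  if (hi > 1.02 || lo < -0.02)
    msg <- c(msg, "background +/- contrast and texture must stay near [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' @param height,width image size in pixels.
#' @param nCells number of non-overlapping cells.
#' @param radiusRange numeric(2) cell radius range in pixels.
#' @param cellContrast cell brightness above background.
#' @param backgroundLevel background intensity.
#' @param textureAmplitude intra-cell texture amplitude.
#' @param seed integer seed.
#' @return A [PhantomSpec-class].
#' @examples
#' phantomSpec(nCells = 5, seed = 2)
#' @export
phantomSpec <- function(height = 256L, width = 256L, nCells = 12L,
                        radiusRange = c(6, 14), cellContrast = 0.35,
                        backgroundLevel = 0.55, textureAmplitude = 0.08,
                        seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nCells = as.integer(nCells), radiusRange = as.numeric(radiusRange),
      cellContrast = as.numeric(cellContrast),
      backgroundLevel = as.numeric(backgroundLevel),
      textureAmplitude = as.numeric(textureAmplitude),
      seed = as.integer(seed))
}

#' Specification of a defocus sweep
#'
#' Maps frame index to defocus blur. The default profile is
#' \code{|i - peakFrame| * 0.6} pixels of blur sigma: zero exactly at the
#' in-focus frame and strictly increasing away from it, giving the
#' defocus--focus--defocus shape of a through-focus acquisition.
#'
#' @slot nFrames number of frames (default 21).
#' @slot peakFrame 1-based index of the in-focus frame (default centre).
#' @slot blurSigmas numeric vector of per-frame blur sigmas in pixels.
#' @slot psf point-spread-function family, \code{"gaussian"} or
#'   \code{"disk"}.
#' @seealso [makeStack()]
#' @export
setClass("SweepSpec", representation(
  nFrames = "integer",
  peakFrame = "integer",
  blurSigmas = "numeric",
  psf = "character"
))

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (object@nFrames < 3L) msg <- c(msg, "a sweep needs at least 3 frames")
  if (object@peakFrame < 1L || object@peakFrame > object@nFrames)
    msg <- c(msg, "peakFrame must index a frame")
  if (length(object@blurSigmas) != object@nFrames)
    msg <- c(msg, "one blur sigma per frame is required")
  else {
    p <- object@peakFrame
    if (object@blurSigmas[p] != 0)
      msg <- c(msg, "blur sigma must be 0 at the peak frame")
    left <- object@blurSigmas[seq_len(p)]
    right <- object@blurSigmas[p:object@nFrames]
    if (length(left) > 1L && is.unsorted(rev(left), strictly = TRUE))
      msg <- c(msg, "blur sigma must strictly decrease towards the peak")
    if (length(right) > 1L && is.unsorted(right, strictly = TRUE))
      msg <- c(msg, "blur sigma must strictly increase after the peak")
  }
  if (!object@psf %in% c("gaussian", "disk"))
    msg <- c(msg, "psf must be 'gaussian' or 'disk'")
  if (length(msg)) msg else TRUE
})

#' Create a defocus-sweep specification
#'
#' @param nFrames number of frames.
#' @param peakFrame in-focus frame (default centre frame).
#' @param step blur-sigma increment per frame of defocus (pixels,
#'   default 0.6).
#' @param blurSigmas explicit per-frame sigmas overriding the linear
#'   profile.
#' @param psf \code{"gaussian"} (default) or \code{"disk"}.
#' @return A [SweepSpec-class].
#' @examples
#' sweepSpec(nFrames = 9, step = 1)
#' @export
sweepSpec <- function(nFrames = 21L, peakFrame = (nFrames + 1L) %/% 2L,
                      step = 0.6, blurSigmas = NULL, psf = "gaussian") {
  nFrames <- as.integer(nFrames)
  peakFrame <- as.integer(peakFrame)
  if (is.null(blurSigmas))
    blurSigmas <- abs(seq_len(nFrames) - peakFrame) * step
  new("SweepSpec", nFrames = nFrames, peakFrame = peakFrame,
      blurSigmas = as.numeric(blurSigmas), psf = psf)
}
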