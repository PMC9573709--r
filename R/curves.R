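# Focus curves and the evaluation statistics computed from them.

#' Score every frame of a focal stack
#'
#' Applies one sharpness measure to each frame and returns the raw scores
#' together with their min--max normalisation
#' \eqn{(x - \min)/(\max - \min)}; a constant raw curve normalises to all
#' zeros and is flagged.
#'
#' @param stack a [FocalStack-class].
#' @param measure a name from [sharpnessMeasures()].
#' @param params an [NSSTSharpnessParams-class] (used when
#'   \code{measure = "nsst"}).
#' @return A [FocusCurve-class].
#' @examples
#' stack <- makeStack(makePhantom(phantomSpec(seed = 3)),
#'                    sweepSpec(nFrames = 5, step = 1.5))
#' scoreStack(stack, "tenengrad")
#' @seealso [narrowWidth()], [diagnoseCurve()]
#' @export
scoreStack <- function(stack, measure = "nsst",
                       params = nsstSharpnessParams()) {
  stopifnot(is(stack, "FocalStack"))
  if (!measure %in% sharpnessMeasures())
    stop("unknown focus measure: ", measure, call. = FALSE)
  raw <- vapply(frames(stack), sharpnessScore, numeric(1),
                measure = measure, params = params)
  .focusCurve(raw, frameLabels(stack), measure)
}

.focusCurve <- function(raw, labels, measure) {
  rng <- range(raw)
  constant <- !is.finite(diff(rng)) || diff(rng) <= 0
  normalized <- if (constant) rep(0, length(raw)) else
    (raw - rng[1]) / diff(rng)
  new("FocusCurve", raw = as.numeric(raw), normalized = normalized,
      frameLabels = as.character(labels), measure = measure,
      constant = constant)
}

#' Build a focus curve from precomputed scores
#'
#' @param raw numeric vector of per-frame scores in acquisition order.
#' @param labels optional frame labels.
#' @param measure measure identifier to record.
#' @return A [FocusCurve-class].
#' @export
focusCurve <- function(raw, labels = as.character(seq_along(raw)),
                       measure = "custom") {
  .focusCurve(raw, labels, measure)
}

#' Narrow-width statistic of a focus curve
#'
#' Measures how steep a normalised focus curve is around its peak: the width
#' of its level set at 0.4 (\code{alpha}) and at 0.8 (\code{beta}), each the
#' distance in fractional frame indices between the outermost crossings of
#' the level on either side of the peak, found by linear interpolation
#' between adjacent samples. The reported statistic is
#' \code{ratio = beta / alpha}; for a unimodal curve the 0.8-level set nests
#' inside the 0.4-level set, so the ratio lies in (0, 1], and larger values
#' mean a steeper, more discriminative curve.
#'
#' When the curve never descends through a level inside the frame range (or
#' inside the requested peak's basin), the width is clipped to the observed
#' range, a warning is raised and the result is flagged truncated.
#'
#' @param curve a [FocusCurve-class]; must be non-constant with a unique
#'   global maximum (or supply \code{peak}).
#' @param peak optional 1-based frame index selecting one peak of a
#'   multi-modal curve; the search is then restricted to that peak's basin
#'   (out to the nearest local minima) and levels are measured relative to
#'   that peak's height.
#' @return A [NarrowWidthResult-class].
#' @examples
#' tri <- focusCurve(pmax(0, 1 - abs(seq_len(21) - 11) / 10))
#' narrowWidth(tri)  # alpha 12, beta 4, ratio 1/3
#' @export
narrowWidth <- function(curve, peak = NULL) {
  stopifnot(is(curve, "FocusCurve"))
  if (curve@constant)
    stop("narrow width is undefined for a constant curve", call. = FALSE)
  y <- curve@normalized
  n <- length(y)
  if (is.null(peak)) {
    mx <- which(y == max(y))
    if (length(mx) > 1L)
      stop("curve has tied global maxima; pass `peak` to pick one",
           call. = FALSE)
    peak <- mx
    lo <- 1L; hi <- n
    peakVal <- 1
  } else {
    peak <- as.integer(peak)
    stopifnot(peak >= 1L, peak <= n)
    lo <- peak; while (lo > 1L && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- peak; while (hi < n && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    peakVal <- y[peak]
    if (peakVal <= 0)
      stop("selected peak has zero normalised height", call. = FALSE)
  }
  widthAt <- function(level) {
    L <- level * peakVal
    truncated <- FALSE
    # leftmost (outermost) crossing between lo..peak
    left <- NA_real_
    for (i in seq(lo, max(lo, peak - 1L))) {
      if (peak == lo) break
      y0 <- y[i]; y1 <- y[i + 1L]
      if ((y0 < L && y1 >= L) || (y0 >= L && y1 < L)) {
        left <- i + (L - y0) / (y1 - y0)
        break
      }
    }
    if (is.na(left)) {
      if (y[lo] >= L) { left <- lo; truncated <- TRUE } else left <- peak
    }
    right <- NA_real_
    for (i in seq(min(hi, peak + 1L), hi)) {
      if (peak == hi) break
      y0 <- y[i - 1L]; y1 <- y[i]
      if ((y0 >= L && y1 < L) || (y0 < L && y1 >= L)) right <- (i - 1L) + (L - y0) / (y1 - y0)
    }
    if (is.na(right)) {
      if (y[hi] >= L) { right <- hi; truncated <- TRUE } else right <- peak
    }
    list(width = right - left, truncated = truncated)
  }
  a <- widthAt(0.4)
  b <- widthAt(0.8)
  if (a$truncated || b$truncated)
    warning("focus curve does not cross a level inside the frame range; ",
            "width clipped to the observed range", call. = FALSE)
  if (a$width <= 0)
    stop("degenerate zero width at the 0.4 level", call. = FALSE)
  new("NarrowWidthResult", alpha = a$width, beta = b$width,
      ratio = b$width / a$width,
      truncated = a$truncated || b$truncated)
}

#' Unimodality diagnostics of a focus curve
#'
#' Counts local maxima of the normalised curve. Runs of equal values
#' (plateaus) collapse to a single candidate at the plateau's leftmost
#' frame; an interior maximum must be strictly greater than both
#' neighbouring runs, an endpoint strictly greater than its single
#' neighbour. A constant curve has 0 local maxima and is not unimodal.
#'
#' @param curve a [FocusCurve-class].
#' @return A [CurveDiagnostics-class].
#' @examples
#' diagnoseCurve(focusCurve(c(0, 1, 0, 0.6, 0)))
#' @export
diagnoseCurve <- function(curve) {
  stopifnot(is(curve, "FocusCurve"))
  y <- curve@normalized
  n <- length(y)
  if (n == 0L) stop("empty curve", call. = FALSE)
  if (curve@constant || n == 1L)
    return(new("CurveDiagnostics",
               argmaxFrame = 1L, nLocalMaxima = 0L, isUnimodal = FALSE,
               maxSecondaryPeak = 0))
  r <- rle(y)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(v)
  isMax <- logical(k)
  for (i in seq_len(k)) {
    leftOK <- i == 1L || v[i] > v[i - 1L]
    rightOK <- i == k || v[i] > v[i + 1L]
    isMax[i] <- leftOK && rightOK
  }
  peakFrames <- starts[isMax]
  peakVals <- v[isMax]
  gmax <- which.max(peakVals)
  secondary <- if (length(peakVals) > 1L) max(peakVals[-gmax]) else 0
  new("CurveDiagnostics",
      argmaxFrame = as.integer(peakFrames[gmax]),
      nLocalMaxima = length(peakFrames),
      isUnimodal = length(peakFrames) == 1L,
      maxSecondaryPeak = as.numeric(secondary))
}

#' Export a set of focus curves as a tidy table
#'
#' @param curves a [FocusCurve-class] or list of them.
#' @return data.frame with columns \code{frame_label}, \code{measure},
#'   \code{raw}, \code{normalized}.
#' @seealso [scoreStack()]
#' @export
curveTable <- function(curves) {
  if (is(curves, "FocusCurve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv)
    data.frame(frame_label = cv@frameLabels, measure = cv@measure,
               raw = cv@raw, normalized = cv@normalized,
               stringsAsFactors = FALSE)))
}

#' Curve metrics as a JSON-ready record
#'
#' Combines [narrowWidth()] and [diagnoseCurve()] for one curve into a flat
#' list. When the narrow width is undefined (constant curve, tied maxima) or
#' truncated, that is recorded instead of failing.
#'
#' @param curve a [FocusCurve-class].
#' @param peak optional peak frame forwarded to [narrowWidth()].
#' @return named list.
#' @export
curveMetrics <- function(curve, peak = NULL) {
  diag <- diagnoseCurve(curve)
  out <- list(
    measure = curve@measure,
    constant = curve@constant,
    argmax_frame = diag@argmaxFrame,
    n_local_maxima = diag@nLocalMaxima,
    is_unimodal = diag@isUnimodal,
    max_secondary_peak = diag@maxSecondaryPeak
  )
  nw <- if (curve@constant) NULL else tryCatch(
    suppressWarnings(narrowWidth(curve, peak = peak)),
    error = function(e) NULL)
  if (is.null(nw)) {
    out$narrow_width <- NA_real_
  } else {
    out$narrow_width_alpha <- nw@alpha
    out$narrow_width_beta <- nw@beta
    out$narrow_width <- nw@ratio
    out$narrow_width_truncated <- nw@truncated
  }
  out
}
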