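# Sharpness measures: the shearlet-variance score and the classical focus
# measures used for comparison.

#' Population variance of a coefficient array
#'
#' The variance focus measure: mean squared deviation from the array mean,
#' dividing by the pixel count MN (population form, not MN - 1). Squaring
#' amplifies larger excursions from the mean intensity, which is what makes
#' the statistic respond to focus.
#'
#' @param coeffs non-empty numeric matrix (or vector).
#' @return non-negative scalar.
#' @examples
#' subbandVariance(matrix(c(0, 0, 1, 1), 2))  # 0.25
#' @export
subbandVariance <- function(coeffs) {
  if (length(coeffs) == 0L)
    stop("cannot take the variance of an empty array", call. = FALSE)
  if (!is.numeric(coeffs))
    stop("coefficients must be numeric", call. = FALSE)
  mean((coeffs - mean(coeffs))^2)
}

#' Energy breakdown of the shearlet sharpness score
#'
#' Decomposes the image with [nsstDecompose()] and aggregates per-sub-band
#' variances into the sharpness score: the low-frequency energy is
#' \eqn{E_L = V(\mathrm{low})}; at each scale k the directional variances are
#' summed, \eqn{SV_k = \sum_l V_{k,l}}; each scale is weighted as
#' \eqn{E_k^H = SV_k / 2^k} (k = 1 the finest); the total high-frequency
#' energy is \eqn{E^H = s E_1^H + (1-s) \sum_{k \ge 2} E_k^H / w}; and the
#' score is \eqn{h = E^H / E_L}. The low band carries the slowly varying
#' background that dominates sparse cell images, so dividing by its energy
#' suppresses background and noise influence; with the defaults s = 0.8 and
#' w = 3 most of the weight sits on the finest, most defocus-sensitive
#' scale.
#'
#' A featureless (constant) image has all variances zero; the epsilon guard
#' in the denominator makes its score 0, ranking it below any structured
#' frame.
#'
#' @param image numeric matrix in [0, 1].
#' @param params an [NSSTSharpnessParams-class].
#' @return An [EnergyBreakdown-class].
#' @examples
#' img <- makePhantom(phantomSpec(height = 64, width = 64, nCells = 3))
#' nsstEnergyBreakdown(img, nsstSharpnessParams(nsst = nsstConfig(2, c(4, 4))))
#' @seealso [nsstSharpness()], [baselineSharpness()]
#' @export
nsstEnergyBreakdown <- function(image, params = nsstSharpnessParams()) {
  stopifnot(is(params, "NSSTSharpnessParams"))
  validObject(params)
  sb <- nsstDecompose(image, params@nsst)
  EL <- subbandVariance(sb@low)
  SV <- vapply(sb@high, function(bands)
    sum(vapply(bands, subbandVariance, numeric(1))), numeric(1))
  EkH <- SV / 2^seq_along(SV)
  EH <- params@s * EkH[1L] +
    (1 - params@s) * (if (length(EkH) > 1L) sum(EkH[-1L]) else 0) / params@w
  h <- EH / max(EL, params@epsilon)
  new("EnergyBreakdown", EL = EL, SV = unname(SV), EkH = unname(EkH),
      EH = unname(EH), h = unname(h))
}

#' Shearlet sharpness score of one image
#'
#' Convenience wrapper returning only the final score h of
#' [nsstEnergyBreakdown()].
#'
#' @inheritParams nsstEnergyBreakdown
#' @return non-negative scalar.
#' @export
nsstSharpness <- function(image, params = nsstSharpnessParams()) {
  nsstEnergyBreakdown(image, params)@h
}

#' Measure identifiers known to the package
#' @return character vector of valid measure names.
#' @export
sharpnessMeasures <- function() {
  c("nsst", "tenengrad", "roberts", "laplacian", "eog", "dct", "canny",
    "variance")
}

#' Classical baseline focus measures
#'
#' Standard single-image focus measures used as comparison points for the
#' shearlet score. All return a non-negative scalar that is 0 on a constant
#' image:
#' \describe{
#'   \item{tenengrad}{sum of squared Sobel gradient responses,
#'     \eqn{\sum G_x^2 + G_y^2}.}
#'   \item{roberts}{sum of squared Roberts-cross diagonal differences.}
#'   \item{laplacian}{sum of squared 3x3 Laplacian responses.}
#'   \item{eog}{energy of gradient: sum of squared forward differences in
#'     both axes.}
#'   \item{dct}{fraction of AC spectral energy carried by high-frequency
#'     DCT coefficients (index sum above a cutoff, default a quarter of the
#'     maximal index sum).}
#'   \item{canny}{fraction of pixels marked edge by a Canny detector
#'     (Gaussian sigma 1, hysteresis thresholds 0.1/0.2 of the gradient
#'     range).}
#'   \item{variance}{population variance of the whole image.}
#' }
#' Derivative stencils use replicate borders, so a constant image scores
#' exactly 0 for every method.
#'
#' @param image numeric matrix in [0, 1].
#' @param method one of \code{"tenengrad"}, \code{"roberts"},
#'   \code{"laplacian"}, \code{"eog"}, \code{"dct"}, \code{"canny"},
#'   \code{"variance"}.
#' @param dctCutoff index-sum cutoff for the DCT high band; default
#'   \code{(M + N - 2) / 4}.
#' @param cannySigma,cannyLow,cannyHigh Canny smoothing sigma and hysteresis
#'   thresholds as fractions of the gradient range.
#' @return non-negative scalar.
#' @examples
#' step <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
#' baselineSharpness(step, "tenengrad")
#' @seealso [nsstSharpness()], [sharpnessScore()]
#' @export
baselineSharpness <- function(image,
                              method = c("tenengrad", "roberts", "laplacian",
                                         "eog", "dct", "canny", "variance"),
                              dctCutoff = NULL, cannySigma = 1,
                              cannyLow = 0.1, cannyHigh = 0.2) {
  if (length(method) != 1L || !method %in% c("tenengrad", "roberts",
                                             "laplacian", "eog", "dct",
                                             "canny", "variance"))
    stop("unknown focus measure: ",
         paste(method, collapse = ", "), call. = FALSE)
  .validateImage(image)
  switch(method,
         tenengrad = .fmTenengrad(image),
         roberts = .fmRoberts(image),
         laplacian = .fmLaplacian(image),
         eog = .fmEOG(image),
         dct = .fmDCT(image, dctCutoff),
         canny = .fmCanny(image, cannySigma, cannyLow, cannyHigh),
         variance = subbandVariance(image))
}

#' Score one image with any measure
#'
#' Uniform entry point dispatching to [nsstSharpness()] for
#' \code{measure = "nsst"} and to [baselineSharpness()] otherwise.
#'
#' @param image numeric matrix in [0, 1].
#' @param measure a name from [sharpnessMeasures()].
#' @param params an [NSSTSharpnessParams-class] (used by \code{"nsst"}).
#' @return non-negative scalar.
#' @export
sharpnessScore <- function(image, measure = "nsst",
                           params = nsstSharpnessParams()) {
  if (identical(measure, "nsst")) return(nsstSharpness(image, params))
  baselineSharpness(image, measure)
}

.sobelPair <- function(x) {
  up <- .clampShift(x, -1L, 0L); dn <- .clampShift(x, 1L, 0L)
  lf <- .clampShift(x, 0L, -1L); rt <- .clampShift(x, 0L, 1L)
  ul <- .clampShift(x, -1L, -1L); ur <- .clampShift(x, -1L, 1L)
  dl <- .clampShift(x, 1L, -1L); dr <- .clampShift(x, 1L, 1L)
  list(gx = (ur + 2 * rt + dr) - (ul + 2 * lf + dl),   # column gradient
       gy = (dl + 2 * dn + dr) - (ul + 2 * up + ur))   # row gradient
}

.fmTenengrad <- function(x) {
  g <- .sobelPair(x)
  sum(g$gx^2 + g$gy^2)
}

.fmRoberts <- function(x) {
  n <- nrow(x); m <- ncol(x)
  a <- x[-n, -m] - x[-1, -1]
  b <- x[-n, -1] - x[-1, -m]
  sum(a^2) + sum(b^2)
}

.fmLaplacian <- function(x) {
  lap <- .clampShift(x, -1L, 0L) + .clampShift(x, 1L, 0L) +
    .clampShift(x, 0L, -1L) + .clampShift(x, 0L, 1L) - 4 * x
  sum(lap^2)
}

.fmEOG <- function(x) {
  n <- nrow(x); m <- ncol(x)
  dv <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
  dh <- x[, -1, drop = FALSE] - x[, -m, drop = FALSE]
  sum(dv^2) + sum(dh^2)
}

# Orthonormal DCT-II basis matrix.
.dctMatrix <- function(n) {
  k <- seq_len(n) - 1
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- sqrt(1 / n)
  D
}

.fmDCT <- function(x, cutoff = NULL) {
  n <- nrow(x); m <- ncol(x)
  C <- .dctMatrix(n) %*% x %*% t(.dctMatrix(m))
  if (is.null(cutoff)) cutoff <- (n + m - 2) / 4
  idxSum <- outer(seq_len(n) - 1, seq_len(m) - 1, `+`)
  e <- C^2
  dc <- e[1, 1]
  e[1, 1] <- 0                       # drop DC
  acTotal <- sum(e)
  # round-off AC energy on a (near-)constant image is not signal
  if (acTotal <= 1e-12 * (dc + acTotal)) return(0)
  sum(e[idxSum > cutoff]) / acTotal
}

.fmCanny <- function(x, sigma = 1, low = 0.1, high = 0.2) {
  xs <- .gaussianBlurFFT(x, sigma)
  g <- .sobelPair(xs)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax <= 0) return(0)
  # non-maximum suppression along the quantised gradient direction
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5) %% 4) + 1  # 1:E-W 2:NE-SW 3:N-S 4:NW-SE
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(x), ncol(x))
  for (s in 1:4) {
    o <- offs[[s]]
    fwd <- .clampShift(mag, o[1], o[2])
    bwd <- .clampShift(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag >= fwd & mag >= bwd)
  }
  thin <- mag * keep
  strong <- thin >= high * mmax
  weak <- thin >= low * mmax
  # hysteresis: grow strong edges through weak pixels (8-connected)
  repeat {
    grown <- strong
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      grown <- grown | .clampShift(strong, di, dj)
    }
    grown <- grown & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  mean(strong)
}
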