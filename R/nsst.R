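# Non-subsampled shearlet transform.
#
# The bank is built entirely in the frequency domain as an additive partition
# of unity: radial (max-norm) scale windows with a smooth transition
# telescope across scales, and angular Meyer-bump wedges split each
# high-frequency annulus by orientation. Because the windows sum to one at
# every frequency, synthesis is plain summation, so perfect reconstruction,
# linearity, shift equivariance (all convolutions are circular) and the
# directional-partition identity hold exactly, up to FFT round-off.

# Smooth transition profiles: 1 for r <= lo, 0 for r >= hi.
# "maxflat" uses the polynomial nu(t) = t^4 (35 - 84 t + 70 t^2 - 20 t^3),
# maximally flat at both ends and satisfying nu(t) + nu(1 - t) = 1;
# "cosine" is the raised-cosine profile with the same complementarity.
.transitionStep <- function(r, lo, hi, id) {
  t <- pmin(pmax((r - lo) / (hi - lo), 0), 1)
  if (id == "maxflat") {
    nu <- t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
  } else {
    nu <- sin(pi * t / 2)^2
  }
  1 - nu
}

# Radial scale windows on an n x m grid: a list of nScales high-pass windows
# (element 1 = finest) plus the low-pass residual, summing to 1 pointwise.
.scaleWindows <- function(n, m, nScales, id) {
  fx <- abs(.fftFreq(n)) / 0.5
  fy <- abs(.fftFreq(m)) / 0.5
  rho <- outer(fx, fy, pmax)                   # max-norm radius in [0, 1]
  prevLow <- matrix(1, n, m)
  high <- vector("list", nScales)
  for (j in seq_len(nScales)) {
    Lj <- .transitionStep(rho, 2^(-j), 2^(-j + 1), id)
    high[[j]] <- prevLow - Lj
    prevLow <- Lj
  }
  list(high = high, low = prevLow)
}

# Angular wedge windows partitioning orientation space [0, pi) into nDir
# overlapping Meyer bumps summing to 1; symmetrised over frequency negation
# so that filtering a real band yields exactly real sub-bands.
.angularWindows <- function(n, m, nDir, id) {
  fx <- .fftFreq(n)
  fy <- .fftFreq(m)
  theta <- atan2(rep(fy, each = n), rep(fx, times = m)) %% pi
  theta <- matrix(theta, n, m)
  delta <- pi / nDir
  # bump: nu-shaped rise on [-1, 0], fall on [0, 1], in units of delta
  bump <- function(t, id) {
    out <- numeric(length(t))
    a <- t >= -1 & t <= 0
    b <- t > 0 & t <= 1
    out[a] <- 1 - .transitionStep(1 + t[a], 0, 1, id)
    out[b] <- .transitionStep(t[b], 0, 1, id)
    out
  }
  conjIdxR <- c(1L, rev(seq_len(n - 1L) + 1L))
  conjIdxC <- c(1L, rev(seq_len(m - 1L) + 1L))
  wins <- vector("list", nDir)
  for (d in seq_len(nDir)) {
    u <- (theta / delta - (d - 1))
    u <- ((u + nDir / 2) %% nDir) - nDir / 2   # wrap to the nearest period
    W <- matrix(bump(as.vector(u), id), n, m)
    wins[[d]] <- (W + W[conjIdxR, conjIdxC]) / 2  # enforce evenness
  }
  wins
}

.checkNSSTSize <- function(image, nScales) {
  .validateImage(image)
  need <- max(32L, 2L^(nScales + 2L))
  if (nrow(image) < need || ncol(image) < need)
    stop(sprintf(
      "image %dx%d too small for %d-scale decomposition (needs >= %dx%d)",
      nrow(image), ncol(image), nScales, need, need), call. = FALSE)
  invisible(TRUE)
}

#' Non-subsampled pyramid decomposition
#'
#' Splits an image into \code{nScales} high-pass bands plus one low-pass
#' residual using radial frequency windows that telescope to a partition of
#' unity (the non-subsampled, a-trous analogue of a Laplacian pyramid). All
#' bands have the input's shape; summing them reproduces the input exactly.
#'
#' @param image numeric matrix in [0, 1] (or any real matrix).
#' @param nScales number of high-frequency scales (scale 1 = finest).
#' @param pyramidFilterId transition profile, \code{"maxflat"} or
#'   \code{"cosine"}.
#' @return list with elements \code{low} (matrix) and \code{bands} (list of
#'   matrices, finest first).
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' p <- nspDecompose(img, 3)
#' max(abs(Reduce(`+`, p$bands) + p$low - img))  # ~ 1e-15
#' @seealso [nsstDecompose()]
#' @export
nspDecompose <- function(image, nScales = 3L, pyramidFilterId = "maxflat") {
  nScales <- as.integer(nScales)
  if (nScales < 1L) stop("nScales must be >= 1", call. = FALSE)
  .checkNSSTSize(image, nScales)
  W <- .scaleWindows(nrow(image), ncol(image), nScales, pyramidFilterId)
  F <- .fft2(image)
  bands <- lapply(W$high, function(w) .applyFreqWindow(F, w))
  low <- .applyFreqWindow(F, W$low)
  list(low = low, bands = bands)
}

#' Shear-filter directional decomposition of one band
#'
#' Splits a (typically high-pass) coefficient array into \code{nDirections}
#' directional sub-bands by pointwise multiplication in the frequency domain
#' with a bank of smooth angular wedges tiling orientation space. The wedges
#' form a partition of unity, so the directional sub-bands sum back to the
#' input band exactly.
#'
#' @param band numeric matrix of coefficients.
#' @param nDirections power of two >= 2.
#' @param shearFilterSize nominal directional-filter support, recorded for
#'   provenance (the windows live on the full FFT grid).
#' @param pyramidFilterId transition profile shared with the pyramid.
#' @return list of \code{nDirections} matrices.
#' @seealso [nsstDecompose()]
#' @export
shearDecompose <- function(band, nDirections, shearFilterSize = 32L,
                           pyramidFilterId = "maxflat") {
  .validateImage(band)
  nDirections <- as.integer(nDirections)
  if (nDirections < 2L || !.isPow2(nDirections))
    stop("nDirections must be a power of two >= 2", call. = FALSE)
  W <- .angularWindows(nrow(band), ncol(band), nDirections, pyramidFilterId)
  F <- .fft2(band)
  lapply(W, function(w) .applyFreqWindow(F, w))
}

#' Non-subsampled shearlet decomposition
#'
#' Multiscale decomposition by the non-subsampled pyramid followed by
#' shear-filter directional splitting of each high-frequency band. The
#' result keeps the input's shape in every sub-band (translation
#' invariance): circularly shifting the input shifts every sub-band
#' identically, which is what suppresses pseudo-Gibbs artifacts in
#' shift-sensitive applications such as focus scoring.
#'
#' @param image numeric matrix, at least 32 x 32 (and at least
#'   \code{2^(nScales + 2)} per side).
#' @param config an [NSSTConfig-class].
#' @return A [SubbandSet-class].
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' sb <- nsstDecompose(img, nsstConfig(nScales = 2, directionsPerScale = c(4, 4)))
#' sb
#' max(abs(nsstReconstruct(sb) - img))  # ~ 1e-15
#' @seealso [nsstReconstruct()], [nsstSharpness()]
#' @export
nsstDecompose <- function(image, config = nsstConfig()) {
  stopifnot(is(config, "NSSTConfig"))
  validObject(config)
  p <- nspDecompose(image, config@nScales, config@pyramidFilterId)
  high <- vector("list", config@nScales)
  for (k in seq_len(config@nScales)) {
    high[[k]] <- shearDecompose(p$bands[[k]], config@directionsPerScale[k],
                                config@shearFilterSize,
                                config@pyramidFilterId)
  }
  new("SubbandSet", low = p$low, high = high, config = config)
}

#' Reconstruct an image from its shearlet sub-bands
#'
#' Validation-only inverse of [nsstDecompose()]: because the analysis
#' windows form a partition of unity, synthesis is the sum of the low band
#' and all directional sub-bands. The sharpness pipeline never calls this;
#' it exists to certify perfect reconstruction.
#'
#' @param subbands a [SubbandSet-class].
#' @return numeric matrix with the shape of the decomposed image.
#' @seealso [nsstDecompose()]
#' @export
nsstReconstruct <- function(subbands) {
  stopifnot(is(subbands, "SubbandSet"))
  validObject(subbands)
  out <- subbands@low
  for (bands in subbands@high)
    for (b in bands)
      out <- out + b
  out
}
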