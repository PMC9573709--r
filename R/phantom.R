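# Synthetic phantom and defocus sweep generator.

#' Render a synthetic cell phantom
#'
#' Draws a deterministic (seeded) in-focus scene with the image statistics
#' of sparse sediment cells under a microscope: \code{nCells} bright,
#' quasi-circular objects (smooth boundary perturbation of at most 20% of
#' the radius) with granular interior texture, placed without overlap and
#' fully inside the frame by rejection sampling, over a near-uniform
#' background with mild low-frequency shading. Interiors carry texture
#' because a perfectly flat disk would hold almost no fine-scale energy even
#' in focus, starving any high-frequency sharpness measure.
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric matrix in [0, 1] of size \code{height x width}.
#' @examples
#' img <- makePhantom(phantomSpec(nCells = 6, seed = 11))
#' range(img)
#' @seealso [makeStack()]
#' @export
makePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .withSeed(spec@seed, .renderPhantom(spec))
}

.renderPhantom <- function(spec) {
  h <- spec@height; w <- spec@width
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)

  # background: flat level plus mild low-frequency shading
  shadeAmp <- 0.02
  phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
  img <- spec@backgroundLevel +
    shadeAmp * sin(2 * pi * ii / h + phx) * cos(2 * pi * jj / w + phy)

  # place cells by rejection sampling: disjoint, fully inside the frame
  # (margins account for the <= 20% boundary perturbation)
  cells <- list()
  maxAttempts <- 200L * max(1L, spec@nCells)
  attempts <- 0L
  while (length(cells) < spec@nCells) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(
        paste0("could not place %d non-overlapping cells in a %dx%d frame ",
               "after %d attempts; reduce nCells or radiusRange"),
        spec@nCells, h, w, maxAttempts), call. = FALSE)
    r <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
    margin <- 1.25 * r + 2
    if (2 * margin >= min(h, w)) next
    ci <- stats::runif(1, margin, h - margin)
    cj <- stats::runif(1, margin, w - margin)
    ok <- TRUE
    for (cl in cells) {
      if (sqrt((ci - cl$i)^2 + (cj - cl$j)^2) < 1.25 * (r + cl$r) + 2) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # quasi-circular boundary: low-order harmonic perturbation <= 20% of r
    amp <- stats::runif(3, 0, 0.2 / 3)
    phase <- stats::runif(3, 0, 2 * pi)
    cells[[length(cells) + 1L]] <- list(i = ci, j = cj, r = r,
                                        amp = amp, phase = phase)
  }

  mask <- matrix(0, h, w)
  for (cl in cells) {
    di <- ii - cl$i; dj <- jj - cl$j
    d <- sqrt(di^2 + dj^2)
    box <- d <= 1.3 * cl$r + 2
    ang <- atan2(di[box], dj[box])
    rb <- cl$r * (1 + cl$amp[1] * cos(2 * ang + cl$phase[1]) +
                    cl$amp[2] * cos(3 * ang + cl$phase[2]) +
                    cl$amp[3] * cos(4 * ang + cl$phase[3]))
    # soft 1.2 px edge via a smoothstep on the signed distance
    t <- pmin(pmax((rb - d[box]) / 1.2 + 0.5, 0), 1)
    mask[box] <- pmax(mask[box], t * t * (3 - 2 * t))
  }

  img <- img + spec@cellContrast * mask
  if (spec@textureAmplitude > 0 && length(cells)) {
    tex <- .gaussianBlurFFT(matrix(stats::rnorm(h * w), h, w), 0.5)
    tex <- tex / stats::sd(tex) * spec@textureAmplitude
    img <- img + tex * mask
  }
  .clip01(img)
}

#' Render a focal stack by a parametric defocus sweep
#'
#' Frame i is the phantom convolved (circularly) with the point spread
#' function of blur sigma \code{blurSigmas[i]}; sigma 0 reproduces the
#' phantom exactly, so the in-focus frame is the phantom itself. The
#' Gaussian PSF uses its exact frequency response; the disk (pillbox) PSF —
#' the idealised defocused "circular light spot" — uses an anti-aliased
#' spatial kernel of radius sigma.
#'
#' @param phantom numeric matrix in [0, 1] (an in-focus scene).
#' @param sweep a [SweepSpec-class].
#' @return A [FocalStack-class] with labels \code{frame_01, ...}.
#' @examples
#' stack <- makeStack(makePhantom(phantomSpec(seed = 4)),
#'                    sweepSpec(nFrames = 7, step = 1))
#' stack
#' @seealso [makePhantom()], [scoreStack()]
#' @export
makeStack <- function(phantom, sweep = sweepSpec()) {
  stopifnot(is(sweep, "SweepSpec"))
  validObject(sweep)
  .validateImage(phantom)
  frames <- vector("list", sweep@nFrames)
  for (i in seq_len(sweep@nFrames)) {
    s <- sweep@blurSigmas[i]
    frames[[i]] <- if (s <= 0) phantom
    else if (sweep@psf == "gaussian") .gaussianBlurFFT(phantom, s)
    else .diskBlurFFT(phantom, s)
  }
  focalStack(frames, labels = sprintf("frame_%02d", seq_len(sweep@nFrames)))
}

# Circular convolution with an anti-aliased pillbox of the given radius.
.diskBlurFFT <- function(x, radius) {
  n <- nrow(x); m <- ncol(x)
  di <- .fftFreq(n) * n   # wrapped pixel offsets: 0, 1, ..., -1
  dj <- .fftFreq(m) * m
  d <- sqrt(outer(di^2, dj^2, `+`))
  k <- pmin(pmax(radius + 0.5 - d, 0), 1)   # linear edge anti-aliasing
  k <- k / sum(k)
  Re(.ifft2(.fft2(x) * .fft2(k)))
}

#' Generate the package's default synthetic focal stack
#'
#' Convenience wrapper: phantom plus sweep in one call, the study condition
#' every stack-level experiment runs on.
#'
#' @param phantom a [PhantomSpec-class].
#' @param sweep a [SweepSpec-class].
#' @return A [FocalStack-class].
#' @export
syntheticStack <- function(phantom = phantomSpec(), sweep = sweepSpec()) {
  makeStack(makePhantom(phantom), sweep)
}
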