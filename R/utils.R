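# Internal helpers shared across modules.

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Centred FFT frequencies in cycles/pixel, wrapped to [-1/2, 1/2).
.fftFreq <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# Real part of a circular frequency-domain filter application.
.applyFreqWindow <- function(F, W) Re(.ifft2(F * W))

# Circular Gaussian blur via its frequency response; sigma 0 is identity.
.gaussianBlurFFT <- function(x, sigma) {
  if (sigma <= 0) return(x)
  fx <- .fftFreq(nrow(x))
  fy <- .fftFreq(ncol(x))
  T <- exp(-2 * pi^2 * sigma^2 * outer(fx^2, fy^2, `+`))
  Re(.ifft2(.fft2(x) * T))
}

# Shift an image circularly by (di, dj) rows/columns.
.circShift <- function(x, di, dj) {
  n <- nrow(x); m <- ncol(x)
  i <- ((seq_len(n) - 1 - di) %% n) + 1
  j <- ((seq_len(m) - 1 - dj) %% m) + 1
  x[i, j, drop = FALSE]
}

# Index-clamped (replicate-border) shift used by local spatial filters.
.clampShift <- function(x, di, dj) {
  n <- nrow(x); m <- ncol(x)
  i <- pmin(pmax(seq_len(n) + di, 1L), n)
  j <- pmin(pmax(seq_len(m) + dj, 1L), m)
  x[i, j, drop = FALSE]
}

# Box filter (moving window sum) with edge-aware counts via padded cumsums.
.boxSum <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  cs <- apply(rbind(0, apply(x, 2, cumsum)), 1, cumsum)
  cs <- t(rbind(0, cs))  # (n+1) x (m+1) integral image
  i1 <- pmax(seq_len(n) - r, 1L); i2 <- pmin(seq_len(n) + r, n)
  j1 <- pmax(seq_len(m) - r, 1L); j2 <- pmin(seq_len(m) + r, m)
  cs[i2 + 1, j2 + 1] - cs[i1, j2 + 1] - cs[i2 + 1, j1] + cs[i1, j1]
}

.boxCount <- function(n, m, r) .boxSum(matrix(1, n, m), r)

.validateImage <- function(image, minSize = 1L) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  if (nrow(image) < minSize || ncol(image) < minSize)
    stop(sprintf("image must be at least %dx%d pixels", minSize, minSize),
         call. = FALSE)
  invisible(image)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)
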