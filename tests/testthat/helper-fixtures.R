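# Shared fixtures, all generated in code.

randImg <- function(n = 64, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

# Compact transform configuration for fast unit tests.
smallConfig <- function() nsstConfig(nScales = 2L, directionsPerScale = c(4L, 4L))
smallParams <- function() nsstSharpnessParams(nsst = smallConfig())

# Small phantom + short sweep for stack-level unit tests.
tinyStack <- function(seed = 5, nFrames = 7L, step = 1) {
  ph <- makePhantom(phantomSpec(height = 96L, width = 96L, nCells = 5L,
                                radiusRange = c(5, 9), seed = seed))
  makeStack(ph, sweepSpec(nFrames = nFrames, step = step))
}

writeGrayPNG <- function(mat, path = tempfile(fileext = ".png")) {
  EBImage::writeImage(EBImage::Image(t(mat)), path, type = "png")
  path
}
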