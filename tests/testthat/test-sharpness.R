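test_that("subbandVariance is the population variance", {
  expect_identical(subbandVariance(matrix(c(0, 0, 1, 1), 2)), 0.25)
  expect_identical(subbandVariance(matrix(0.7, 5, 5)), 0)

  # brute-force double-sum oracle on random arrays
  bruteVar <- function(g) {
    MN <- length(g); gbar <- sum(g) / MN
    acc <- 0
    for (i in seq_len(nrow(g)))
      for (j in seq_len(ncol(g)))
        acc <- acc + (g[i, j] - gbar)^2
    acc / MN
  }
  for (seed in 1:5) {
    g <- randImg(11, 7, seed = seed)
    expect_equal(subbandVariance(g), bruteVar(g), tolerance = 1e-12)
  }

  # shift invariance and error handling
  g <- randImg(8, seed = 9)
  expect_equal(subbandVariance(g + 3.2), subbandVariance(g),
               tolerance = 1e-10)
  expect_error(subbandVariance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the energy breakdown matches a literal composition of its equations", {
  params <- nsstSharpnessParams()   # s = 0.8, w = 3, 3 scales
  literal <- function(image, p) {
    sb <- nsstDecompose(image, p@nsst)
    EL <- subbandVariance(lowBand(sb))
    N <- nScales(sb)
    EkH <- numeric(N)
    for (k in seq_len(N)) {
      SVk <- 0
      for (d in highBands(sb, k)) SVk <- SVk + subbandVariance(d)
      EkH[k] <- SVk / 2^k
    }
    EH <- p@s * EkH[1] + (1 - p@s) * sum(EkH[-1]) / p@w
    EH / max(EL, p@epsilon)
  }
  for (seed in 1:20) {
    img <- randImg(64, seed = 100 + seed)
    got <- nsstEnergyBreakdown(img, params)
    expect_equal(got@h, literal(img, params), tolerance = 1e-12)
  }
})

test_that("the minimal one-scale configuration composes as expected", {
  # N = 1 scale, 2 directions, s = 1: h = (V(d1) + V(d2)) / 2 / V(low)
  p <- nsstSharpnessParams(s = 1, nsst = nsstConfig(1L, 2L))
  img <- randImg(64, seed = 31)
  sb <- nsstDecompose(img, p@nsst)
  expect_equal(
    nsstSharpness(img, p),
    (subbandVariance(highBands(sb, 1)[[1]]) +
       subbandVariance(highBands(sb, 1)[[2]])) / 2 /
      subbandVariance(lowBand(sb)),
    tolerance = 1e-12)
})

test_that("a featureless image scores zero and a sharp image beats its blur", {
  expect_identical(nsstSharpness(matrix(0.5, 64, 64), smallParams()), 0)
  eb <- nsstEnergyBreakdown(matrix(0.5, 64, 64), smallParams())
  expect_identical(eb@EL, 0)
  expect_identical(eb@EH, 0)

  sharp <- makePhantom(phantomSpec(height = 96L, width = 96L, nCells = 5L,
                                   seed = 12))
  blurred <- frames(makeStack(sharp, sweepSpec(3L, 1L,
                                               blurSigmas = c(0, 3, 6))))[[2]]
  expect_gt(nsstSharpness(sharp, smallParams()),
            nsstSharpness(blurred, smallParams()))
})

test_that("the shearlet score decreases monotonically with defocus blur", {
  ph <- makePhantom(phantomSpec(height = 96L, width = 96L, nCells = 5L,
                                seed = 13))
  sigmas <- seq(0, 5, by = 0.5)
  h <- vapply(sigmas, function(s) {
    f <- if (s == 0) ph else
      frames(makeStack(ph, sweepSpec(3L, 1L, blurSigmas = c(0, s, s + 1))))[[2]]
    nsstSharpness(f, smallParams())
  }, numeric(1))
  expect_true(all(diff(h) < 0))
})

test_that("the score is invariant to intensity shifts and circular shifts", {
  ph <- makePhantom(phantomSpec(height = 64L, width = 64L, nCells = 3L, radiusRange = c(4, 8),
                                seed = 14, backgroundLevel = 0.45))
  p <- smallParams()
  h0 <- nsstSharpness(ph, p)
  expect_equal(nsstSharpness(ph + 0.05, p), h0, tolerance = 1e-10)
  shifted <- ph[c(11:64, 1:10), c(30:64, 1:29)]
  expect_equal(nsstSharpness(shifted, p), h0, tolerance = 1e-10)
})

test_that("baseline measures vanish on constant images", {
  flat <- matrix(0.42, 48, 48)
  for (m in setdiff(sharpnessMeasures(), "nsst"))
    expect_identical(baselineSharpness(flat, m), 0)
})

test_that("tenengrad responds to an edge and only to it", {
  step <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  expect_gt(baselineSharpness(step, "tenengrad"), 0)
  expect_identical(baselineSharpness(matrix(1, 20, 20), "tenengrad"), 0)
})

test_that("energy of gradient matches direct evaluation on a ramp", {
  ramp <- matrix(rep(0:3, each = 6), nrow = 6)  # rows are [0, 1, 2, 3]
  # per row: 3 unit horizontal steps -> 3 per row, no vertical differences
  expect_identical(baselineSharpness(ramp, "eog"), 6 * 3)
})

test_that("remaining baselines react to structure and reject bad names", {
  img <- makePhantom(phantomSpec(height = 64L, width = 64L, nCells = 3L, radiusRange = c(4, 8),
                                 seed = 15))
  for (m in c("roberts", "laplacian", "dct", "canny", "variance"))
    expect_gt(baselineSharpness(img, m), 0)
  expect_error(baselineSharpness(img, "sobelx"), "unknown")
  expect_error(sharpnessScore(img, "prewitt"), "unknown")
})

test_that("every measure is intensity-shift invariant", {
  img <- makePhantom(phantomSpec(height = 64L, width = 64L, nCells = 3L, radiusRange = c(4, 8),
                                 seed = 16, backgroundLevel = 0.45))
  for (m in setdiff(sharpnessMeasures(), "nsst")) {
    a <- baselineSharpness(img, m)
    b <- baselineSharpness(img + 0.04, m)
    expect_equal(b, a, tolerance = 1e-8 * max(a, 1), label = m)
  }
})
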