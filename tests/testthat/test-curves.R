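test_that("scoreStack normalises scores per the min-max rule", {
  st <- tinyStack(seed = 21, nFrames = 5L)
  cv <- scoreStack(st, "variance")
  expect_s4_class(cv, "FocusCurve")
  expect_equal(sum(normScores(cv) == 1), 1)
  expect_equal(min(normScores(cv)), 0)
  expect_identical(frameLabels(cv), frameLabels(st))
  expect_error(scoreStack(st, "nope"), "unknown")

  # direct min-max arithmetic
  expect_equal(normScores(focusCurve(c(1, 3, 2))), c(0, 1, 0.5))

  # constant raw scores flag the curve and normalise to zero
  flat <- focusCurve(rep(2.5, 6))
  expect_true(flat@constant)
  expect_identical(normScores(flat), rep(0, 6))
})

test_that("narrow width is exact on a symmetric triangle", {
  tri <- focusCurve(pmax(0, 1 - abs(seq_len(21) - 11) / 10))
  nw <- narrowWidth(tri)
  expect_equal(nw@alpha, 12, tolerance = 1e-12)
  expect_equal(nw@beta, 4, tolerance = 1e-12)
  expect_equal(nw@ratio, 1 / 3, tolerance = 1e-12)
  expect_false(nw@truncated)
})

test_that("narrow width interpolates across a single-frame spike", {
  spike <- focusCurve(c(0, 0, 0, 1, 0, 0, 0))
  nw <- narrowWidth(spike)
  expect_equal(nw@alpha, 2 * 0.6, tolerance = 1e-12)
  expect_equal(nw@beta, 2 * 0.2, tolerance = 1e-12)
  expect_equal(nw@ratio, 1 / 3, tolerance = 1e-12)
})

test_that("narrow width converges to the Gaussian closed form", {
  x <- seq(-6, 6, length.out = 1201)
  gs <- focusCurve(exp(-x^2 / 2))
  nw <- narrowWidth(gs)
  expect_equal(nw@ratio, sqrt(log(1 / 0.8) / log(1 / 0.4)), tolerance = 1e-3)
})

test_that("narrow width is invariant under affine rescaling of raw scores", {
  set.seed(41)
  raw <- exp(-(seq_len(19) - 9)^2 / 12)
  a <- narrowWidth(focusCurve(raw))
  b <- narrowWidth(focusCurve(5 + 30 * raw))
  expect_equal(a@ratio, b@ratio, tolerance = 1e-12)
  expect_equal(a@alpha, b@alpha, tolerance = 1e-12)
})

test_that("narrow width stays in (0, 1] for unimodal curves", {
  set.seed(42)
  for (rep in 1:25) {
    peak <- sample(3:17, 1)
    width <- runif(1, 1.5, 6)
    raw <- exp(-(seq_len(19) - peak)^2 / (2 * width^2))
    nw <- suppressWarnings(narrowWidth(focusCurve(raw)))
    expect_gt(nw@ratio, 0)
    expect_lte(nw@ratio, 1 + 1e-12)
  }
})

test_that("level sets clipped at the frame range raise a truncation flag", {
  # monotone curve: the descent past the peak is cut off by the last frame
  raw <- c(0, 0.3, 0.6, 0.8, 1)
  expect_warning(nw <- narrowWidth(focusCurve(raw)), "clipped")
  expect_true(nw@truncated)
  expect_error(narrowWidth(focusCurve(rep(1, 5))), "constant")
  expect_error(narrowWidth(focusCurve(c(0, 1, 1, 0))), "tied")
})

test_that("a peak argument restricts the width search to one basin", {
  # bimodal: taller peak at 4, secondary at 12
  raw <- c(0, 0.5, 0.9, 1, 0.9, 0.5, 0.1, 0.2, 0.5, 0.7, 0.75, 0.8, 0.7,
           0.4, 0.1)
  left <- narrowWidth(focusCurve(raw), peak = 4)
  right <- narrowWidth(focusCurve(raw), peak = 12)
  expect_false(left@truncated)
  expect_false(right@truncated)
  expect_gt(left@ratio, 0); expect_lte(left@ratio, 1)
  expect_gt(right@ratio, 0); expect_lte(right@ratio, 1)
  # the two basins have different widths
  expect_false(isTRUE(all.equal(left@alpha, right@alpha)))
})

test_that("curve diagnostics count local maxima with plateau collapsing", {
  d1 <- diagnoseCurve(focusCurve(c(0, 0.5, 1, 0.5, 0)))
  expect_identical(d1@argmaxFrame, 3L)
  expect_identical(d1@nLocalMaxima, 1L)
  expect_true(d1@isUnimodal)
  expect_identical(d1@maxSecondaryPeak, 0)

  d2 <- diagnoseCurve(focusCurve(c(0, 1, 0, 0.6, 0)))
  expect_identical(d2@nLocalMaxima, 2L)
  expect_false(d2@isUnimodal)
  expect_equal(d2@maxSecondaryPeak, 0.6)

  # constant curves have no maxima by convention
  d3 <- diagnoseCurve(focusCurve(c(0.3, 0.3, 0.3)))
  expect_identical(d3@nLocalMaxima, 0L)
  expect_false(d3@isUnimodal)

  # plateau collapses to its leftmost frame
  d4 <- diagnoseCurve(focusCurve(c(0, 1, 1, 0)))
  expect_identical(d4@argmaxFrame, 2L)
  expect_identical(d4@nLocalMaxima, 1L)

  # endpoints count only when strictly above their neighbour
  d5 <- diagnoseCurve(focusCurve(c(1, 0, 0.5, 0.2)))
  expect_identical(d5@nLocalMaxima, 2L)
  expect_identical(d5@argmaxFrame, 1L)
})

test_that("diagnostics agree with an exhaustive neighbour-scan oracle", {
  oracle <- function(y) {
    # collapse equal runs, then scan strict neighbour comparisons
    r <- rle(y)
    v <- r$values
    k <- length(v)
    if (k == 1L) return(0L)
    cnt <- 0L
    for (i in seq_len(k)) {
      left <- if (i == 1L) -Inf else v[i - 1L]
      right <- if (i == k) -Inf else v[i + 1L]
      if (v[i] > left && v[i] > right) cnt <- cnt + 1L
    }
    cnt
  }
  set.seed(77)
  for (rep in 1:40) {
    y <- round(runif(sample(4:25, 1)), 1)  # rounding creates ties/plateaus
    cv <- focusCurve(y)
    expect_identical(diagnoseCurve(cv)@nLocalMaxima,
                     if (cv@constant) 0L else oracle(normScores(cv)))
  }
})

test_that("curve tables carry one row per frame and measure", {
  st <- tinyStack(seed = 22, nFrames = 4L)
  cvs <- list(scoreStack(st, "variance"), scoreStack(st, "eog"))
  tab <- curveTable(cvs)
  expect_identical(nrow(tab), 8L)
  expect_identical(unique(tab$measure), c("variance", "eog"))
  met <- curveMetrics(cvs[[1]])
  expect_true(all(c("argmax_frame", "n_local_maxima", "narrow_width") %in%
                    names(met)))
})
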