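test_that("zero-density noise is the identity", {
  img <- randImg(32, seed = 51)
  expect_identical(addNoise(img, noiseSpec("gaussian", 0, seed = 1)), img)
  expect_identical(addNoise(img, noiseSpec("salt_pepper", 0, seed = 1)), img)
})

test_that("exact-count salt and pepper corrupts the stated pixel fraction", {
  img <- matrix(0.5, 100, 100)
  out <- addNoise(img, noiseSpec("salt_pepper", 0.1, seed = 3))
  changed <- sum(out != img)
  expect_identical(changed, 1000L)
  expect_true(all(out[out != 0.5] %in% c(0, 1)))

  # bernoulli mode corrupts approximately the fraction
  outB <- addNoise(img, noiseSpec("salt_pepper", 0.1, seed = 3,
                                  mode = "bernoulli"))
  expect_gt(mean(outB != img), 0.07)
  expect_lt(mean(outB != img), 0.13)
})

test_that("gaussian noise has the requested variance", {
  img <- matrix(0.5, 100, 100)
  out <- addNoise(img, noiseSpec("gaussian", 0.01, seed = 4))
  v <- var(as.vector(out - img))
  se <- 0.01 * sqrt(2 / (length(img) - 1))
  expect_lt(abs(v - 0.01), 3 * se)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("poisson noise preserves the mean at the quantisation scale", {
  img <- matrix(0.25, 120, 120)
  out <- addNoise(img, noiseSpec("poisson", seed = 5))
  # mean of Poisson(0.25 * 255)/255 is 0.25; sd of the mean ~ sqrt(64)/255/n
  se <- sqrt(0.25 * 255) / 255 / sqrt(length(img))
  expect_lt(abs(mean(out) - 0.25), 4 * se)
  expect_true(all(abs(out * 255 - round(out * 255)) < 1e-9))
})

test_that("noise injection is reproducible and leaves the caller's RNG alone", {
  img <- randImg(48, seed = 52)
  spec <- noiseSpec("salt_pepper", 0.1, seed = 99)
  set.seed(123); before <- runif(1)
  a <- addNoise(img, spec)
  b <- addNoise(img, spec)
  expect_identical(a, b)
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("mean squared corruption grows with gaussian density", {
  img <- makePhantom(phantomSpec(height = 64L, width = 64L, nCells = 3L, radiusRange = c(4, 8),
                                 seed = 53))
  mses <- vapply(c(0.001, 0.01, 0.1), function(d) {
    mean((addNoise(img, noiseSpec("gaussian", d, seed = 7)) - img)^2)
  }, numeric(1))
  expect_true(all(diff(mses) > 0))
})

test_that("the identity filter and weight normalisation behave", {
  img <- randImg(40, seed = 54)
  expect_identical(denoise(img, filterSpec("none")), img)
  flat <- matrix(0.6, 40, 40)
  expect_equal(denoise(flat, filterSpec("bilateral")), flat,
               tolerance = 1e-12)
})

test_that("both pre-filters reduce gaussian-noise error on phantoms", {
  img <- makePhantom(phantomSpec(height = 64L, width = 64L, nCells = 4L,
                                 radiusRange = c(4, 8), seed = 55))
  wins <- matrix(NA, 10, 2)
  for (s in 1:10) {
    noisy <- addNoise(img, noiseSpec("gaussian", 0.01, seed = 60 + s))
    mseN <- mean((noisy - img)^2)
    wins[s, 1] <- mean((denoise(noisy, filterSpec("bilateral")) - img)^2) < mseN
    wins[s, 2] <- mean((denoise(noisy, filterSpec("guided")) - img)^2) < mseN
  }
  expect_true(all(wins))
})

test_that("an over-regularised guided filter approaches the box-mean cascade", {
  img <- randImg(48, seed = 56)
  out <- denoise(img, filterSpec("guided", radius = 4L,
                                 regularization = 1e8))
  # independent oracle: with a -> 0, b -> window mean, q -> mean of b
  box <- function(x, r) {
    n <- nrow(x); m <- ncol(x)
    out <- matrix(0, n, m)
    cnt <- matrix(0, n, m)
    for (di in -r:r) for (dj in -r:r) {
      ii <- pmin(pmax(seq_len(n) + di, 1), n)
      jj <- pmin(pmax(seq_len(m) + dj, 1), m)
      w <- outer(seq_len(n) + di >= 1 & seq_len(n) + di <= n,
                 seq_len(m) + dj >= 1 & seq_len(m) + dj <= m)
      out <- out + x[ii, jj] * w
      cnt <- cnt + w
    }
    out / cnt
  }
  expect_lt(max(abs(out - box(box(img, 4L), 4L))), 1e-6)
})

test_that("the robustness experiment reproduces the clean benchmark at zero noise", {
  st <- tinyStack(seed = 57, nFrames = 5L)
  res <- robustnessExperiment(st, c("variance", "eog"),
                              noiseSpec("gaussian", 0, seed = 1),
                              filterSpec("none"), smallParams())
  clean <- scoreStack(st, "variance", smallParams())
  expect_equal(rawScores(res$curves$variance), rawScores(clean),
               tolerance = 1e-12)
  expect_identical(nrow(res$report), 2L)
  expect_true(all(res$report$argmax_frame ==
                    which.max(rawScores(clean))))
})

test_that("robustness reports are bit-reproducible and judgement-free", {
  st <- tinyStack(seed = 58, nFrames = 5L)
  run <- function() robustnessExperiment(
    st, c("variance", "roberts"), noiseSpec("salt_pepper", 0.1, seed = 11),
    filterSpec("bilateral"), smallParams())
  r1 <- run(); r2 <- run()
  expect_identical(r1$report, r2$report)
  expect_identical(rawScores(r1$curves$roberts), rawScores(r2$curves$roberts))
  # a baseline may lose unimodality under impulse noise; that is recorded,
  # not asserted against
  expect_true(all(r1$report$n_local_maxima >= 1L))
  expect_error(robustnessExperiment(st, "nope",
                                    noiseSpec("gaussian", 0.01),
                                    filterSpec("none")), "unknown")
})
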