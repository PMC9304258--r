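test_that("zero noise level returns the input unchanged", {
  f <- small_phantom(64L)
  g <- addPoissonNoise(f, NoiseSpec(muPercent = 0, seed = 1L))
  expect_identical(pixels(g), pixels(f))
})

test_that("added noise has Poisson moments lambda = mu * alpha / 100", {
  f <- ImageFrame(matrix(100, 1000, 1000), bitDepth = 16L)
  g <- addPoissonNoise(f, NoiseSpec(muPercent = 60, seed = 123L))
  noise <- pixels(g) - pixels(f)
  expect_lt(abs(mean(noise) - 60), 0.08)
  expect_lt(abs(stats::var(as.numeric(noise)) - 60), 1)
  expect_true(all(noise >= 0))
})

test_that("mean-subtracted degradation is zero-mean", {
  f <- ImageFrame(matrix(100, 500, 500), bitDepth = 16L)
  g <- addPoissonNoise(f, NoiseSpec(muPercent = 60, seed = 3L,
                                    meanSubtract = TRUE))
  expect_lt(abs(mean(pixels(g) - pixels(f))), 0.15)
})

test_that("degradation is seeded and all-zero frames warn", {
  f <- small_phantom(64L)
  a <- addPoissonNoise(f, NoiseSpec(seed = 5L))
  b <- addPoissonNoise(f, NoiseSpec(seed = 5L))
  d <- addPoissonNoise(f, NoiseSpec(seed = 6L))
  expect_identical(pixels(a), pixels(b))
  expect_gt(max(abs(pixels(a) - pixels(d))), 0)
  z <- ImageFrame(matrix(0, 8, 8))
  expect_warning(addPoissonNoise(z, NoiseSpec()), "lambda = 0")
})

test_that("added-noise variance scales linearly with the noise level", {
  f <- ImageFrame(matrix(100, 400, 400), bitDepth = 16L)
  mus <- c(10, 30, 60, 100)
  vars <- vapply(seq_along(mus), function(i) {
    g <- addPoissonNoise(f, NoiseSpec(muPercent = mus[i], seed = 10L + i))
    stats::var(as.numeric(pixels(g) - pixels(f)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(vars ~ mus))[2]
  expect_lt(abs(slope - 1) / 1, 0.1)  # alpha / 100 = 1 for this frame
})

test_that("mean local SNR is non-increasing in the noise level", {
  # the zero-mean variant isolates the stochastic degradation: the literal
  # model's positive mean lambda inflates tile means at high mu, which is a
  # brightness bias rather than a noise effect
  f <- small_phantom(128L)
  snr_by_mu <- vapply(c(10, 30, 60, 100), function(mu) {
    mean(vapply(1:20, function(s) {
      localSNR(addPoissonNoise(f, NoiseSpec(muPercent = mu,
                                            seed = 100L * mu + s,
                                            meanSubtract = TRUE)))@meanSnr
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(snr_by_mu) <= 0))
  # under the literal model the clean frame still outscores 60% degradation
  deg <- localSNR(addPoissonNoise(f, NoiseSpec(muPercent = 60,
                                               seed = 1L)))@meanSnr
  expect_gt(localSNR(f)@meanSnr, deg)
})

test_that("noise-level counts follow the binned Gaussian", {
  spec <- NoiseSpec()
  counts <- noiseLevelCounts(10000, spec)
  expect_equal(counts$level, seq(10, 100, by = 10))
  expect_true(all(counts$count >= 0))
  # renormalized masses sum to the total within rounding
  expect_lte(abs(sum(counts$count) - 10000), nrow(counts) / 2)
  # raw-mass variant reproduces the closed-form bin count:
  # round(1000 * (pnorm(0.25) - pnorm(-0.25))) = 197 for the 60% bin
  raw <- noiseLevelCounts(1000, spec, renormalize = FALSE)
  expect_equal(raw$count[raw$level == 60], 197L)
  # wide coverage (mean +/- 6 sigma) needs no renormalization to normalize
  wide <- noiseLevelCounts(1000, NoiseSpec(levelRange = c(-60, 180)),
                           renormalize = FALSE)
  expect_lte(abs(sum(wide$count) - 1000), nrow(wide) / 2)
})

test_that("buildTrainingSet yields matched pairs with the requested histogram", {
  frames <- generateDataset(defaultPhantomSpec(size = c(64L, 64L)), 3L,
                            seed = 2L)
  spec <- NoiseSpec(seed = 21L)
  ds <- buildTrainingSet(frames, 100L, patchSize = 32L, spec = spec)
  expect_s4_class(ds, "PatchDataset")
  expect_equal(dim(ds@clean), c(32L, 32L, 100L))
  expect_equal(dim(ds@noisy), c(32L, 32L, 100L))
  expect_length(ds@levels, 100L)
  # recorded level histogram equals the analytic one
  counts <- noiseLevelCounts(100L, spec)
  hist <- table(factor(ds@levels, levels = counts$level))
  expect_true(all(abs(as.integer(hist) - counts$count) <= 1))
  # reproducibility
  ds2 <- buildTrainingSet(frames, 100L, patchSize = 32L, spec = spec)
  expect_identical(ds@noisy, ds2@noisy)
})

test_that("frames smaller than the patch are skipped with a warning", {
  small <- ImageFrame(matrix(10, 16, 16))
  big <- small_phantom(64L)
  expect_warning(ds <- buildTrainingSet(list(small, big), 10L,
                                        patchSize = 32L,
                                        spec = NoiseSpec(seed = 1L)),
                 "skipping")
  expect_equal(dim(ds@clean)[3], 10L)
  expect_error(
    suppressWarnings(buildTrainingSet(list(small), 10L, patchSize = 32L,
                                      spec = NoiseSpec(seed = 1L))),
    "no usable frames")
})
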