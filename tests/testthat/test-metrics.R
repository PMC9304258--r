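test_that("PSNR matches its closed forms", {
  a <- ImageFrame(matrix(0, 8, 8)); b <- ImageFrame(matrix(1, 8, 8))
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, b), 10 * log10(255^2), tolerance = 1e-12)
  c255 <- ImageFrame(matrix(255, 8, 8))
  expect_equal(psnr(a, c255), 0, tolerance = 1e-12)
  expect_error(psnr(a, ImageFrame(matrix(0, 4, 4))), "shape")
  expect_error(psnr(a, ImageFrame(matrix(0, 8, 8), bitDepth = 16L)),
               "bit depths")
})

test_that("PSNR strictly decreases as MSE increases", {
  ref <- rand_frame(1, 32, 32)
  vals <- vapply(c(1, 4, 9, 25), function(off) {
    psnr(ImageFrame(pmin(pixels(ref) + sqrt(off), 255)), ref)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM matches a direct evaluation of the formula", {
  a <- ImageFrame(matrix(c(0, 255, 0, 255), 2, 2))
  b <- ImageFrame(matrix(0, 2, 2))
  # hand evaluation with global population statistics
  mu_a <- 127.5; mu_b <- 0
  va <- 127.5^2; vb <- 0; cab <- 0
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  want <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  expect_equal(ssim(a, b), want, tolerance = 1e-12)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
})

test_that("psnr and ssim agree with independent textbook evaluations", {
  for (s in 1:20) {
    set.seed(s)
    a <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    mse <- sum((a - b)^2) / 64
    expect_equal(psnr(ImageFrame(a), ImageFrame(b)),
                 10 * log10(255^2 / mse), tolerance = 1e-9)
    mu_a <- sum(a) / 64; mu_b <- sum(b) / 64
    va <- sum((a - mu_a)^2) / 64; vb <- sum((b - mu_b)^2) / 64
    cab <- sum((a - mu_a) * (b - mu_b)) / 64
    c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
    want <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
    expect_equal(ssim(ImageFrame(a), ImageFrame(b)), want, tolerance = 1e-9)
  }
})

test_that("the windowed SSIM variant behaves like a local mean-SSIM", {
  a <- rand_frame(3, 16, 16)
  expect_equal(ssim(a, a, window = 8L), 1)
  b <- rand_frame(4, 16, 16)
  v <- ssim(a, b, window = 8L)
  expect_true(v >= -1 && v <= 1)
})

test_that("local SNR decomposes a frame into 16x16 tiles with population sigma", {
  # one tile, half 10s and half 20s: mu = 15, sigma = 5, SNR = 3
  tile <- rbind(matrix(10, 8, 16), matrix(20, 8, 16))
  r <- localSNR(ImageFrame(tile))
  expect_equal(nrow(r@perPatch), 1L)
  expect_equal(r@perPatch$mu, 15)
  expect_equal(r@perPatch$sigma, 5)
  expect_equal(r@meanSnr, 3)
  # partial border tiles are dropped
  r2 <- localSNR(ImageFrame(cbind(tile, matrix(1, 16, 7))))
  expect_equal(nrow(r2@perPatch) + r2@nExcluded, 1L)
})

test_that("constant frames have no defined local SNR", {
  r <- localSNR(ImageFrame(matrix(50, 32, 32)))
  expect_true(is.nan(r@meanSnr))
  expect_equal(r@nExcluded, 4L)
  expect_equal(nrow(r@perPatch), 0L)
  expect_error(localSNR(ImageFrame(matrix(0, 8, 8)), patchSize = 16L),
               "smaller")
})

test_that("adding zero-mean noise decreases the mean local SNR", {
  f <- small_phantom(128L)
  base <- localSNR(f)@meanSnr
  noisy <- vapply(1:20, function(s) {
    localSNR(addPoissonNoise(f, NoiseSpec(muPercent = 30, seed = s,
                                          meanSubtract = TRUE)))@meanSnr
  }, numeric(1))
  expect_true(all(noisy < base))
})

test_that("relative dose is the squared SNR ratio", {
  expect_equal(relativeDose(1, 1), 1)
  expect_equal(relativeDose(2, 1), 4)
  expect_equal(round(relativeDose(24.5, 11.3), 1), 4.7)
  expect_error(relativeDose(0, 1), "positive")
})
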