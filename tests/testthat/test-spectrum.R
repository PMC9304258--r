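test_that("a constant frame has all spectral energy at DC", {
  p <- radialProfile(matrix(9, 16, 16))
  expect_gt(p@sOfR[p@radii == 0], 0)
  expect_equal(max(p@sOfR[p@radii > 0]), 0)
})

test_that("a pure cosine peaks in its own annulus", {
  x <- outer(rep(1, 64), 0:63)
  m <- 100 + 50 * cos(2 * pi * 8 * x / 64)   # 8 cycles across the width
  p <- radialProfile(m)
  nz <- p@radii > 0
  expect_equal(p@radii[nz][which.max(p@sOfR[nz])], 8L)
})

test_that("radialProfile matches a direct-DFT oracle", {
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(stats::rnorm(12 * 12, 100, 20), 12, 12)
    want <- naive_radial_profile(m)
    got <- radialProfile(m)
    expect_equal(got@sOfR, as.numeric(want), tolerance = 1e-6)
    expect_equal(got@radii, as.integer(names(want)))
  }
})

test_that("annulus means conserve the total spectral magnitude", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(stats::runif(32 * 24, 0, 255), 32, 24)
    p <- radialProfile(m)
    tot <- sum(Mod(stats::fft(m)))
    expect_equal(sum(p@sOfR * p@nOfR), tot, tolerance = 1e-6 * tot)
  }
})

test_that("Nyquist rescaling applies the magnification correction", {
  expect_equal(nyquistCyclesPerMm(GeometrySpec(0.5, 1000, 1000)), 1.0)
  # 0.4 mm at the detector, SED/SID = 0.8 -> 0.32 mm at the entrance plane
  expect_equal(nyquistCyclesPerMm(GeometrySpec(0.4, 1000, 800)), 1.5625)
  # monotonicity: finer detector or larger SID -> higher Nyquist
  expect_gt(nyquistCyclesPerMm(GeometrySpec(0.3, 1000, 800)),
            nyquistCyclesPerMm(GeometrySpec(0.4, 1000, 800)))
  expect_gt(nyquistCyclesPerMm(GeometrySpec(0.4, 1200, 800)),
            nyquistCyclesPerMm(GeometrySpec(0.4, 1000, 800)))
})

test_that("profiles carry cycles/mm when geometry or spacing is known", {
  f <- ImageFrame(matrix(stats::runif(64 * 64, 0, 255), 64, 64),
                  pixelSpacingMm = 0.5)
  p <- radialProfile(f)
  expect_equal(p@nyquistCpmm, 1.0)
  expect_equal(p@cyclesPerMm, p@radii / (64 * 0.5))
  g <- radialProfile(f, geometry = GeometrySpec(0.4, 1000, 800))
  expect_equal(g@nyquistCpmm, 1.5625)
  bare <- radialProfile(matrix(stats::runif(64 * 64), 64, 64))
  expect_length(bare@cyclesPerMm, 0L)
})

test_that("transfer ratios are 1 against self and scale linearly", {
  f <- matrix(stats::runif(32 * 32, 10, 200), 32, 32)
  p <- radialProfile(f)
  self <- transferRatio(p, p)
  expect_true(all(self$ratio[!is.na(self$ratio)] == 1))
  half <- transferRatio(radialProfile(f * 0.5), p)
  ok <- !is.na(half$ratio)
  expect_equal(half$ratio[ok], rep(0.5, sum(ok)), tolerance = 1e-9)
  expect_error(transferRatio(p, radialProfile(matrix(1, 16, 16))), "grids")
})

test_that("noise adds magnitude in the upper annuli of the spectrum", {
  ratios <- lapply(1:20, function(s) {
    clean <- generateDataset(defaultPhantomSpec(size = c(128L, 128L)), 1L,
                             seed = 200L + s)[[1L]]
    noisy <- addPoissonNoise(clean, NoiseSpec(muPercent = 60, seed = s))
    transferRatio(radialProfile(noisy), radialProfile(clean))
  })
  avg <- averageTransferRatios(ratios)
  top <- avg$radius >= stats::quantile(avg$radius, 0.75)
  expect_true(all(avg$mean[top] > 1))
})

test_that("the bandpass filter is an exact annular mask", {
  f <- ImageFrame(matrix(stats::runif(64 * 64, 50, 200), 64, 64),
                  pixelSpacingMm = 0.5)
  # identity band
  out <- bandpassFilter(f, Band(0, 1.0))
  expect_equal(pixels(out), pixels(f), tolerance = 1e-6)
  # two-tone separation: keep 0.25 cycles/mm (r=8), remove 0.75 (r=24)
  x <- outer(rep(1, 64), 0:63)
  two <- 100 + 40 * cos(2 * pi * 8 * x / 64) + 40 * cos(2 * pi * 24 * x / 64)
  g <- ImageFrame(two, pixelSpacingMm = 0.5)
  kept <- bandpassFilter(g, Band(0.15, 0.45))
  spec <- radialProfile(kept)
  amp_in <- spec@sOfR[spec@radii == 8]
  amp_out <- spec@sOfR[spec@radii == 24]
  ref <- radialProfile(g)
  expect_gt(amp_in / ref@sOfR[ref@radii == 8], 0.99)
  expect_lt(amp_out / ref@sOfR[ref@radii == 24], 0.01)
  # DC is removed unless fLo = 0
  expect_lt(abs(mean(pixels(kept))), 1e-6)
})

test_that("bandpass filtering is idempotent and validates its band", {
  f <- ImageFrame(matrix(stats::runif(32 * 32, 0, 255), 32, 32),
                  pixelSpacingMm = 0.5)
  once <- bandpassFilter(f, Band(0.2, 0.8))
  twice <- bandpassFilter(once, Band(0.2, 0.8))
  expect_equal(pixels(twice), pixels(once), tolerance = 1e-9)
  expect_error(bandpassFilter(f, Band(0.5, 0.2)), "band")
  expect_error(bandpassFilter(f, Band(0, 2.0)), "band")
  expect_error(bandpassFilter(matrix(1, 16, 16), Band(0.1, 0.3)),
               "cycles/mm")
})

test_that("observer band consensus takes the union and intersection", {
  r <- bandConsensus(list(c(0.02, 0.39), c(0.10, 0.23)))
  expect_equal(r$overall@fLo, 0.02); expect_equal(r$overall@fHi, 0.39)
  expect_equal(r$consensus@fLo, 0.10); expect_equal(r$consensus@fHi, 0.23)
  one <- bandConsensus(list(Band(0.05, 0.25)))
  expect_equal(one$overall, one$consensus)
  disjoint <- bandConsensus(list(c(0.1, 0.2), c(0.3, 0.4)))
  expect_true(isEmptyBand(disjoint$consensus))
  expect_error(bandConsensus(list()), "no selections")
  expect_error(bandConsensus(list(c(0.3, 0.1))), "fLo < fHi")
})
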