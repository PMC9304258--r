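test_that("the Charbonnier loss matches its closed forms", {
  # rho(0) = epsilon, so identical k-element inputs give exactly k * epsilon
  expect_equal(charbonnierLoss(matrix(0, 4, 4), matrix(0, 4, 4)), 16e-3)
  expect_equal(charbonnierLoss(array(1, c(3, 3, 2)), array(1, c(3, 3, 2)),
                               epsilon = 1e-2), 18e-2)
  # single element, diff 3: sqrt(9 + 1e-6)
  expect_equal(charbonnierLoss(matrix(0, 1, 1), matrix(3, 1, 1)),
               sqrt(9 + 1e-6), tolerance = 1e-12)
  expect_error(charbonnierLoss(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
  expect_error(charbonnierLoss(matrix(0, 2, 2), matrix(0, 2, 2),
                               epsilon = 0), "epsilon")
})

test_that("the batchmean reduction is permutation-invariant within a batch", {
  set.seed(1)
  p <- array(stats::rnorm(4 * 4 * 5), c(4, 4, 5))
  t <- array(stats::rnorm(4 * 4 * 5), c(4, 4, 5))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(
    charbonnierLoss(p, t, reduction = "batchmean"),
    charbonnierLoss(p[, , perm], t[, , perm], reduction = "batchmean"))
  # batchmean = sum / elements-per-item
  expect_equal(charbonnierLoss(p, t, reduction = "batchmean"),
               charbonnierLoss(p, t) / 16)
})

test_that("the learning-rate schedule halves every 2000 steps down to the floor", {
  cfg <- TrainConfig()
  expect_equal(lrSchedule(0, cfg), 1e-3)
  expect_equal(lrSchedule(1999, cfg), 1e-3)
  expect_equal(lrSchedule(2000, cfg), 5e-4)
  expect_equal(lrSchedule(4000, cfg), 2.5e-4)
  expect_equal(lrSchedule(1e6, cfg), 1e-6)
})

make_tiny_dataset <- function(n = 24L, patch = 16L, seed = 3L) {
  frames <- generateDataset(defaultPhantomSpec(size = c(64L, 64L)), 3L,
                            seed = seed)
  buildTrainingSet(frames, n, patchSize = patch, spec = NoiseSpec(seed = seed))
}

tiny_train_model <- function(seed = 5L) {
  buildModel(ModelConfig(variant = "eedn", nUdbsTotal = 2L,
                         nUdbsDenoiser = 1L, nUdbsEdge = 1L, udbLayers = 2L,
                         growthChannels = 4L, baseChannels = 4L,
                         edgeChannels = 2L, seed = seed))
}

test_that("zero steps leave the parameters untouched", {
  ds <- make_tiny_dataset()
  m <- tiny_train_model()
  r <- trainModel(m, ds, TrainConfig(maxSteps = 0L, patchSize = 16L))
  expect_equal(eedn:::p_checksum(r$model@params), eedn:::p_checksum(m@params))
  expect_length(r$history@loss, 0L)
})

test_that("training reduces the loss, records the lr trace, and is reproducible", {
  ds <- make_tiny_dataset(n = 48L)
  m <- tiny_train_model()
  cfg <- TrainConfig(maxSteps = 40L, batchSize = 8L, patchSize = 16L,
                     lrHalveEvery = 10L, seed = 9L)
  r1 <- trainModel(m, ds, cfg)
  expect_length(r1$history@loss, 40L)
  # exact schedule at every logged step
  expect_equal(r1$history@lr, lrSchedule(0:39, cfg))
  expect_lt(mean(r1$history@loss[31:40]), mean(r1$history@loss[1:10]))
  expect_equal(r1$model@steps, 40L)
  r2 <- trainModel(m, ds, cfg)
  expect_identical(r1$history@loss, r2$history@loss)
  expect_equal(eedn:::p_checksum(r1$model@params),
               eedn:::p_checksum(r2$model@params))
})

test_that("held-out evaluation and checkpointing are recorded", {
  ds <- make_tiny_dataset(n = 32L)
  m <- tiny_train_model()
  clean <- small_phantom(32L, seed = 2L)
  noisy <- addPoissonNoise(clean, NoiseSpec(seed = 4L))
  ck <- tempfile(fileext = ".rds")
  r <- trainModel(m, ds,
                  TrainConfig(maxSteps = 10L, batchSize = 8L,
                              patchSize = 16L, evalEvery = 5L, seed = 2L),
                  heldout = list(list(noisy = noisy, clean = clean)),
                  checkpointPath = ck)
  expect_equal(r$history@evalSteps, c(5L, 10L))
  expect_length(r$history@evalPsnr, 2L)
  expect_true(file.exists(ck))
  m2 <- loadModel(ck)
  expect_equal(eedn:::p_checksum(m2@params),
               eedn:::p_checksum(r$model@params))
  expect_equal(m2@config@seed, m@config@seed)
})

test_that("desk-scale profiles encode the reduced architecture", {
  mc <- deskModelConfig(7L)
  expect_equal(mc@nUdbsDenoiser, 1L)
  expect_equal(mc@nUdbsEdge, 1L)
  expect_equal(mc@growthChannels, 8L)
  tc <- deskTrainConfig(7L)
  expect_equal(tc@maxSteps, 500L)
  expect_equal(tc@batchSize, 16L)
  expect_equal(tc@patchSize, 96L)
})
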