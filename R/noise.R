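#' @include AllClasses.R
NULL

#' Degrade a frame with Poisson quantum noise
#'
#' Implements the quantum-limited low-dose degradation model: every output
#' pixel is `input + Poisson(lambda)` with a common mean
#' \eqn{\lambda = \mu \alpha / 100}, where \eqn{\mu} is the percentage noise
#' level and \eqn{\alpha} is the mean intensity of the clean frame. As
#' written the model adds noise with positive mean \eqn{\lambda} (a
#' brightness bias); set `meanSubtract = TRUE` in the spec for a zero-mean
#' variant (\eqn{\lambda} subtracted after the draw). The result stays in
#' floating point — clipping to the integer range happens only at
#' [writeFrame()] / [clipFrame()] time.
#'
#' @param frame an [ImageFrame-class] with non-negative intensities
#' @param spec a [NoiseSpec-class]; `muPercent` and `seed` drive the draw
#' @param muPercent optional override of `spec@muPercent`
#' @param seed optional override of `spec@seed`
#' @return the degraded [ImageFrame-class]
#' @examples
#' f <- generatePhantom(defaultPhantomSpec(size = c(64L, 64L)))
#' g <- addPoissonNoise(f, NoiseSpec(muPercent = 60, seed = 1L))
#' @export
addPoissonNoise <- function(frame, spec = NoiseSpec(), muPercent = NULL,
                            seed = NULL) {
  stopifnot(is(frame, "ImageFrame"), is(spec, "NoiseSpec"))
  validObject(spec)
  mu <- if (is.null(muPercent)) spec@muPercent else as.numeric(muPercent)
  if (mu < 0) stop("noise level 'muPercent' must be non-negative")
  if (min(frame@pixels) < 0)
    stop("clean frame must have non-negative intensities")
  alpha <- mean(frame@pixels)
  if (alpha == 0) {
    warning("all-zero frame: lambda = 0, returning the input unchanged")
    return(frame)
  }
  lambda <- mu * alpha / 100
  if (lambda == 0) return(frame)
  old <- local_rng_seed(if (is.null(seed)) spec@seed else as.integer(seed))
  on.exit(restore_rng(old))
  noise <- stats::rpois(length(frame@pixels), lambda)
  out <- frame@pixels + noise
  if (spec@meanSubtract) out <- out - lambda
  frame@pixels <- matrix(out, nrow(frame@pixels), ncol(frame@pixels))
  frame
}

#' Per-level image counts of the Gaussian noise-level distribution
#'
#' Training corpora use a range of noise levels whose per-level image counts
#' follow a Gaussian distribution centered on `meanPercent` (default 60) with
#' standard deviation `sigmaPercent` (default 20): the count at level x is
#' \eqn{N_x = \mathrm{round}(N_T \int_{x-\delta/2}^{x+\delta/2}
#' \mathcal{N}(\mathrm{mean}, \sigma)\,dx)}. Bins are centered at
#' `seq(levelRange[1], levelRange[2], by = deltaPercent)`. With
#' `renormalize = TRUE` (default) the Gaussian tail mass outside `levelRange`
#' is redistributed proportionally over the covered bins so the counts sum to
#' `nTotal` up to rounding; `renormalize = FALSE` uses the raw bin masses.
#'
#' @param nTotal total number of images/patches \eqn{N_T}
#' @param spec a [NoiseSpec-class]
#' @param renormalize redistribute out-of-range tail mass? (default TRUE)
#' @return data.frame with columns `level` (bin center, %) and `count`
#' @examples
#' noiseLevelCounts(10000, NoiseSpec())
#' @export
noiseLevelCounts <- function(nTotal, spec = NoiseSpec(), renormalize = TRUE) {
  stopifnot(is(spec, "NoiseSpec"))
  validObject(spec)
  centers <- seq(spec@levelRange[1], spec@levelRange[2],
                 by = spec@deltaPercent)
  if (length(centers) == 0L) stop("empty noise-level bin list")
  mass <- stats::pnorm(centers + spec@deltaPercent / 2, spec@meanPercent,
                       spec@sigmaPercent) -
    stats::pnorm(centers - spec@deltaPercent / 2, spec@meanPercent,
                 spec@sigmaPercent)
  if (renormalize) mass <- mass / sum(mass)
  data.frame(level = centers, count = as.integer(round(nTotal * mass)))
}

#' Build a paired noisy/clean patch training set
#'
#' Samples `nPatches` patch locations uniformly over the supplied clean
#' frames (reproducibly from `seed`), degrades each clean patch with
#' [addPoissonNoise()] at a level assigned so that the empirical level
#' histogram matches [noiseLevelCounts]`(nPatches, spec)`. The Poisson mean
#' \eqn{\lambda} of each patch is computed from its source frame's mean
#' intensity (\eqn{\alpha} is a whole-frame quantity), which the patch
#' inherits.
#'
#' @param cleanFrames list of [ImageFrame-class]
#' @param nPatches number of pairs to draw
#' @param patchSize patch side in pixels (default 96)
#' @param spec a [NoiseSpec-class] (level distribution + seed)
#' @return a [PatchDataset-class]
#' @examples
#' frames <- generateDataset(defaultPhantomSpec(size = c(128L, 128L)), 2, 1L)
#' ds <- buildTrainingSet(frames, 10, patchSize = 32L, spec = NoiseSpec())
#' @export
buildTrainingSet <- function(cleanFrames, nPatches, patchSize = 96L,
                             spec = NoiseSpec()) {
  stopifnot(is.list(cleanFrames), nPatches >= 1)
  patchSize <- as.integer(patchSize)
  usable <- vapply(cleanFrames, function(f) {
    ok <- all(dim(f@pixels) >= patchSize)
    if (!ok) warning("skipping frame smaller than the patch size")
    ok
  }, logical(1))
  cleanFrames <- cleanFrames[usable]
  if (length(cleanFrames) == 0L) stop("no usable frames (all smaller than the patch)")

  counts <- noiseLevelCounts(nPatches, spec)
  levels <- rep(counts$level, counts$count)
  # rounding can leave the total a few short/long of nPatches; trim or top up
  # with draws from the bins of largest mass
  if (length(levels) > nPatches) levels <- levels[seq_len(nPatches)]
  while (length(levels) < nPatches)
    levels <- c(levels, counts$level[which.max(counts$count)])

  old <- local_rng_seed(spec@seed)
  on.exit(restore_rng(old))
  levels <- sample(levels)

  bd <- cleanFrames[[1]]@bitDepth
  clean <- array(0, c(patchSize, patchSize, nPatches))
  noisy <- array(0, c(patchSize, patchSize, nPatches))
  src <- character(nPatches)
  frame_idx <- sample.int(length(cleanFrames), nPatches, replace = TRUE)
  alphas <- vapply(cleanFrames, function(f) mean(f@pixels), numeric(1))
  for (i in seq_len(nPatches)) {
    f <- cleanFrames[[frame_idx[i]]]
    d <- dim(f@pixels)
    r0 <- sample.int(d[1] - patchSize + 1L, 1L)
    c0 <- sample.int(d[2] - patchSize + 1L, 1L)
    p <- f@pixels[r0:(r0 + patchSize - 1L), c0:(c0 + patchSize - 1L)]
    lambda <- levels[i] * alphas[frame_idx[i]] / 100
    n <- stats::rpois(length(p), lambda)
    q <- p + n
    if (spec@meanSubtract) q <- q - lambda
    clean[, , i] <- p
    noisy[, , i] <- q
    src[i] <- if (is.na(f@frameId)) as.character(frame_idx[i]) else f@frameId
  }
  new("PatchDataset", clean = clean, noisy = noisy, levels = levels,
      sourceIds = src, bitDepth = bd, seed = spec@seed)
}
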