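#' @import methods
NULL

#' ImageFrame: a 2D radiographic intensity raster
#'
#' The universal currency of the package: a single grayscale frame with its
#' nominal bit depth and (optionally) the physical detector-plane pixel
#' spacing. Intensities are held in floating point during processing; they are
#' only quantized and clipped to \eqn{[0, 2^n - 1]} when written to disk by
#' [writeFrame()].
#'
#' @slot pixels numeric matrix of intensities (rows = height N, cols = width M)
#' @slot bitDepth integer bit depth \eqn{n}; nominal intensity range
#'   \eqn{[0, 2^n - 1]}
#' @slot pixelSpacingMm detector-plane pixel spacing in mm/pixel, or
#'   `numeric(0)` when unknown
#' @slot geometry a [GeometrySpec-class] or `NULL` when the acquisition
#'   geometry is unknown
#' @slot frameId opaque character label
#' @export
setClass("ImageFrame",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    pixelSpacingMm = "numeric",
    geometry = "ANY",
    frameId = "character"
  ),
  prototype(
    bitDepth = 8L,
    pixelSpacingMm = numeric(0),
    geometry = NULL,
    frameId = NA_character_
  )
)

setValidity("ImageFrame", function(object) {
  msg <- character(0)
  p <- object@pixels
  if (!is.numeric(p)) msg <- c(msg, "'pixels' must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) msg <- c(msg, "frame must be at least 1x1")
  if (any(!is.finite(p))) msg <- c(msg, "all intensities must be finite")
  if (length(object@bitDepth) != 1L || is.na(object@bitDepth) ||
      object@bitDepth < 1L) {
    msg <- c(msg, "'bitDepth' must be a single positive integer")
  }
  if (length(object@pixelSpacingMm) > 1L ||
      (length(object@pixelSpacingMm) == 1L &&
       (!is.finite(object@pixelSpacingMm) || object@pixelSpacingMm <= 0))) {
    msg <- c(msg, "'pixelSpacingMm' must be empty or a single positive number")
  }
  if (!is.null(object@geometry) && !is(object@geometry, "GeometrySpec"))
    msg <- c(msg, "'geometry' must be NULL or a GeometrySpec")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageFrame
#'
#' @param pixels numeric matrix of intensities
#' @param bitDepth integer bit depth (default 8)
#' @param pixelSpacingMm optional detector-plane spacing (mm/pixel)
#' @param geometry optional [GeometrySpec-class]
#' @param frameId optional label
#' @return an [ImageFrame-class]
#' @examples
#' f <- ImageFrame(matrix(0:255, 16, 16), bitDepth = 8L)
#' @export
ImageFrame <- function(pixels, bitDepth = 8L, pixelSpacingMm = numeric(0),
                       geometry = NULL, frameId = NA_character_) {
  new("ImageFrame", pixels = as.matrix(pixels), bitDepth = as.integer(bitDepth),
      pixelSpacingMm = as.numeric(pixelSpacingMm), geometry = geometry,
      frameId = as.character(frameId))
}

#' GeometrySpec: X-ray acquisition geometry
#'
#' Holds the three header quantities that determine the Nyquist frequency at
#' the patient entrance plane: detector element spacing, source-to-image
#' distance (SID) and source-to-entrance distance (SED). The effective pixel
#' spacing at the entrance plane is `detectorSpacingMm * sedMm / sidMm`
#' (magnification correction).
#'
#' @slot detectorSpacingMm detector element spacing (mm)
#' @slot sidMm source-to-image distance (mm)
#' @slot sedMm source-to-entrance distance (mm)
#' @export
setClass("GeometrySpec",
  representation(detectorSpacingMm = "numeric", sidMm = "numeric",
                 sedMm = "numeric")
)

setValidity("GeometrySpec", function(object) {
  v <- c(object@detectorSpacingMm, object@sidMm, object@sedMm)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("detectorSpacingMm, sidMm and sedMm must all be single positive numbers")
  if (object@sedMm > object@sidMm)
    return("source-to-entrance distance cannot exceed source-to-image distance")
  TRUE
})

#' Construct a GeometrySpec
#'
#' @param detectorSpacingMm detector element spacing (mm)
#' @param sidMm source-to-image distance (mm)
#' @param sedMm source-to-entrance distance (mm)
#' @return a [GeometrySpec-class]
#' @examples
#' GeometrySpec(0.4, 1000, 800)
#' @export
GeometrySpec <- function(detectorSpacingMm, sidMm, sedMm) {
  new("GeometrySpec", detectorSpacingMm = as.numeric(detectorSpacingMm),
      sidMm = as.numeric(sidMm), sedMm = as.numeric(sedMm))
}

#' NoiseSpec: Poisson degradation and noise-level distribution parameters
#'
#' Describes both a single degradation (percentage noise level `muPercent`,
#' with Poisson mean \eqn{\lambda = \mu \alpha / 100} where \eqn{\alpha} is the
#' clean-frame mean intensity) and the Gaussian distribution of noise levels
#' used to build training corpora (centered on `meanPercent` with standard
#' deviation `sigmaPercent`, binned in steps of `deltaPercent` over
#' `levelRange`).
#'
#' @slot muPercent percentage noise level \eqn{\mu} for a single degradation
#' @slot meanPercent center of the Gaussian level distribution (default 60)
#' @slot sigmaPercent its standard deviation (default 20)
#' @slot deltaPercent bin width \eqn{\delta} of each level bin (default 10)
#' @slot levelRange `c(min, max)` of simulated level bins (default 10..100)
#' @slot seed integer RNG seed
#' @slot meanSubtract if TRUE, subtract \eqn{\lambda} after adding the Poisson
#'   draw so the added noise is zero-mean (off by default: the degradation
#'   model adds noise with positive mean \eqn{\lambda})
#' @export
setClass("NoiseSpec",
  representation(
    muPercent = "numeric", meanPercent = "numeric", sigmaPercent = "numeric",
    deltaPercent = "numeric", levelRange = "numeric", seed = "integer",
    meanSubtract = "logical"
  ),
  prototype(muPercent = 60, meanPercent = 60, sigmaPercent = 20,
            deltaPercent = 10, levelRange = c(10, 100), seed = 1L,
            meanSubtract = FALSE)
)

setValidity("NoiseSpec", function(object) {
  msg <- character(0)
  if (length(object@muPercent) != 1L || !is.finite(object@muPercent) ||
      object@muPercent < 0)
    msg <- c(msg, "'muPercent' must be a single non-negative number")
  if (object@sigmaPercent <= 0) msg <- c(msg, "'sigmaPercent' must be > 0")
  if (object@deltaPercent <= 0) msg <- c(msg, "'deltaPercent' must be > 0")
  if (length(object@levelRange) != 2L ||
      object@levelRange[1] >= object@levelRange[2])
    msg <- c(msg, "'levelRange' must be c(min, max) with min < max")
  if (length(msg)) msg else TRUE
})

#' Construct a NoiseSpec
#'
#' @param muPercent percentage noise level (default 60, the clinical
#'   fluoroscopy regime)
#' @param meanPercent,sigmaPercent,deltaPercent,levelRange Gaussian
#'   level-distribution parameters; see [NoiseSpec-class]
#' @param seed RNG seed
#' @param meanSubtract subtract the Poisson mean after degradation?
#' @return a [NoiseSpec-class]
#' @examples
#' NoiseSpec(muPercent = 60, seed = 1L)
#' @export
NoiseSpec <- function(muPercent = 60, meanPercent = 60, sigmaPercent = 20,
                      deltaPercent = 10, levelRange = c(10, 100), seed = 1L,
                      meanSubtract = FALSE) {
  new("NoiseSpec", muPercent = as.numeric(muPercent),
      meanPercent = as.numeric(meanPercent),
      sigmaPercent = as.numeric(sigmaPercent),
      deltaPercent = as.numeric(deltaPercent),
      levelRange = as.numeric(levelRange), seed = as.integer(seed),
      meanSubtract = isTRUE(meanSubtract))
}

#' PhantomSpec: description of a synthetic fluoroscopy phantom
#'
#' A phantom frame consists of a smooth low-frequency anatomical background
#' (constant base level + linear gradient + broad Gaussian blobs), dark
#' curvilinear device tracks (catheter/wire-like curves rendered with a
#' Gaussian cross-profile), and sharp step-edge bands. Rendering is fully
#' deterministic given the spec.
#'
#' @slot size `c(M, N)` frame size in pixels (width, height)
#' @slot bitDepth bit depth
#' @slot pixelSpacingMm pixel spacing (mm)
#' @slot baseLevel constant background level
#' @slot gradient `c(gx, gy)` linear intensity gradient per pixel
#' @slot background list of blobs, each `list(center = c(row, col), radius,
#'   amplitude)`
#' @slot devices list of curvilinear devices, each `list(points = n x 2 matrix
#'   of control points (row, col), width, contrast)`
#' @slot edges list of step edges, each `list(position = c(row, col),
#'   orientation (radians), height)`
#' @slot seed integer seed (used by [generateDataset()] randomization)
#' @export
setClass("PhantomSpec",
  representation(
    size = "integer", bitDepth = "integer", pixelSpacingMm = "numeric",
    baseLevel = "numeric", gradient = "numeric", background = "list",
    devices = "list", edges = "list", seed = "integer"
  ),
  prototype(size = c(512L, 512L), bitDepth = 8L, pixelSpacingMm = 0.5,
            baseLevel = 140, gradient = c(0.02, 0.01), background = list(),
            devices = list(), edges = list(), seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@size) != 2L || any(object@size < 8L))
    msg <- c(msg, "'size' must be c(M, N) with both >= 8")
  for (d in object@devices) {
    if (!is.matrix(d$points) || nrow(d$points) < 2L)
      msg <- c(msg, "each device needs at least 2 control points")
    if (!is.null(d$width) && d$width < 1)
      msg <- c(msg, "device width must be >= 1 px")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param size `c(M, N)` in pixels
#' @param bitDepth bit depth (default 8, matching 512 x 512 clinical frames)
#' @param pixelSpacingMm pixel spacing (default 0.5 mm)
#' @param baseLevel constant background level
#' @param gradient `c(gx, gy)` linear gradient
#' @param background,devices,edges content descriptors; see
#'   [PhantomSpec-class]
#' @param seed integer seed
#' @return a [PhantomSpec-class]
#' @export
PhantomSpec <- function(size = c(512L, 512L), bitDepth = 8L,
                        pixelSpacingMm = 0.5, baseLevel = 140,
                        gradient = c(0.02, 0.01), background = list(),
                        devices = list(), edges = list(), seed = 1L) {
  new("PhantomSpec", size = as.integer(size), bitDepth = as.integer(bitDepth),
      pixelSpacingMm = as.numeric(pixelSpacingMm),
      baseLevel = as.numeric(baseLevel), gradient = as.numeric(gradient),
      background = background, devices = devices, edges = edges,
      seed = as.integer(seed))
}

#' PatchDataset: paired noisy/clean training patches
#'
#' @slot clean array `(P, P, n)` of clean patches (intensity domain)
#' @slot noisy array `(P, P, n)` of degraded patches
#' @slot levels numeric vector: percentage noise level used for each pair
#' @slot sourceIds character vector: provenance (frame id) of each patch
#' @slot bitDepth bit depth of the source frames
#' @slot seed integer seed the sampling was derived from
#' @export
setClass("PatchDataset",
  representation(clean = "array", noisy = "array", levels = "numeric",
                 sourceIds = "character", bitDepth = "integer",
                 seed = "integer")
)

setValidity("PatchDataset", function(object) {
  dc <- dim(object@clean); dn <- dim(object@noisy)
  if (length(dc) != 3L || length(dn) != 3L || !all(dc == dn))
    return("'clean' and 'noisy' must be (P, P, n) arrays of equal dimensions")
  if (dc[1] != dc[2]) return("patches must be square")
  n <- dc[3]
  if (length(object@levels) != n || length(object@sourceIds) != n)
    return("'levels' and 'sourceIds' must have one entry per pair")
  TRUE
})

#' ModelConfig: architecture hyper-parameters for EEDN/UDDN
#'
#' @slot variant "eedn" (initial denoiser + attention edge-enhancement branch)
#'   or "uddn" (plain stack of UDBs, the baseline)
#' @slot nUdbsTotal total number of ultra-dense blocks (default 6)
#' @slot nUdbsDenoiser UDBs in the initial denoiser (default 3, half the
#'   total)
#' @slot nUdbsEdge UDBs in the edge-enhancement branch (default 3)
#' @slot udbLayers dense conv layers inside each UDB (default 4)
#' @slot growthChannels feature maps added per UDB layer (default 32)
#' @slot baseChannels width of the denoiser entry/exit convolutions
#'   (default 64)
#' @slot edgeChannels width of the edge branch after the stride-2 encoder
#'   (default `baseChannels / 2`, keeping total capacity on par with the
#'   UDDN baseline)
#' @slot attentionLayers convolution layers in the attention block (fixed 6)
#' @slot seed integer seed for deterministic parameter initialization
#' @export
setClass("ModelConfig",
  representation(
    variant = "character", nUdbsTotal = "integer", nUdbsDenoiser = "integer",
    nUdbsEdge = "integer", udbLayers = "integer", growthChannels = "integer",
    baseChannels = "integer", edgeChannels = "integer",
    attentionLayers = "integer", seed = "integer"
  ),
  prototype(variant = "eedn", nUdbsTotal = 6L, nUdbsDenoiser = 3L,
            nUdbsEdge = 3L, udbLayers = 4L, growthChannels = 32L,
            baseChannels = 64L, edgeChannels = 32L, attentionLayers = 6L,
            seed = 1L)
)

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("eedn", "uddn"))
    msg <- c(msg, "'variant' must be \"eedn\" or \"uddn\"")
  if (object@variant == "eedn" &&
      object@nUdbsDenoiser + object@nUdbsEdge != object@nUdbsTotal)
    msg <- c(msg, "eedn requires nUdbsDenoiser + nUdbsEdge == nUdbsTotal")
  if (object@attentionLayers != 6L)
    msg <- c(msg, "the attention block has a fixed depth of 6 layers")
  if (any(c(object@udbLayers, object@growthChannels, object@baseChannels,
            object@edgeChannels) < 1L))
    msg <- c(msg, "layer counts and channel widths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' @param variant "eedn" or "uddn"
#' @param nUdbsTotal,nUdbsDenoiser,nUdbsEdge,udbLayers UDB counts/depth
#' @param growthChannels,baseChannels,edgeChannels channel widths; when
#'   `edgeChannels` is `NULL` it defaults to `baseChannels / 2`
#' @param seed parameter-initialization seed
#' @return a [ModelConfig-class]
#' @examples
#' ModelConfig()                       # paper-scale EEDN (3 + 3 UDBs)
#' ModelConfig(variant = "uddn")       # 6-UDB baseline
#' @export
ModelConfig <- function(variant = c("eedn", "uddn"), nUdbsTotal = 6L,
                        nUdbsDenoiser = NULL, nUdbsEdge = NULL, udbLayers = 4L,
                        growthChannels = 32L, baseChannels = 64L,
                        edgeChannels = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(nUdbsDenoiser)) nUdbsDenoiser <- as.integer(nUdbsTotal) %/% 2L
  if (is.null(nUdbsEdge)) nUdbsEdge <- as.integer(nUdbsTotal) - as.integer(nUdbsDenoiser)
  if (is.null(edgeChannels)) edgeChannels <- max(1L, as.integer(baseChannels) %/% 2L)
  new("ModelConfig", variant = variant, nUdbsTotal = as.integer(nUdbsTotal),
      nUdbsDenoiser = as.integer(nUdbsDenoiser),
      nUdbsEdge = as.integer(nUdbsEdge), udbLayers = as.integer(udbLayers),
      growthChannels = as.integer(growthChannels),
      baseChannels = as.integer(baseChannels),
      edgeChannels = as.integer(edgeChannels), attentionLayers = 6L,
      seed = as.integer(seed))
}

#' EEDNModel: a network with its parameters
#'
#' @slot config the [ModelConfig-class] the parameters were built for
#' @slot params nested list of numeric arrays (weights, biases, PReLU slopes)
#' @slot steps number of optimization steps the parameters have seen
#' @export
setClass("EEDNModel",
  representation(config = "ModelConfig", params = "list", steps = "integer"),
  prototype(steps = 0L)
)

#' ForwardTrace: all four rasters of one denoising pass
#'
#' Satisfies the composition identity
#' `iOutput == iInter + iEdgePlus - iEdge` elementwise, and all four rasters
#' share the input frame's dimensions and intensity domain.
#'
#' @slot iInter intermediate denoised frame (initial denoiser output)
#' @slot iEdge Laplacian edge map of `iInter`
#' @slot iEdgePlus enhanced edge map from the attention edge branch
#' @slot iOutput final composed frame
#' @export
setClass("ForwardTrace",
  representation(iInter = "matrix", iEdge = "matrix", iEdgePlus = "matrix",
                 iOutput = "matrix")
)

setValidity("ForwardTrace", function(object) {
  d <- dim(object@iInter)
  if (!all(dim(object@iEdge) == d) || !all(dim(object@iEdgePlus) == d) ||
      !all(dim(object@iOutput) == d))
    return("all four rasters must share the same dimensions")
  TRUE
})

#' TrainConfig: optimization schedule
#'
#' Defaults follow the published schedule: batches of 16 patches of 96 x 96,
#' learning rate 1e-3 halved every 2000 steps down to a floor of 1e-6,
#' Charbonnier epsilon 1e-3.
#'
#' @slot batchSize patches per step (default 16)
#' @slot patchSize patch side in pixels (default 96)
#' @slot lrInit initial learning rate (default 1e-3)
#' @slot lrHalveEvery halve the rate every this many steps (default 2000)
#' @slot lrFloor lower bound on the rate (default 1e-6)
#' @slot epsilon Charbonnier compensation parameter (default 1e-3)
#' @slot maxSteps total optimization steps
#' @slot evalEvery run held-out evaluation every this many steps (0 = never)
#' @slot seed shuffling seed
#' @export
setClass("TrainConfig",
  representation(
    batchSize = "integer", patchSize = "integer", lrInit = "numeric",
    lrHalveEvery = "integer", lrFloor = "numeric", epsilon = "numeric",
    maxSteps = "integer", evalEvery = "integer", seed = "integer"
  ),
  prototype(batchSize = 16L, patchSize = 96L, lrInit = 1e-3,
            lrHalveEvery = 2000L, lrFloor = 1e-6, epsilon = 1e-3,
            maxSteps = 40000L, evalEvery = 0L, seed = 1L)
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@lrFloor > object@lrInit) msg <- c(msg, "lrFloor must be <= lrInit")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@maxSteps < 0L) msg <- c(msg, "maxSteps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param batchSize,patchSize,lrInit,lrHalveEvery,lrFloor,epsilon,maxSteps,evalEvery,seed
#'   see [TrainConfig-class]
#' @return a [TrainConfig-class]
#' @export
TrainConfig <- function(batchSize = 16L, patchSize = 96L, lrInit = 1e-3,
                        lrHalveEvery = 2000L, lrFloor = 1e-6, epsilon = 1e-3,
                        maxSteps = 40000L, evalEvery = 0L, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      patchSize = as.integer(patchSize), lrInit = as.numeric(lrInit),
      lrHalveEvery = as.integer(lrHalveEvery), lrFloor = as.numeric(lrFloor),
      epsilon = as.numeric(epsilon), maxSteps = as.integer(maxSteps),
      evalEvery = as.integer(evalEvery), seed = as.integer(seed))
}

#' TrainHistory: per-step training record
#'
#' @slot loss per-step Charbonnier loss
#' @slot lr per-step learning rate (matches [lrSchedule()] exactly)
#' @slot evalSteps steps at which held-out evaluation ran
#' @slot evalPsnr,evalSsim held-out metrics at those steps
#' @export
setClass("TrainHistory",
  representation(loss = "numeric", lr = "numeric", evalSteps = "integer",
                 evalPsnr = "numeric", evalSsim = "numeric")
)

#' LocalSNRResult: per-tile local signal-to-noise decomposition
#'
#' @slot perPatch data.frame with one row per included tile: `row`, `col`
#'   (tile indices), `mu`, `sigma`, `snr`
#' @slot meanSnr arithmetic mean of the included per-tile SNRs (`NaN` when
#'   every tile was excluded)
#' @slot nExcluded number of tiles excluded because their standard deviation
#'   was zero
#' @slot patchSize tile side in pixels
#' @export
setClass("LocalSNRResult",
  representation(perPatch = "data.frame", meanSnr = "numeric",
                 nExcluded = "integer", patchSize = "integer")
)

#' SpectrumProfile: radially averaged spectral magnitude
#'
#' For each integer annulus \eqn{r \le \sqrt{u^2+v^2} < r+1} in centered DFT
#' coordinates, `sOfR` holds the mean magnitude S(r) and `nOfR` the number of
#' frequency bins in the annulus, so that `sum(nOfR * sOfR)` equals the total
#' spectral magnitude over all covered bins.
#'
#' @slot radii integer annulus indices (0 = DC)
#' @slot sOfR mean magnitude per annulus
#' @slot nOfR bin count per annulus
#' @slot cyclesPerMm physical frequency of each annulus (cycles/mm), or
#'   `numeric(0)` when no geometry was available
#' @slot nyquistCpmm Nyquist frequency in cycles/mm, or `numeric(0)`
#' @export
setClass("SpectrumProfile",
  representation(radii = "integer", sOfR = "numeric", nOfR = "integer",
                 cyclesPerMm = "numeric", nyquistCpmm = "numeric"),
  prototype(cyclesPerMm = numeric(0), nyquistCpmm = numeric(0))
)

setValidity("SpectrumProfile", function(object) {
  msg <- character(0)
  if (length(object@radii) != length(object@sOfR) ||
      length(object@radii) != length(object@nOfR))
    msg <- c(msg, "radii, sOfR and nOfR must have equal length")
  if (is.unsorted(object@radii, strictly = TRUE))
    msg <- c(msg, "radii must be strictly increasing")
  if (any(object@sOfR < 0)) msg <- c(msg, "sOfR must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Band: a spatial-frequency interval in cycles/mm
#'
#' @slot fLo,fHi lower and upper frequency (cycles/mm); an empty band
#'   (e.g. an empty observer consensus) has `fLo >= fHi`
#' @export
setClass("Band", representation(fLo = "numeric", fHi = "numeric"))

#' Construct a Band
#'
#' @param fLo,fHi band limits in cycles/mm
#' @return a [Band-class]
#' @examples
#' Band(0.10, 0.23)  # the observer consensus band of the clinical study
#' @export
Band <- function(fLo, fHi) {
  new("Band", fLo = as.numeric(fLo), fHi = as.numeric(fHi))
}
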