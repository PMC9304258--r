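#' @include AllGenerics.R
NULL

#' @describeIn ImageFrame pixel matrix
#' @param x an ImageFrame
#' @aliases pixels,ImageFrame-method
#' @export
setMethod("pixels", "ImageFrame", function(x) x@pixels)

#' @describeIn ImageFrame bit depth
#' @aliases bitDepth,ImageFrame-method
#' @export
setMethod("bitDepth", "ImageFrame", function(x) x@bitDepth)

#' @describeIn ImageFrame pixel spacing in mm (may be empty)
#' @aliases pixelSpacing,ImageFrame-method
#' @export
setMethod("pixelSpacing", "ImageFrame", function(x) x@pixelSpacingMm)

#' @describeIn ImageFrame acquisition geometry (may be NULL)
#' @aliases geometry,ImageFrame-method
#' @export
setMethod("geometry", "ImageFrame", function(x) x@geometry)

setMethod("bitDepth", "PatchDataset", function(x) x@bitDepth)

#' @describeIn ImageFrame dimensions as c(height, width)
#' @export
setMethod("dim", "ImageFrame", function(x) dim(x@pixels))

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  sp <- if (length(object@pixelSpacingMm)) {
    sprintf(", %.3g mm/px", object@pixelSpacingMm)
  } else ""
  cat(sprintf("ImageFrame %dx%d, %d-bit%s\n", d[2], d[1], object@bitDepth, sp))
  cat(sprintf("  intensity range [%.4g, %.4g]%s\n",
              min(object@pixels), max(object@pixels),
              if (is.null(object@geometry)) "" else ", geometry attached"))
})

setMethod("show", "GeometrySpec", function(object) {
  cat(sprintf(
    "GeometrySpec: detector %.4g mm, SID %.4g mm, SED %.4g mm (Nyquist %.4g cycles/mm)\n",
    object@detectorSpacingMm, object@sidMm, object@sedMm,
    nyquistCyclesPerMm(object)))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(
    "NoiseSpec: mu = %.4g%%, level distribution N(%.4g, %.4g^2)%%, delta %.4g%%, range [%g, %g]%%\n",
    object@muPercent, object@meanPercent, object@sigmaPercent,
    object@deltaPercent, object@levelRange[1], object@levelRange[2]))
})

setMethod("show", "PatchDataset", function(object) {
  d <- dim(object@clean)
  cat(sprintf("PatchDataset: %d pairs of %dx%d patches (%d-bit source)\n",
              d[3], d[1], d[2], object@bitDepth))
  lv <- sort(unique(object@levels))
  cat("  levels (%):", paste(lv, collapse = " "), "\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig [%s]: %d UDBs", object@variant, object@nUdbsTotal))
  if (object@variant == "eedn")
    cat(sprintf(" (%d denoiser + %d edge)", object@nUdbsDenoiser,
                object@nUdbsEdge))
  cat(sprintf(", %d layers/UDB, growth %d, base %d, edge %d channels\n",
              object@udbLayers, object@growthChannels, object@baseChannels,
              object@edgeChannels))
})

setMethod("show", "EEDNModel", function(object) {
  cat(sprintf("EEDNModel (%s), %d parameters, trained %d steps\n",
              object@config@variant, parameterCount(object), object@steps))
})

setMethod("show", "ForwardTrace", function(object) {
  d <- dim(object@iInter)
  resid <- max(abs(object@iOutput -
                     (object@iInter + object@iEdgePlus - object@iEdge)))
  cat(sprintf("ForwardTrace %dx%d (composition residual %.3g)\n",
              d[2], d[1], resid))
})

setMethod("show", "LocalSNRResult", function(object) {
  cat(sprintf("LocalSNRResult: mean SNR %.4g over %d tiles of %dx%d (%d excluded)\n",
              object@meanSnr, nrow(object@perPatch), object@patchSize,
              object@patchSize, object@nExcluded))
})

setMethod("show", "SpectrumProfile", function(object) {
  cat(sprintf("SpectrumProfile: %d annuli", length(object@radii)))
  if (length(object@nyquistCpmm))
    cat(sprintf(", Nyquist %.4g cycles/mm", object@nyquistCpmm))
  cat("\n")
})

setMethod("show", "Band", function(object) {
  if (isEmptyBand(object)) cat("Band: empty\n")
  else cat(sprintf("Band: %.4g - %.4g cycles/mm\n", object@fLo, object@fHi))
})

#' Is a band empty?
#'
#' A band is empty when `fLo >= fHi` (e.g. the consensus of disjoint observer
#' selections).
#'
#' @param band a [Band-class]
#' @return logical
#' @export
isEmptyBand <- function(band) {
  stopifnot(is(band, "Band"))
  band@fLo >= band@fHi
}
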