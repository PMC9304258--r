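#' @include AllClasses.R
NULL

#' Pixel matrix of a frame
#' @param x an [ImageFrame-class]
#' @return numeric matrix
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Bit depth of a frame or dataset
#' @param x an [ImageFrame-class] or [PatchDataset-class]
#' @return integer
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Detector-plane pixel spacing (mm/pixel)
#' @param x an [ImageFrame-class]
#' @return numeric scalar, or `numeric(0)` when unknown
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Acquisition geometry of a frame
#' @param x an [ImageFrame-class]
#' @return a [GeometrySpec-class] or `NULL`
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Denoise a frame with a trained (or untrained) network
#'
#' @param model an [EEDNModel-class]
#' @param frame an [ImageFrame-class] or numeric matrix
#' @param ... unused
#' @return a [ForwardTrace-class] in the input's intensity domain
#' @export
setGeneric("denoise", function(model, frame, ...) standardGeneric("denoise"))

#' Number of trainable parameters
#' @param model an [EEDNModel-class]
#' @return integer count
#' @export
setGeneric("parameterCount", function(model) standardGeneric("parameterCount"))
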