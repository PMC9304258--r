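#' @include AllClasses.R
NULL

#' Read a radiographic frame from disk
#'
#' Reads PNG, TIFF or uncompressed little-endian DICOM into an
#' [ImageFrame-class]. Bit depth is inferred from the file (PNG IHDR, TIFF
#' BitsPerSample, DICOM BitsStored). For DICOM, pixel values are rescaled by
#' the header slope/intercept and, when the relevant tags are present, a
#' [GeometrySpec-class] is attached; frames without geometry tags are
#' accepted with a warning and carry `geometry = NULL`.
#'
#' DICOM tag mapping: detector element spacing is taken from Imager Pixel
#' Spacing (0018,1164), falling back to Pixel Spacing (0028,0030);
#' source-to-image distance from Distance Source to Detector (0018,1110);
#' source-to-entrance distance from Distance Source to Entrance (0040,0306),
#' falling back to Distance Source to Patient (0018,1111).
#'
#' @param path file path
#' @param format "png", "tiff", "dicom", or "auto" (from the extension)
#' @param frame frame index for multi-frame DICOM (default 1)
#' @return an [ImageFrame-class]
#' @seealso [writeFrame()]
#' @examples
#' f <- ImageFrame(matrix(sample(0:255, 256, TRUE), 16, 16))
#' p <- tempfile(fileext = ".png")
#' writeFrame(f, p)
#' g <- readFrame(p)
#' stopifnot(identical(pixels(f), pixels(g)))
#' @export
readFrame <- function(path, format = c("auto", "png", "tiff", "dicom"),
                      frame = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff", dcm = "dicom", dicom = "dicom",
      stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
    png = read_png_frame(path),
    tiff = read_tiff_frame(path),
    dicom = read_dicom_frame(path, frame))
}

read_png_frame <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("unreadable PNG file: ", conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L &&
        (max(abs(img[, , 1] - img[, , 2])) > 0 ||
         max(abs(img[, , 1] - img[, , 3])) > 0))
      stop("color PNG images are not supported")
    img <- img[, , 1]
  }
  bd <- png_bit_depth(path)
  ImageFrame(round(img * (2^bd - 1)), bitDepth = bd,
             frameId = basename(path))
}

# bit depth byte of the IHDR chunk (offset 24 past the 8-byte signature)
png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 32L)
  if (length(hdr) < 25L) stop("truncated PNG file")
  as.integer(hdr[25])
}

read_tiff_frame <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e)
                    stop("unreadable TIFF file: ", conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L && max(abs(img[, , 1] - img[, , 2])) > 0)
      stop("color TIFF images are not supported")
    img <- img[, , 1]
  }
  bd <- attr(img, "bits.per.sample")
  if (is.null(bd)) bd <- 8L
  m <- as.matrix(img)
  attributes(m) <- list(dim = dim(m))
  ImageFrame(m, bitDepth = as.integer(bd), frameId = basename(path))
}

#' Write a frame to disk
#'
#' Quantizes (rounds) the intensities and writes a grayscale PNG (8-bit) or
#' TIFF (8- or 16-bit). Intensities must already lie inside
#' \eqn{[0, 2^n - 1]}: out-of-range values are a contract violation and the
#' caller is expected to clip first (processing keeps frames in floating
#' point; quantization happens only here). The round trip
#' `readFrame(writeFrame(x))` is lossless for integer data.
#'
#' @param frame an [ImageFrame-class]
#' @param path output path
#' @param format "png", "tiff" or "auto"
#' @return `invisible(path)`
#' @seealso [readFrame()], [clipFrame()]
#' @export
writeFrame <- function(frame, path, format = c("auto", "png", "tiff")) {
  stopifnot(is(frame, "ImageFrame"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, png = "png", tif = "tiff", tiff = "tiff",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  maxv <- 2^frame@bitDepth - 1
  p <- round(frame@pixels)
  if (min(frame@pixels) < 0 || max(frame@pixels) > maxv)
    stop("intensities outside [0, 2^n - 1]; clip before writing ",
         "(see clipFrame())")
  if (format == "png") {
    if (frame@bitDepth != 8L)
      stop("PNG output supports 8-bit frames only; use TIFF for 16-bit")
    png::writePNG(p / maxv, path)
  } else {
    if (!frame@bitDepth %in% c(8L, 16L))
      stop("TIFF output supports 8- or 16-bit frames")
    tiff::writeTIFF(p / maxv, path,
                    bits.per.sample = as.integer(frame@bitDepth))
  }
  invisible(path)
}

#' Clip and quantize a frame to its integer intensity range
#'
#' @param frame an [ImageFrame-class]
#' @return an [ImageFrame-class] with intensities rounded and clipped to
#'   \eqn{[0, 2^n - 1]}
#' @export
clipFrame <- function(frame) {
  stopifnot(is(frame, "ImageFrame"))
  maxv <- 2^frame@bitDepth - 1
  frame@pixels <- pmin(pmax(round(frame@pixels), 0), maxv)
  frame
}
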