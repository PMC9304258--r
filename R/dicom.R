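# Minimal DICOM reader: single- and multi-frame uncompressed little-endian
# files (implicit and explicit VR). Only the tags needed for pixel data,
# rescaling and acquisition geometry are interpreted; everything else is
# skipped by length. Compressed transfer syntaxes and undefined-length
# sequences are rejected.

DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
u32 <- function(raw, off) {
  as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
}

# VRs carrying a 2-byte reserved field and a 4-byte length in explicit mode
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dicom_parse <- function(raw) {
  n <- length(raw)
  off <- 0L
  if (n > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  elems <- list()
  explicit <- TRUE   # file meta group is always explicit little endian
  ts <- DICOM_EXPLICIT_LE
  in_meta_checked <- FALSE
  while (off + 8L <= n) {
    group <- u16(raw, off)
    elem <- u16(raw, off + 2L)
    if (!in_meta_checked && group != 2L) {
      # leaving (or never having had) the meta group: apply transfer syntax
      explicit <- !identical(ts, DICOM_IMPLICIT_LE)
      in_meta_checked <- TRUE
    }
    if (group == 2L || explicit) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% DICOM_LONG_VRS) {
          len <- u32(raw, off + 8L)
          hdr <- 12L
        } else {
          len <- u16(raw, off + 6L)
          hdr <- 8L
        }
      } else {
        # not a valid VR: fall back to implicit layout for this element
        vr <- NA_character_
        len <- u32(raw, off + 4L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(raw, off + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    start <- off + hdr
    if (start + len > n) stop("truncated DICOM element at offset ", off)
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- raw[seq.int(start + 1L, length.out = len)]
    if (key == "0002,0010") {
      ts <- sub("\\x00+$", "", rawToChar(elems[[key]]))
      ts <- trimws(ts)
    }
    off <- start + as.integer(len)
  }
  if (!identical(ts, DICOM_EXPLICIT_LE) && !identical(ts, DICOM_IMPLICIT_LE))
    stop("unsupported DICOM transfer syntax: ", ts)
  elems
}

dicom_str <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  trimws(sub("\\x00+$", "", rawToChar(v)))
}

dicom_num <- function(elems, key) {
  s <- dicom_str(elems, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v) || length(v) < 2L) return(NULL)
  u16(v, 0L)
}

read_dicom_frame <- function(path, frame = 1L) {
  raw <- readBin(path, "raw", file.info(path)$size)
  elems <- tryCatch(dicom_parse(raw), error = function(e)
    stop("unreadable DICOM file: ", conditionMessage(e)))
  rows <- dicom_us(elems, "0028,0010")
  cols <- dicom_us(elems, "0028,0011")
  bits_alloc <- dicom_us(elems, "0028,0100")
  bits_stored <- dicom_us(elems, "0028,0101")
  pixrep <- dicom_us(elems, "0028,0103")
  px <- elems[["7fe0,0010"]]
  if (is.null(px) || is.null(rows) || is.null(cols))
    stop("DICOM file has no usable pixel data")
  if (is.null(bits_alloc)) bits_alloc <- 16L
  if (is.null(bits_stored)) bits_stored <- bits_alloc
  nframes <- suppressWarnings(as.integer(dicom_str(elems, "0028,0008")))
  if (is.na(nframes) || is.null(nframes) || length(nframes) == 0L) nframes <- 1L
  if (frame < 1L || frame > nframes)
    stop("frame ", frame, " out of range (file has ", nframes, " frame(s))")
  npix <- rows * cols
  if (bits_alloc == 8L) {
    vals <- as.integer(px)
    size <- 1L
  } else if (bits_alloc == 16L) {
    vals <- readBin(px, "integer", n = length(px) %/% 2L, size = 2L,
                    signed = FALSE, endian = "little")
    size <- 2L
  } else stop("unsupported BitsAllocated: ", bits_alloc)
  if (length(vals) < npix * nframes)
    stop("DICOM pixel data shorter than Rows x Columns x NumberOfFrames")
  vals <- vals[seq.int((frame - 1L) * npix + 1L, length.out = npix)]
  if (identical(pixrep, 1L)) {
    wrap <- 2^bits_alloc
    vals <- ifelse(vals >= wrap / 2, vals - wrap, vals)
  }
  # DICOM pixel order is row-major from the top-left
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  slope <- dicom_num(elems, "0028,1053")
  inter <- dicom_num(elems, "0028,1052")
  if (!is.null(slope) || !is.null(inter)) {
    m <- m * (if (is.null(slope)) 1 else slope[1]) +
      (if (is.null(inter)) 0 else inter[1])
  }
  spacing <- dicom_num(elems, "0018,1164")
  if (is.null(spacing)) spacing <- dicom_num(elems, "0028,0030")
  sid <- dicom_num(elems, "0018,1110")
  sed <- dicom_num(elems, "0040,0306")
  if (is.null(sed)) sed <- dicom_num(elems, "0018,1111")
  geom <- NULL
  if (!is.null(spacing) && !is.null(sid) && !is.null(sed)) {
    geom <- GeometrySpec(mean(spacing), sid[1], sed[1])
  } else {
    warning("DICOM geometry tags incomplete; frame returned without geometry")
  }
  ImageFrame(m, bitDepth = as.integer(bits_stored),
             pixelSpacingMm = if (is.null(spacing)) numeric(0) else mean(spacing),
             geometry = geom, frameId = basename(path))
}
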