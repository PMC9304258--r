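# Shared fixtures: random frames, a byte-level DICOM writer used as the
# independent oracle for the reader, and the memoized desk-scale training
# run shared by the end-to-end checks.

rand_frame <- function(seed, h = 16L, w = 16L, bitDepth = 8L) {
  set.seed(seed)
  ImageFrame(matrix(sample(0:(2^bitDepth - 1), h * w, replace = TRUE), h, w),
             bitDepth = bitDepth)
}

small_phantom <- function(size = 128L, seed = 1L) {
  generatePhantom(defaultPhantomSpec(size = c(size, size), seed = seed))
}

# --- minimal DICOM writer (explicit VR little endian) -----------------------
# Written directly at the byte level, independently of the package's parser.

.u16 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
.u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.elem <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  if (vr %in% c("OB", "OW")) {
    c(.u16(group), .u16(element), charToRaw(vr), as.raw(c(0L, 0L)),
      .u32(length(value)), value)
  } else {
    c(.u16(group), .u16(element), charToRaw(vr), .u16(length(value)), value)
  }
}

# pixels: a matrix or list of matrices (multi-frame); geometry tags optional
write_test_dicom <- function(path, pixels, bits_stored = 16L,
                             spacing = c(0.4, 0.4), sid = 1000, sed = 800,
                             slope = NULL, intercept = NULL,
                             with_geometry = TRUE) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  rows <- nrow(pixels[[1L]]); cols <- ncol(pixels[[1L]])
  px <- unlist(lapply(pixels, function(m) as.integer(t(m))))  # row-major
  pxraw <- writeBin(px, raw(), size = 2L, endian = "little")
  meta <- c(
    .elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(.elem(0x0002, 0x0000, "UL", .u32(length(meta))), meta)
  ds <- c(
    if (with_geometry) .elem(0x0018, 0x1110, "DS", format(sid)),
    if (with_geometry) .elem(0x0018, 0x1164, "DS",
                             paste(format(spacing), collapse = "\\")),
    .elem(0x0028, 0x0002, "US", .u16(1L)),
    if (length(pixels) > 1L)
      .elem(0x0028, 0x0008, "IS", as.character(length(pixels))),
    .elem(0x0028, 0x0010, "US", .u16(rows)),
    .elem(0x0028, 0x0011, "US", .u16(cols)),
    .elem(0x0028, 0x0100, "US", .u16(16L)),
    .elem(0x0028, 0x0101, "US", .u16(bits_stored)),
    .elem(0x0028, 0x0102, "US", .u16(bits_stored - 1L)),
    .elem(0x0028, 0x0103, "US", .u16(0L)),
    if (!is.null(intercept)) .elem(0x0028, 0x1052, "DS", format(intercept)),
    if (!is.null(slope)) .elem(0x0028, 0x1053, "DS", format(slope)),
    if (with_geometry) .elem(0x0040, 0x0306, "DS", format(sed)),
    .elem(0x7FE0, 0x0010, "OW", pxraw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

# --- memoized desk-scale run ------------------------------------------------
# One tiny-network training (1 denoiser + 1 edge UDB, growth 8) on 2000
# phantom patches with Gaussian-distributed noise levels, evaluated on 20
# held-out phantoms degraded at the 60% clinical level. Shared across the
# end-to-end test blocks so training happens once.

.desk_cache <- new.env(parent = emptyenv())

desk_run <- function() {
  if (!is.null(.desk_cache$run)) return(.desk_cache$run)
  train_frames <- generateDataset(
    defaultPhantomSpec(size = c(256L, 256L), seed = 7L), 20L, seed = 7L)
  ds <- buildTrainingSet(train_frames, 2000L, patchSize = 96L,
                         spec = NoiseSpec(seed = 7L))
  model <- buildModel(deskModelConfig(seed = 7L))
  fit <- trainModel(model, ds, deskTrainConfig(seed = 7L))

  held_clean <- generateDataset(
    defaultPhantomSpec(size = c(256L, 256L), seed = 77L), 20L, seed = 77L)
  res <- lapply(seq_along(held_clean), function(i) {
    clean <- held_clean[[i]]
    noisy <- addPoissonNoise(clean, NoiseSpec(muPercent = 60,
                                              seed = 1000L + i))
    tr <- denoise(fit$model, noisy)
    den <- ImageFrame(tr@iOutput, bitDepth = 8L,
                      pixelSpacingMm = clean@pixelSpacingMm)
    list(
      comp_resid = max(abs(tr@iOutput -
                             (tr@iInter + tr@iEdgePlus - tr@iEdge))),
      psnr_noisy = psnr(clipFrame(noisy), clean),
      psnr_denoised = psnr(clipFrame(den), clean),
      snr_noisy = localSNR(noisy)@meanSnr,
      snr_denoised = localSNR(den)@meanSnr,
      ratio = transferRatio(radialProfile(den), radialProfile(noisy)))
  })
  .desk_cache$run <- list(
    model = fit$model, history = fit$history,
    comp_resid = max(vapply(res, `[[`, numeric(1), "comp_resid")),
    psnr_noisy = vapply(res, `[[`, numeric(1), "psnr_noisy"),
    psnr_denoised = vapply(res, `[[`, numeric(1), "psnr_denoised"),
    snr_noisy = vapply(res, `[[`, numeric(1), "snr_noisy"),
    snr_denoised = vapply(res, `[[`, numeric(1), "snr_denoised"),
    ratios = lapply(res, `[[`, "ratio"))
  .desk_cache$run
}
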